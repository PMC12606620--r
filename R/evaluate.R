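# Scoring, the scaled transfer-learning experiment, and leave-one-design-out
# cross-validation.

# mean metrics of a prediction matrix against the truth in a pair set
score_matrix <- function(pred, pairs) {
  n <- nrow(pred)
  vals <- vapply(seq_len(n), function(i) c(
    sam = sam(pred[i, ], pairs$clean[i, ]),
    rmse = rmse(pred[i, ], pairs$clean[i, ]),
    mae = mae(pred[i, ], pairs$clean[i, ]),
    uned = uned(pred[i, ], pairs$clean[i, ])), numeric(4))
  rowMeans(vals)
}

#' Score correction variants on a test pair set
#'
#' Computes SAM, RMSE, MAE and UNED for the uncorrected spectra, each model
#' in `models`, and (optionally) the best-window Savitzky-Golay baseline;
#' percentage improvements are relative to the uncorrected variant.
#'
#' @param pairs a test `pair_set`.
#' @param models named list of trained `unet_model`s (e.g.
#'   `list(model1_TL = ..., model2_real_only = ...)`).
#' @param sg_windows odd window grid for the SG baseline, or `NULL` to skip.
#' @return list with the long-format `records` data.frame (variant, metric,
#'   value, improvement_pct) and `mean_diff`, a matrix of mean
#'   (prediction - truth) curves per variant.
#' @export
evaluate_pairs <- function(pairs, models = list(),
                           sg_windows = seq(5, 101, by = 4)) {
  preds <- list(uncorrected = pairs$corrupted)
  for (nm in names(models)) preds[[nm]] <- correct(models[[nm]], pairs$corrupted)
  if (!is.null(sg_windows)) {
    sg <- sg_best_rmse(pairs$corrupted, pairs$clean, sg_windows)
    preds$sg_baseline <- t(apply(pairs$corrupted, 1, signal::sgolayfilt,
                                 p = 3, n = sg$best_window))
  }
  base <- score_matrix(preds$uncorrected, pairs)
  records <- do.call(rbind, lapply(names(preds), function(v) {
    m <- score_matrix(preds[[v]], pairs)
    data.frame(variant = v, metric = names(m), value = unname(m),
               improvement_pct = unname(improvement_pct(base, m)))
  }))
  mean_diff <- vapply(preds, function(p) colMeans(p - pairs$clean),
                      numeric(ncol(pairs$clean)))
  out <- list(records = records, mean_diff = mean_diff)
  if (!is.null(sg_windows)) out$sg_best_window <- sg$best_window
  out
}

# shared builder: corpora and pairs for a set of training designs plus
# held-out test sets; all randomness derives from `seed`.  Training
# interpolation designs contribute silicon-thickness variants alongside
# their nominal stacks (the interpolation protocol), so fringe periods are
# covered continuously; held-out designs always use their exact stack only.
.build_corpora <- function(profiles, train_ids, test_ids, seed, n_pretrain,
                           n_finetune, n_test, axis, suite = NULL,
                           n_variants = 10, instrument_fwhm = NULL) {
  if (is.null(instrument_fwhm)) instrument_fwhm <- 2 * (axis[2] - axis[1])
  tr <- profiles[as.character(train_ids)]
  if (!is.null(suite) && n_variants > 0)
    for (id in intersect(train_ids, 6:8))
      tr <- c(tr, vary_profiles(suite[[id]], n_variants, axis,
                                derive_seed(seed, paste0("variants", id))))
  corpus <- function(n, label) apply_instrument(
    raman_corpus(n, derive_seed(seed, label), axis), instrument_fwhm)
  pre <- make_simulated_pairs(corpus(n_pretrain, "pretrain_corpus"),
                              tr, seed = derive_seed(seed, "pretrain_pairs"))
  fine <- make_experimental_pairs(corpus(n_finetune, "finetune_corpus"),
                                  tr, seed = derive_seed(seed, "finetune_pairs"))
  tests <- lapply(test_ids, function(id) make_experimental_pairs(
    corpus(n_test, paste0("test_corpus", id)),
    profiles[as.character(id)], seed = derive_seed(seed, paste0("test_pairs", id))))
  names(tests) <- as.character(test_ids)
  list(pre = pre, fine = fine, tests = tests)
}

# shared trainer: transfer-learning model (pretrain + finetune) and
# real-only model on the same fine-tuning pairs
.fit_models <- function(corp, unet, seed, pre_cfg, fine_cfg, scratch_cfg) {
  L <- length(corp$pre$axis)
  m1 <- build_unet(unet, input_length = L, seed = derive_seed(seed, "init1"))
  m1 <- pretrain(m1, corp$pre, pre_cfg)
  m1 <- finetune(m1, corp$fine, fine_cfg)
  m2 <- build_unet(unet, input_length = L, seed = derive_seed(seed, "init2"))
  m2 <- train_unet(m2, corp$fine, scratch_cfg, phase = "real_only")
  list(model1_TL = m1, model2_real_only = m2)
}

# reduced-width, reduced-depth architecture used by the desk-scale
# experiments (the full-scale reference is 32-...-512 | 1024 at 5 levels)
.experiment_unet <- function() unet_config(channels = c(16, 32),
                                           bottleneck = 64, kernel = 9)

# the two models receive the same experimental-data budget (12 epochs);
# the transfer-learning model differs only by its pretraining phase
.experiment_cfgs <- function(seed) list(
  pre = train_config(batch_size = 64, epochs = 6, base_lr = 1e-3, max_lr = 1e-2,
                     weight_decay = 1e-3, half_cycle_epochs = 2,
                     seed = derive_seed(seed, "pre")),
  fine = train_config(batch_size = 64, epochs = 12, base_lr = 1e-3, max_lr = 5e-3,
                      weight_decay = 1e-3, half_cycle_epochs = 3,
                      seed = derive_seed(seed, "fine")),
  scratch = train_config(batch_size = 64, epochs = 12, base_lr = 1e-3, max_lr = 1e-2,
                         weight_decay = 1e-3, half_cycle_epochs = 3,
                         seed = derive_seed(seed, "scratch")))

#' Scaled-down two-phase transfer-learning experiment
#'
#' Reproduces the study protocol at desk scale with a joint holdout: one
#' interpolation design and one extrapolation design are excluded from all
#' training data; the transfer-learning model (pretrained on simulated
#' A-times pairs from the six remaining designs, fine-tuned on
#' experimental-like E+1 pairs) and a real-only model (trained from scratch
#' on the same fine-tuning pairs) are then scored on both held-out designs.
#'
#' @param seed master seed; every corpus, jitter, initialization and
#'   shuffling seed derives from it.
#' @param holdout_interp held-out interpolation design id (default 8).
#' @param holdout_extrap held-out extrapolation design id (default 1).
#' @param n_pretrain,n_finetune,n_test corpus sizes (defaults 2000/1000/64).
#' @param axis_points spectral resolution of the experiment (default 256
#'   points over 0-3700 cm^-1).
#' @param instrument_fwhm spectrograph-response width applied to the clean
#'   corpora (cm^-1); default two axis steps (anti-aliased sampling).
#' @param unet architecture (default reduced 16-32 | 64, kernel 9).
#' @param cfgs list of `pre`, `fine`, `scratch` [train_config()]s.
#' @return list with per-holdout evaluation (`interp`, `extrap`, each as
#'   returned by [evaluate_pairs()]), the trained `models`, and a `summary`
#'   data.frame of RMSE ratios and mean improvements.
#' @export
transfer_experiment <- function(seed = 1, holdout_interp = 8, holdout_extrap = 1,
                                n_pretrain = 2000, n_finetune = 1000, n_test = 48,
                                axis_points = 256, instrument_fwhm = NULL,
                                unet = .experiment_unet(),
                                cfgs = .experiment_cfgs(seed)) {
  axis <- default_axis(axis_points)
  suite <- design_suite(seed)
  train_ids <- setdiff(1:8, c(holdout_interp, holdout_extrap))
  profiles <- design_profiles(suite, axis)
  corp <- .build_corpora(profiles, train_ids, c(holdout_interp, holdout_extrap),
                         seed, n_pretrain, n_finetune, n_test, axis,
                         suite = suite, instrument_fwhm = instrument_fwhm)
  models <- .fit_models(corp, unet, seed, cfgs$pre, cfgs$fine, cfgs$scratch)
  ev_i <- evaluate_pairs(corp$tests[[as.character(holdout_interp)]], models)
  ev_e <- evaluate_pairs(corp$tests[[as.character(holdout_extrap)]], models)
  pick <- function(ev, v, m, col = "value")
    ev$records[ev$records$variant == v & ev$records$metric == m, col]
  summary <- data.frame(
    holdout = c("interp", "extrap"),
    design_id = c(holdout_interp, holdout_extrap),
    rmse_uncorrected = c(pick(ev_i, "uncorrected", "rmse"),
                         pick(ev_e, "uncorrected", "rmse")),
    rmse_model1 = c(pick(ev_i, "model1_TL", "rmse"),
                    pick(ev_e, "model1_TL", "rmse")),
    rmse_model2 = c(pick(ev_i, "model2_real_only", "rmse"),
                    pick(ev_e, "model2_real_only", "rmse")),
    impr_model1 = c(mean(ev_i$records$improvement_pct[ev_i$records$variant == "model1_TL"]),
                    mean(ev_e$records$improvement_pct[ev_e$records$variant == "model1_TL"])),
    impr_model2 = c(mean(ev_i$records$improvement_pct[ev_i$records$variant == "model2_real_only"]),
                    mean(ev_e$records$improvement_pct[ev_e$records$variant == "model2_real_only"])))
  summary$rmse_ratio_model1 <- summary$rmse_model1 / summary$rmse_uncorrected
  list(interp = ev_i, extrap = ev_e, models = models, summary = summary,
       seed = seed)
}

#' Leave-one-design-out cross-validation
#'
#' For each fold one design is held entirely out; the transfer-learning
#' model (Model 1) and the real-only model (Model 2) are trained on the
#' remaining designs and scored on the held-out one with SAM, RMSE, MAE and
#' UNED plus the Savitzky-Golay baseline.
#'
#' @param seed master seed.
#' @param folds design ids to use as held-out folds (default all 8).
#' @param n_pretrain,n_finetune,n_test per-fold corpus sizes.
#' @param axis_points spectral resolution.
#' @param unet architecture for both models.
#' @param sg_windows SG baseline window grid (or `NULL` to skip).
#' @return a `cv_report`: list with the long `records` data.frame (fold,
#'   scenario, variant, metric, value, improvement_pct) and per-fold
#'   mean-difference curves.
#' @export
lodo_cv <- function(seed = 1, folds = 1:8, n_pretrain = 2000, n_finetune = 1000,
                    n_test = 64, axis_points = 256, instrument_fwhm = NULL,
                    unet = .experiment_unet(),
                    sg_windows = seq(5, 101, by = 4)) {
  axis <- default_axis(axis_points)
  suite <- design_suite(seed)
  profiles <- design_profiles(suite, axis)
  records <- list(); mean_diff <- list()
  for (fold in folds) {
    fseed <- derive_seed(seed, paste0("fold", fold))
    cfgs <- .experiment_cfgs(fseed)
    corp <- .build_corpora(profiles, setdiff(1:8, fold), fold, fseed,
                           n_pretrain, n_finetune, n_test, axis, suite = suite,
                           instrument_fwhm = instrument_fwhm)
    models <- .fit_models(corp, unet, fseed, cfgs$pre, cfgs$fine, cfgs$scratch)
    ev <- evaluate_pairs(corp$tests[[as.character(fold)]], models, sg_windows)
    rec <- ev$records
    rec$fold <- fold
    rec$scenario <- design_scenario(fold)
    records[[as.character(fold)]] <- rec
    mean_diff[[as.character(fold)]] <- ev$mean_diff
  }
  structure(list(records = do.call(rbind, records), mean_diff = mean_diff,
                 seed = seed, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds (designs %s)\n", length(x$folds),
              paste(x$folds, collapse = ",")))
  agg <- stats::aggregate(improvement_pct ~ variant + scenario, x$records, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report to CSV
#' @param report a `cv_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  utils::write.csv(report$records, path, row.names = FALSE)
  invisible(path)
}
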