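#' Training settings
#'
#' The defaults are a documented point inside the hyperparameter search
#' space of [search_space()]: batch 128, GELU, AdamW, base learning rate
#' 1e-5, max 1e-3, Triangular2 cyclic schedule, weight decay 1e-4,
#' half-cycle 2 epochs.  The loss is mean-squared error on max-normalized
#' intensities (`"mae"` selects mean absolute error instead).
#'
#' @param batch_size minibatch size.
#' @param activation if non-NULL, overrides the model's activation (the
#'   activations carry no weights, so this is safe at any phase).
#' @param base_lr,max_lr cyclic learning-rate bounds.
#' @param weight_decay decoupled weight decay (AdamW) or L2 (Adam/NAdam).
#' @param scheduler `"Triangular"` or `"Triangular2"`.
#' @param optimizer `"AdamW"`, `"Adam"` or `"NAdam"`.
#' @param half_cycle_epochs epochs per half learning-rate cycle.
#' @param epochs number of training epochs.
#' @param seed integer seed for shuffling, dropout and any stochastic
#'   activation.
#' @param loss `"mse"` or `"mae"`.
#' @param clip_norm global gradient-norm clip (numerical guard).
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 128, activation = NULL, base_lr = 1e-5,
                         max_lr = 1e-3, weight_decay = 1e-4,
                         scheduler = c("Triangular2", "Triangular"),
                         optimizer = c("AdamW", "Adam", "NAdam"),
                         half_cycle_epochs = 2, epochs = 10, seed = 1,
                         loss = c("mse", "mae"), clip_norm = 5) {
  structure(list(batch_size = as.integer(batch_size), activation = activation,
                 base_lr = base_lr, max_lr = max_lr, weight_decay = weight_decay,
                 scheduler = match.arg(scheduler), optimizer = match.arg(optimizer),
                 half_cycle_epochs = half_cycle_epochs, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss = match.arg(loss),
                 clip_norm = clip_norm),
            class = "train_config")
}

# cyclic learning rate at a (1-based) global step
cyclic_lr <- function(step, steps_per_half_cycle, base_lr, max_lr, mode) {
  x <- (step - 1) / steps_per_half_cycle
  cycle <- floor(x / 2)
  frac <- 1 - abs(x - 2 * cycle - 1)  # 0 at cycle edges, 1 at mid-cycle
  amp <- if (mode == "Triangular2") 0.5^cycle else 1
  base_lr + (max_lr - base_lr) * frac * amp
}

make_opt_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

opt_step <- function(params, grads, state, lr, cfg,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (cfg$optimizer != "AdamW" && cfg$weight_decay > 0)
      g <- g + cfg$weight_decay * params[[nm]]  # coupled L2
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    if (cfg$optimizer == "NAdam")
      mhat <- beta1 * mhat + (1 - beta1) * g / bc1
    upd <- lr * mhat / (sqrt(state$v[[nm]] / bc2) + eps)
    if (cfg$optimizer == "AdamW" && cfg$weight_decay > 0)
      upd <- upd + lr * cfg$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# row-wise normalization scale (per-spectrum mean intensity; zeros -> 1).
# The mean keeps normalized intensities O(1) across the whole axis, where
# the softplus output head has healthy gradients; max-normalization pushes
# sparse spectra toward the softplus tail and stalls training.
.row_scales <- function(X) {
  s <- rowMeans(X)
  s[!is.finite(s) | s <= 0] <- 1
  s
}

#' Train a U-Net on a set of corruption pairs
#'
#' Core supervised loop: per-spectrum max normalization (input and target
#' share the corrupted spectrum's scale), shuffled minibatches, cyclic
#' learning rate, and the optimizer/loss from `cfg`.  Appends a per-epoch
#' loss record to the model's training log.  A non-finite loss aborts with
#' diagnostics.
#'
#' @param model a `unet_model`.
#' @param pairs a `pair_set` whose spectral length equals the model input
#'   length.
#' @param cfg a [train_config()].
#' @param phase phase label recorded on the result.
#' @return the trained `unet_model`.
#' @export
train_unet <- function(model, pairs, cfg = train_config(), phase = model$phase) {
  stopifnot(inherits(model, "unet_model"), inherits(pairs, "pair_set"))
  if (!is.null(cfg$activation)) model$config$activation <- cfg$activation
  L <- ncol(pairs$corrupted)
  if (L != model$input_length)
    stop_etalon("etalonsim_shape", "pairs length %d != model input length %d",
                L, model$input_length)
  n <- nrow(pairs$corrupted)
  s <- .row_scales(pairs$corrupted)
  Xn <- pairs$corrupted / s
  Yn <- pairs$clean / s
  set.seed(cfg$seed)
  state <- make_opt_state(model$params)
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  half_cycle_steps <- max(1, cfg$half_cycle_epochs * steps_per_epoch)
  step <- 0L
  epoch_losses <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    losses <- numeric(0)
    for (bi in seq_len(steps_per_epoch)) {
      idx <- perm[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      B <- length(idx)
      Xb <- matrix(as.vector(t(Xn[idx, , drop = FALSE])), nrow = 1)
      Tb <- matrix(as.vector(t(Yn[idx, , drop = FALSE])), nrow = 1)
      fw <- unet_forward(model, Xb, L, B, train = TRUE)
      model$bn <- fw$bn
      err <- fw$Y - Tb
      loss <- if (cfg$loss == "mse") mean(err^2) else mean(abs(err))
      if (!is.finite(loss))
        stop_etalon("etalonsim_nan_loss",
                    "non-finite loss at epoch %d step %d (lr %.3g); inputs max %.3g",
                    ep, bi, cyclic_lr(step + 1, half_cycle_steps, cfg$base_lr,
                                      cfg$max_lr, cfg$scheduler), max(Xb))
      dY <- if (cfg$loss == "mse") 2 * err / length(err) else sign(err) / length(err)
      grads <- unet_backward(model, fw$tape, dY)
      if (cfg$clip_norm > 0) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
        if (is.finite(gn) && gn > cfg$clip_norm)
          grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
      }
      step <- step + 1L
      lr <- cyclic_lr(step, half_cycle_steps, cfg$base_lr, cfg$max_lr, cfg$scheduler)
      os <- opt_step(model$params, grads, state, lr, cfg)
      model$params <- os$params
      state <- os$state
      losses <- c(losses, loss)
    }
    epoch_losses <- c(epoch_losses, mean(losses))
  }
  model$training_log <- c(model$training_log,
                          list(list(phase = phase, epochs = cfg$epochs,
                                    loss = epoch_losses, config = unclass(cfg))))
  model$phase <- phase
  model
}

#' Phase I: pretrain on simulated corruption pairs
#'
#' @param model an untrained (or further-trainable) `unet_model`.
#' @param pairs simulated `pair_set` (recipe `A_times`).
#' @param cfg a [train_config()].
#' @return the model with `phase = "pretrained"`.
#' @export
pretrain <- function(model, pairs, cfg = train_config()) {
  if (!identical(pairs$recipe, "A_times"))
    warning("pretraining normally uses recipe 'A_times' pairs")
  train_unet(model, pairs, cfg, phase = "pretrained")
}

#' Phase II: fine-tune a pretrained model on experimental-like pairs
#'
#' All weights are updated (no layer freezing); the parent's provenance is
#' recorded.  `epochs = 0` is a no-op on the weights.
#'
#' @param model a `unet_model` with `phase = "pretrained"`.
#' @param pairs experimental-like `pair_set` (recipe `E_plus_one`).
#' @param cfg a [train_config()].
#' @return the model with `phase = "finetuned"`.
#' @export
finetune <- function(model, pairs, cfg = train_config()) {
  if (!identical(model$phase, "pretrained"))
    stop_etalon("etalonsim_incompatible", "finetune requires a pretrained parent model")
  if (ncol(pairs$corrupted) != model$input_length)
    stop_etalon("etalonsim_incompatible",
                "architecture/input mismatch between parent and fine-tuning pairs")
  parent_info <- list(init_seed = model$init_seed,
                      pre_log = length(model$training_log))
  if (cfg$epochs == 0) {
    model$phase <- "finetuned"
    model$parent <- parent_info
    return(model)
  }
  model <- train_unet(model, pairs, cfg, phase = "finetuned")
  model$parent <- parent_info
  model
}

# reflect-pad a (n x L) matrix to length Lp on the right
.reflect_pad <- function(X, Lp) {
  L <- ncol(X)
  if (Lp == L) return(X)
  extra <- Lp - L
  if (extra > L - 1)
    stop_etalon("etalonsim_shape", "cannot reflect-pad %d to %d points", L, Lp)
  cbind(X, X[, (L - 1):(L - extra), drop = FALSE])
}

#' Correct a corrupted spectrum with a trained model
#'
#' The spectrum is max-normalized, reflect-padded to the model's input
#' length, passed through the network in inference mode, cropped and
#' rescaled.  Outputs are non-negative by the softplus head.  Using an
#' untrained model sets a warning flag in the metadata rather than erroring.
#'
#' @param model a `unet_model`.
#' @param corrupted a `raman_spectrum`, or a numeric matrix with one
#'   spectrum per row (batch mode, order preserved).
#' @return a corrected `raman_spectrum` (or matrix in batch mode).
#' @export
correct <- function(model, corrupted) {
  stopifnot(inherits(model, "unet_model"))
  is_spec <- inherits(corrupted, "raman_spectrum")
  X <- if (is_spec) matrix(corrupted$intensity, 1) else as.matrix(corrupted)
  L <- ncol(X)
  s <- .row_scales(X)
  Xp <- .reflect_pad(X / s, model$input_length)
  Yp <- unet_predict_mat(model, Xp)
  Y <- Yp[, seq_len(L), drop = FALSE] * s
  if (!is_spec) return(Y)
  raman_spectrum(corrupted$shift_cm1, Y[1, ], corrupted$excitation_nm,
                 metadata = list(model_phase = model$phase,
                                 model_seed = model$init_seed,
                                 untrained_warning = model$phase == "untrained"))
}

#' Serialize a trained model to a single-file checkpoint
#' @param model a `unet_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path checkpoint path.
#' @return a `unet_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model"))
    stop_etalon("etalonsim_invalid_argument", "'%s' is not a model checkpoint", path)
  model
}
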