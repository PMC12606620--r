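#' The hyperparameter search space
#'
#' Discrete space over batch size, activation, dropout rates, half-cycle
#' epochs, base/max learning rate, weight decay, scheduler mode and
#' optimizer, matching the documented model-optimization grid.
#'
#' @return named list of candidate value vectors.
#' @export
search_space <- function() {
  list(batch_size = c(64L, 128L, 256L),
       activation = activations(),
       dropout_decoder = c(0, 0.01, 0.1, 0.2),
       dropout_encoder = c(0, 0.01, 0.1, 0.2),
       half_cycle_epochs = c(1L, 2L, 4L),
       base_lr = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7, 1e-8),
       max_lr = c(0.5, 0.1, 0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4, 5e-5),
       weight_decay = c(1e-6, 5e-6, 1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2),
       scheduler = c("Triangular", "Triangular2"),
       optimizer = c("AdamW", "Adam", "NAdam"))
}

# sample one configuration uniformly from the space
.space_sample <- function(space) {
  lapply(space, function(v) v[sample.int(length(v), 1)])
}

# per-dimension categorical densities with Laplace smoothing
.space_density <- function(space, configs) {
  lapply(names(space), function(dim) {
    vals <- vapply(configs, function(cf) match(cf[[dim]], space[[dim]]), integer(1))
    (tabulate(vals, length(space[[dim]])) + 1) /
      (length(vals) + length(space[[dim]]))
  })
}

#' Tree-structured Parzen estimator search with successive-halving pruning
#'
#' Minimizes `objective(config, prune)` over a discrete space.  The first
#' `n_startup` trials are uniform random; afterwards the observed trials are
#' split at the `gamma` quantile into good (l) and bad (g) sets, candidate
#' configurations are drawn from the good-set density and the one maximizing
#' `l(x)/g(x)` is evaluated (per-dimension independent categorical Parzen
#' estimators).  The objective may report intermediate values through
#' `prune(step, value)`; a trial whose intermediate value is worse than the
#' median of previously recorded values at the same rung is told to stop
#' (Hyperband-style early termination), and its last value is used.
#'
#' @param objective `function(config, prune) -> numeric` loss to minimize.
#'   `prune` is `function(step, value) -> logical` (TRUE = stop early).
#' @param space named list of discrete candidate vectors (default
#'   [search_space()]).
#' @param budget total number of trials, >= 1.
#' @param seed integer seed.
#' @param n_startup random trials before TPE kicks in (default 10).
#' @param gamma top quantile regarded as "good" (default 0.25).
#' @param n_candidates candidate draws per TPE step (default 24).
#' @return list with `best_config`, `best_value` and the full `trials`
#'   history (config, value, pruned flag per trial).
#' @export
search_hyperparameters <- function(objective, space = search_space(), budget,
                                   seed = 1, n_startup = 10, gamma = 0.25,
                                   n_candidates = 24) {
  stopifnot(budget >= 1)
  set.seed(as.integer(seed))
  trials <- list()
  rungs <- list()  # step label -> recorded intermediate values
  for (trial_i in seq_len(budget)) {
    cfg <- if (trial_i <= n_startup || length(trials) < 2) {
      .space_sample(space)
    } else {
      vals <- vapply(trials, `[[`, numeric(1), "value")
      n_good <- max(1L, ceiling(gamma * length(vals)))
      ord <- order(vals)
      good <- lapply(trials[ord[seq_len(n_good)]], `[[`, "config")
      bad <- lapply(trials[ord[-seq_len(n_good)]], `[[`, "config")
      dl <- .space_density(space, good)
      dg <- .space_density(space, if (length(bad)) bad else good)
      cands <- replicate(n_candidates, {
        cf <- lapply(seq_along(space), function(d)
          space[[d]][sample.int(length(space[[d]]), 1, prob = dl[[d]])])
        names(cf) <- names(space)
        cf
      }, simplify = FALSE)
      scores <- vapply(cands, function(cf) {
        sum(vapply(seq_along(space), function(d) {
          i <- match(cf[[d]], space[[d]])
          log(dl[[d]][i]) - log(dg[[d]][i])
        }, numeric(1)))
      }, numeric(1))
      cands[[which.max(scores)]]
    }
    pruned <- FALSE
    prune <- function(step, value) {
      key <- as.character(step)
      seen <- rungs[[key]] %||% numeric(0)
      rungs[[key]] <<- c(seen, value)
      stop_now <- length(seen) >= 3 && value > stats::median(seen)
      if (stop_now) pruned <<- TRUE
      stop_now
    }
    value <- objective(cfg, prune)
    trials[[trial_i]] <- list(config = cfg, value = value, pruned = pruned)
  }
  vals <- vapply(trials, `[[`, numeric(1), "value")
  if (all(vapply(trials, `[[`, logical(1), "pruned")))
    warning("all trials were pruned; returning best-so-far")
  best <- which.min(vals)
  list(best_config = trials[[best]]$config, best_value = vals[best],
       trials = trials)
}
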