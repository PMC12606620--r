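# shared internal helpers

stop_etalon <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "etalonsim_error", "error", "condition")))
}

# deterministic child seed from a master seed and an operation label;
# result stays below 2^31 - 1 so it is a valid R integer seed
derive_seed <- function(master, label) {
  s <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(label)) s <- (s * 31 + c) %% 2147483647
  as.integer(s)
}

# local maxima of a numeric vector (strict rise, non-strict fall)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
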