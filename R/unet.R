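#' Architecture settings for the 1D U-Net
#'
#' Five-level encoder (channels strictly doubling, default
#' 32-64-128-256-512) with a 1024-channel bottleneck, 2x max-pool
#' downsampling, a transposed-convolution decoder with skip concatenation
#' from the matching encoder level, and a 1x1 output convolution followed by
#' softplus so outputs are non-negative.  All convolutions use the same
#' fixed odd kernel length (default 9, several sampling intervals at
#' 1 cm^-1 resolution).  Input length must be divisible by `2^levels`
#' (callers pad by reflection, see [correct()]).
#'
#' @param channels strictly doubling encoder channel counts.
#' @param bottleneck bottleneck channels (= 2x last encoder level).
#' @param kernel odd convolution kernel length.
#' @param activation one of [activations()].
#' @param dropout_encoder,dropout_decoder dropout rates.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(channels = c(32, 64, 128, 256, 512),
                        bottleneck = 1024, kernel = 9, activation = "gelu",
                        dropout_encoder = 0, dropout_decoder = 0) {
  channels <- as.integer(channels)
  if (length(channels) < 1 || any(channels < 1))
    stop_etalon("etalonsim_config", "need at least one positive channel count")
  if (length(channels) > 1 && any(channels[-1] != 2L * channels[-length(channels)]))
    stop_etalon("etalonsim_config", "encoder channels must strictly double")
  if (bottleneck != 2L * channels[length(channels)])
    stop_etalon("etalonsim_config", "bottleneck must double the last encoder level")
  if (kernel %% 2 == 0) stop_etalon("etalonsim_config", "kernel length must be odd")
  if (!activation %in% activations())
    stop_etalon("etalonsim_config", "unknown activation '%s'", activation)
  structure(list(channels = channels, bottleneck = as.integer(bottleneck),
                 kernel = as.integer(kernel), levels = length(channels),
                 activation = activation,
                 dropout_encoder = dropout_encoder,
                 dropout_decoder = dropout_decoder),
            class = "unet_config")
}

#' Build an (untrained) U-Net model
#'
#' Weights are He-initialized from the given seed; two builds with the same
#' config and seed are identical.
#'
#' @param config a [unet_config()].
#' @param input_length spectral length the model will be trained on; must be
#'   divisible by `2^levels`.
#' @param seed integer seed for weight initialization.
#' @return an object of class `unet_model` with `phase = "untrained"`.
#' @export
build_unet <- function(config = unet_config(), input_length = 3712, seed = 1) {
  stopifnot(inherits(config, "unet_config"))
  if (input_length %% 2^config$levels != 0)
    stop_etalon("etalonsim_shape", "input length %d not divisible by %d",
                input_length, 2^config$levels)
  set.seed(as.integer(seed))
  ch <- config$channels; k <- config$kernel; nl <- config$levels
  params <- list(); bn <- list()
  add_conv <- function(nm, cin, cout, kk = k) {
    cv <- conv_init(cin, cout, kk)
    params[[paste0(nm, "_W")]] <<- cv$W
    params[[paste0(nm, "_b")]] <<- cv$b
  }
  add_bn <- function(nm, c) {
    params[[paste0(nm, "_g")]] <<- rep(1, c)
    params[[paste0(nm, "_beta")]] <<- rep(0, c)
    bn[[nm]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  cin <- 1L
  for (l in seq_len(nl)) {
    add_conv(sprintf("e%d_c1", l), cin, ch[l]); add_bn(sprintf("e%d_bn1", l), ch[l])
    add_conv(sprintf("e%d_c2", l), ch[l], ch[l]); add_bn(sprintf("e%d_bn2", l), ch[l])
    cin <- ch[l]
  }
  cb <- config$bottleneck
  add_conv("bo_c1", ch[nl], cb); add_bn("bo_bn1", cb)
  add_conv("bo_c2", cb, cb); add_bn("bo_bn2", cb)
  prev <- cb
  for (l in rev(seq_len(nl))) {
    up <- upconv_init(prev, ch[l])
    params[[sprintf("d%d_up_W", l)]] <- up$W
    params[[sprintf("d%d_up_b", l)]] <- up$b
    add_conv(sprintf("d%d_c1", l), 2L * ch[l], ch[l]); add_bn(sprintf("d%d_bn1", l), ch[l])
    add_conv(sprintf("d%d_c2", l), ch[l], ch[l]); add_bn(sprintf("d%d_bn2", l), ch[l])
    prev <- ch[l]
  }
  add_conv("out", ch[1], 1L, 1L)
  structure(list(config = config, input_length = as.integer(input_length),
                 params = params, bn = bn, phase = "untrained",
                 training_log = list(), parent = NULL, init_seed = seed),
            class = "unet_model")
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %d levels (%s | %d), kernel %d, %s, input %d, %s, %s params\n",
              x$config$levels, paste(x$config$channels, collapse = "-"),
              x$config$bottleneck, x$config$kernel, x$config$activation,
              x$input_length, x$phase, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# forward pass; X is (1 x L*B).  Returns output (1 x L*B), a tape for
# backprop, and (in training mode) updated batch-norm running stats.
unet_forward <- function(model, X, L, B, train = TRUE) {
  cfg <- model$config; P <- model$params; act <- cfg$activation
  tape <- list(); ti <- 0L
  push <- function(e) { ti <<- ti + 1L; tape[[ti]] <<- e }
  bnrun <- model$bn

  conv_block <- function(cur, nm_c, nm_bn, L, B, drop) {
    cv <- conv_fwd(cur, P[[paste0(nm_c, "_W")]], P[[paste0(nm_c, "_b")]], L, B)
    push(list(kind = "conv", nm = nm_c, col = cv$col, L = L, B = B,
              need_dx = nm_c != "e1_c1"))
    bo <- bn_fwd(cv$Y, P[[paste0(nm_bn, "_g")]], P[[paste0(nm_bn, "_beta")]],
                 bnrun[[nm_bn]], train)
    bnrun[[nm_bn]] <<- bo$run
    push(list(kind = "bn", nm = nm_bn, cache = bo$cache))
    av <- act_fwd(act, bo$Y, train)
    push(list(kind = "act", d = av$d))
    if (drop > 0 && train) {
      dv <- dropout_fwd(av$Y, drop, train)
      push(list(kind = "drop", mask = dv$mask))
      dv$Y
    } else av$Y
  }

  cur <- X; curL <- L
  skips <- list(); skipL <- integer(0)
  for (l in seq_len(cfg$levels)) {
    cur <- conv_block(cur, sprintf("e%d_c1", l), sprintf("e%d_bn1", l), curL, B,
                      cfg$dropout_encoder)
    cur <- conv_block(cur, sprintf("e%d_c2", l), sprintf("e%d_bn2", l), curL, B,
                      cfg$dropout_encoder)
    skips[[l]] <- cur; skipL[l] <- curL
    mp <- maxpool_fwd(cur, curL, B)
    push(list(kind = "pool", cache = mp, ncol_in = ncol(cur)))
    cur <- mp$Y; curL <- curL %/% 2L
  }
  cur <- conv_block(cur, "bo_c1", "bo_bn1", curL, B, 0)
  cur <- conv_block(cur, "bo_c2", "bo_bn2", curL, B, 0)
  for (l in rev(seq_len(cfg$levels))) {
    nm <- sprintf("d%d_up", l)
    uv <- upconv_fwd(cur, P[[paste0(nm, "_W")]], P[[paste0(nm, "_b")]], curL, B)
    push(list(kind = "up", nm = nm, X = cur, o = uv$o))
    curL <- curL * 2L
    cur <- rbind(uv$Y, skips[[l]])
    push(list(kind = "concat", n_top = nrow(uv$Y)))
    cur <- conv_block(cur, sprintf("d%d_c1", l), sprintf("d%d_bn1", l), curL, B,
                      cfg$dropout_decoder)
    cur <- conv_block(cur, sprintf("d%d_c2", l), sprintf("d%d_bn2", l), curL, B,
                      cfg$dropout_decoder)
  }
  cv <- conv_fwd(cur, P[["out_W"]], P[["out_b"]], curL, B)
  push(list(kind = "conv", nm = "out", col = cv$col, L = curL, B = B,
            need_dx = TRUE))
  sp <- softplus_fwd(cv$Y)
  push(list(kind = "softplus", d = sp$d))
  list(Y = sp$Y, tape = tape, bn = bnrun)
}

# backprop through a recorded tape; skip-connection gradients re-enter the
# encoder stream at the matching pool entry
unet_backward <- function(model, tape, dY) {
  P <- model$params
  grads <- list()
  skip_grad <- list()  # gradients waiting to be added at encoder outputs
  dcur <- dY
  for (i in rev(seq_along(tape))) {
    e <- tape[[i]]
    dcur <- switch(e$kind,
      softplus = dcur * e$d,
      act = dcur * e$d,
      drop = dcur * e$mask,
      conv = {
        g <- conv_bwd(dcur, P[[paste0(e$nm, "_W")]], e$col, e$L, e$B, e$need_dx)
        grads[[paste0(e$nm, "_W")]] <- g$dW
        grads[[paste0(e$nm, "_b")]] <- g$db
        g$dX
      },
      bn = {
        g <- bn_bwd(dcur, e$cache)
        grads[[paste0(e$nm, "_g")]] <- g$dg
        grads[[paste0(e$nm, "_beta")]] <- g$db
        g$dX
      },
      pool = {
        d <- maxpool_bwd(dcur, e$cache, e$ncol_in)
        lev <- length(skip_grad)
        if (lev > 0 && !is.null(skip_grad[[lev]])) {
          d <- d + skip_grad[[lev]]
          skip_grad[[lev]] <- NULL
        }
        d
      },
      concat = {
        top <- dcur[seq_len(e$n_top), , drop = FALSE]
        skip_grad[[length(skip_grad) + 1L]] <- dcur[-seq_len(e$n_top), , drop = FALSE]
        top
      },
      up = {
        g <- upconv_bwd(dcur, P[[paste0(e$nm, "_W")]], e$X, e$o)
        grads[[paste0(e$nm, "_W")]] <- g$dW
        grads[[paste0(e$nm, "_b")]] <- g$db
        g$dX
      },
      stop("unknown tape entry"))
  }
  grads
}

# batched inference on an (n x L) matrix of already-normalized spectra;
# L must equal model$input_length
unet_predict_mat <- function(model, X, batch = 64L) {
  n <- nrow(X); L <- ncol(X)
  if (L != model$input_length)
    stop_etalon("etalonsim_shape", "input length %d != model input length %d",
                L, model$input_length)
  out <- matrix(0, n, L)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch - 1L, n)
    Xb <- matrix(as.vector(t(X[idx, , drop = FALSE])), nrow = 1)
    fw <- unet_forward(model, Xb, L, length(idx), train = FALSE)
    out[idx, ] <- matrix(fw$Y, nrow = length(idx), byrow = TRUE)
    i <- i + batch
  }
  out
}
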