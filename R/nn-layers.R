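# Primitive differentiable layers for the 1D encoder-decoder network.
#
# Activations live in matrices of shape (channels x L*B): each of the B
# samples in a batch occupies a contiguous block of L columns.  The
# convolution forward/backward passes and the GELU activation are compiled
# (src/nn_ops.cpp); everything else is base R on BLAS.

conv_init <- function(cin, cout, k) {
  list(W = array(stats::rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))),
                 dim = c(cout, cin, k)),
       b = rep(0, cout))
}

# convolutions run in compiled code (src/nn_ops.cpp); the input matrix is
# kept on the tape for the weight-gradient GEMMs
conv_fwd <- function(X, W, b, L, B) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  list(Y = conv1d_fwd_cpp(X, W, b, L, B), col = X)
}

conv_bwd <- function(dY, W, X, L, B, need_dx = TRUE) {
  g <- conv1d_bwd_cpp(dY, W, X, L, B, need_dx)
  list(dX = if (need_dx) g$dX else NULL, dW = g$dW, db = as.vector(g$db))
}

bn_fwd <- function(X, g, b, run, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    st <- row_stats_cpp(X)
    mu <- as.vector(st$mean)
    v <- as.vector(st$var)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean; v <- run$var
  }
  invsd <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * invsd
  list(Y = g * xhat + b, cache = list(xhat = xhat, invsd = invsd, g = g),
       run = run)
}

bn_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  m1 <- rowMeans(dY)
  m2 <- rowMeans(dY * xhat)
  list(dX = cache$g * cache$invsd * (dY - m1 - xhat * m2),
       dg = rowSums(dY * xhat), db = rowSums(dY))
}

# each activation returns the output and the elementwise derivative matrix
act_fwd <- function(name, X, train = TRUE) {
  switch(name,
    relu = { m <- X > 0; list(Y = X * m, d = m * 1) },
    relu6 = { Y <- pmin(pmax(X, 0), 6); list(Y = Y, d = (X > 0 & X < 6) * 1) },
    leaky_relu = { m <- X > 0; list(Y = ifelse(m, X, 0.01 * X), d = ifelse(m, 1, 0.01)) },
    prelu = { m <- X > 0; list(Y = ifelse(m, X, 0.25 * X), d = ifelse(m, 1, 0.25)) },
    elu = ,
    celu = { m <- X > 0; e <- exp(pmin(X, 0))
             list(Y = ifelse(m, X, e - 1), d = ifelse(m, 1, e)) },
    selu = { la <- 1.0507009873554805; al <- 1.6732632423543772
             m <- X > 0; e <- exp(pmin(X, 0))
             list(Y = la * ifelse(m, X, al * (e - 1)), d = la * ifelse(m, 1, al * e)) },
    gelu = gelu_cpp(X),  # tanh approximation, compiled
    swish = { s <- stats::plogis(X)
              list(Y = X * s, d = s * (1 + X * (1 - s)) ) },
    rrelu = { lo <- 1 / 8; hi <- 1 / 3
              a <- if (train) matrix(stats::runif(length(X), lo, hi), nrow(X))
                   else (lo + hi) / 2
              m <- X > 0; list(Y = ifelse(m, X, a * X), d = ifelse(m, 1, a)) },
    stop_etalon("etalonsim_invalid_argument", "unknown activation '%s'", name))
}

#' Supported activation functions
#' @return character vector of activation names.
#' @export
activations <- function() c("relu", "elu", "leaky_relu", "selu", "gelu", "celu",
                            "swish", "prelu", "relu6", "rrelu")

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) > rate) / (1 - rate), nrow(X))
  list(Y = X * mask, mask = mask)
}

maxpool_fwd <- function(X, L, B) {
  o <- seq.int(1L, L * B, 2L)  # valid because L is even and blocks contiguous
  A <- X[, o, drop = FALSE]
  Bv <- X[, o + 1L, drop = FALSE]
  m <- A >= Bv
  list(Y = A * m + Bv * !m, mask = m, o = o)
}

maxpool_bwd <- function(dY, cache, ncol_in) {
  dX <- matrix(0, nrow(dY), ncol_in)
  dX[, cache$o] <- dY * cache$mask
  dX[, cache$o + 1L] <- dY * !cache$mask
  dX
}

# both output phases start with identical weights so the transposed
# convolution begins as a smooth (nearest-neighbour) upsampler; independent
# slices imprint a 2-sample checkerboard on the decoded spectrum that takes
# many steps to unlearn
upconv_init <- function(cin, cout) {
  W1 <- matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin)
  list(W = array(c(W1, W1), dim = c(cout, cin, 2)), b = rep(0, cout))
}

upconv_fwd <- function(X, W, b, Lh, B) {
  o <- seq.int(1L, 2L * Lh * B, 2L)
  Y <- matrix(0, dim(W)[1], 2L * Lh * B)
  Y[, o] <- W[, , 1] %*% X
  Y[, o + 1L] <- W[, , 2] %*% X
  list(Y = Y + b, o = o)
}

upconv_bwd <- function(dY, W, X, o) {
  dYo <- dY[, o, drop = FALSE]
  dYe <- dY[, o + 1L, drop = FALSE]
  dW <- array(0, dim = dim(W))
  dW[, , 1] <- tcrossprod(dYo, X)
  dW[, , 2] <- tcrossprod(dYe, X)
  list(dX = crossprod(W[, , 1], dYo) + crossprod(W[, , 2], dYe),
       dW = dW, db = rowSums(dY))
}

softplus_fwd <- function(X) {
  list(Y = ifelse(X > 30, X, log1p(exp(pmin(X, 30)))), d = stats::plogis(X))
}
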