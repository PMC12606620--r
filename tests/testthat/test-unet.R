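# Network: shape contracts, determinism, gradients, learning behaviour.

test_that("configuration invariants are enforced", {
  expect_error(unet_config(channels = c(32, 50)), class = "etalonsim_config")
  expect_error(unet_config(bottleneck = 100), class = "etalonsim_config")
  expect_error(unet_config(kernel = 8), class = "etalonsim_config")
  expect_error(unet_config(activation = "tanhx"), class = "etalonsim_config")
  expect_error(build_unet(unet_config(channels = c(4, 8), bottleneck = 16),
                          input_length = 33), class = "etalonsim_shape")
})

test_that("builds are deterministic and outputs respect the shape contract", {
  m1 <- tiny_unet(seed = 5); m2 <- tiny_unet(seed = 5)
  expect_identical(m1$params, m2$params)
  expect_equal(n_parameters(m1), n_parameters(m2))
  # default-architecture parameter count is stable for a given config
  X <- matrix(runif(64 * 3), 1)
  fw <- unet_forward(m1, X, 64, 3, train = FALSE)
  expect_equal(dim(fw$Y), c(1, 64 * 3))
  expect_true(all(fw$Y >= 0))  # softplus head
})

test_that("backpropagation matches central finite differences", {
  set.seed(42)
  m <- tiny_unet(L = 32, seed = 3)
  L <- 32; B <- 2
  X <- matrix(runif(L * B), 1); Tm <- matrix(runif(L * B), 1)
  fw <- unet_forward(m, X, L, B, train = TRUE)
  gr <- unet_backward(m, fw$tape, 2 * (fw$Y - Tm) / length(Tm))
  # skip conv biases directly upstream of batch norm: their exact gradient
  # is 0 (the mean is subtracted), so relative error is meaningless
  check <- c("e1_c1_W", "e2_c2_W", "bo_c1_W", "d2_up_W", "d1_c2_W", "out_W",
             "out_b", "e1_bn1_g", "d2_bn2_beta", "d1_up_b")
  for (nm in check) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      h <- 1e-6
      m2 <- m; m2$params[[nm]][i] <- p[i] + h
      lp <- mean((unet_forward(m2, X, L, B, TRUE)$Y - Tm)^2)
      m2$params[[nm]][i] <- p[i] - h
      lm <- mean((unet_forward(m2, X, L, B, TRUE)$Y - Tm)^2)
      num <- (lp - lm) / (2 * h)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("every activation in the search space runs forward and backward", {
  L <- 32; B <- 2
  X <- matrix(rnorm(L * B), 4)
  for (a in activations()) {
    set.seed(1)
    f <- act_fwd(a, X, train = TRUE)
    expect_equal(dim(f$Y), dim(X))
    # derivative sanity at a few points (rrelu is stochastic in training;
    # re-seed so the sampled slopes match)
    set.seed(1)
    h <- 1e-6
    num <- (act_fwd(a, X + h, TRUE)$Y - { set.seed(1); act_fwd(a, X - h, TRUE)$Y }) / (2 * h)
    set.seed(1)
    d <- act_fwd(a, X, TRUE)$d
    expect_lt(stats::median(abs(num - d)), 1e-5)
  }
})

test_that("a small net overfits a small set (capacity check)", {
  m <- tiny_unet(L = 64, seed = 2)
  ps <- random_pair_set(16, 64, seed = 4)
  cfg <- train_config(batch_size = 16, epochs = 1000, base_lr = 1e-3,
                      max_lr = 1e-2, weight_decay = 0, half_cycle_epochs = 100,
                      seed = 7)
  mt <- train_unet(m, ps, cfg)
  lg <- mt$training_log[[1]]$loss
  expect_lt(lg[length(lg)], 0.01 * lg[1])
})

test_that("identity corruption is learnable to a tight floor", {
  set.seed(8)
  X <- matrix(runif(24 * 64), 24)
  ps <- structure(list(axis = 1:64, clean = X, corrupted = X,
                       design_id = rep(1L, 24), recipe = "A_times", seed = 1),
                  class = "pair_set")
  m <- tiny_unet(L = 64, seed = 2)
  mt <- train_unet(m, ps, train_config(batch_size = 24, epochs = 300,
                                       base_lr = 1e-3, max_lr = 1e-2,
                                       weight_decay = 0,
                                       half_cycle_epochs = 50, seed = 3))
  out <- correct(mt, X)
  expect_lt(sqrt(mean((out - X)^2)), 0.05)
})

test_that("training is reproducible for a fixed seed", {
  ps <- random_pair_set(8, 32, seed = 2)
  cfg <- train_config(batch_size = 4, epochs = 3, seed = 11)
  m1 <- train_unet(tiny_unet(L = 32, seed = 1), ps, cfg)
  m2 <- train_unet(tiny_unet(L = 32, seed = 1), ps, cfg)
  expect_identical(m1$training_log[[1]]$loss, m2$training_log[[1]]$loss)
  expect_identical(m1$params, m2$params)
})

test_that("fine-tuning requires a pretrained parent; 0 epochs is a no-op", {
  ps <- random_pair_set(8, 32, seed = 2, recipe = "E_plus_one")
  fresh <- tiny_unet(L = 32, seed = 1)
  expect_error(finetune(fresh, ps), class = "etalonsim_incompatible")
  pre <- train_unet(fresh, random_pair_set(8, 32, 3),
                    train_config(batch_size = 8, epochs = 2, seed = 5),
                    phase = "pretrained")
  ft0 <- finetune(pre, ps, train_config(epochs = 0))
  expect_identical(ft0$params, pre$params)
  expect_equal(ft0$phase, "finetuned")
  # architecture mismatch between parent and pairs
  long_pairs <- random_pair_set(4, 64, 1, recipe = "E_plus_one")
  expect_error(finetune(pre, long_pairs), class = "etalonsim_incompatible")
})

test_that("correct() pads, crops, rescales and preserves batch order", {
  m <- tiny_unet(L = 64, seed = 6)
  sp <- broaden(sample_peaklist(4), default_axis(50))
  out <- correct(m, sp)
  expect_s3_class(out, "raman_spectrum")
  expect_length(out$intensity, 50)
  expect_true(all(out$intensity >= 0))
  expect_true(out$metadata$untrained_warning)
  # batch mode preserves order
  X <- matrix(runif(3 * 50), 3)
  Y <- correct(m, X)
  expect_equal(dim(Y), c(3, 50))
  for (i in 1:3) expect_equal(Y[i, ], correct(m, X[i, , drop = FALSE])[1, ],
                              tolerance = 1e-12)
})

test_that("checkpoints round-trip exactly", {
  m <- train_unet(tiny_unet(L = 32, seed = 1), random_pair_set(6, 32, 2),
                  train_config(batch_size = 6, epochs = 2, seed = 3))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  X <- matrix(runif(2 * 32), 2)
  expect_identical(correct(m, X), correct(m2, X))
})

test_that("a non-finite loss aborts with diagnostics", {
  ps <- random_pair_set(8, 32, seed = 2)
  ps$corrupted[1, 1] <- Inf
  expect_error(
    train_unet(tiny_unet(L = 32, seed = 1), ps,
               train_config(batch_size = 8, epochs = 1, seed = 1)),
    class = "etalonsim_nan_loss")
})
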