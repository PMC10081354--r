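test_that("mspdnn_config presets resolve and validate", {
  cfg <- mspdnn_config()
  expect_s3_class(cfg, "mspdnn_config")
  expect_equal(cfg$max_epochs, 100L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$lr_decay, 0.8)
  expect_equal(cfg$decay_every, 50L)
  expect_equal(cfg$tol, 1e-4)
  expect_false(cfg$polish)
  acc <- mspdnn_config(preset = "accurate")
  expect_true(acc$polish)
  expect_gt(acc$lr, cfg$lr)
  # explicit arguments override the preset
  expect_equal(mspdnn_config(preset = "accurate", lr = 0.5)$lr, 0.5)
  expect_error(mspdnn_config(lr = -1))
  expect_error(mspdnn_config(lr_decay = 1.5))
  expect_error(mspdnn_config(batch = "minibatch"))
})

test_that("the bilinear transform is the symmetric congruence V Gamma V", {
  W <- diag(c(1, 2))
  G <- diag(c(3, 5))
  # V = W W^T = diag(1, 4); V G V = diag(3, 80)
  expect_equal(mspdnn_transform(W, G), diag(c(3, 80)))
  # ridge enters as W~ = W + lambda I
  Wl <- W + 0.5 * diag(2)
  expect_equal(mspdnn_transform(W, G, lambda = 0.5),
               mspdnn_transform(Wl, G, lambda = 0))
  set.seed(201)
  Wr <- matrix(rnorm(9), 3, 3)
  Gr <- rspd(3)
  out <- mspdnn_transform(Wr, Gr)
  expect_equal(out, t(out))  # symmetric by construction
  expect_true(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) > 0)
  expect_error(mspdnn_transform(matrix(1, 2, 3), Gr), "square")
  expect_error(mspdnn_transform(diag(2), Gr), "mismatch")
})

test_that("the matrix-normal loss matches its closed form and vanishes at the mean", {
  gs <- list(diag(c(1, 4)), diag(c(4, 1)))
  # V = diag(1/2): residual diag(-log 2, -log 2), loss = (log 2)^2 / 2
  expect_equal(mspdnn_loss(diag(1 / sqrt(2), 2), gs), log(2)^2 / 2,
               tolerance = 1e-12)
  # V = G^{-1/2} = diag(1/sqrt(2)) is the exact optimum (mean diag(2, 2))
  expect_equal(mspdnn_loss(diag(2^(-1 / 4), 2), gs), 0, tolerance = 1e-15)
  expect_gte(mspdnn_loss(matrix(c(1, 0.2, 0.2, 1), 2, 2), gs), 0)
  expect_error(mspdnn_loss(diag(3), gs), "2 x 2")
  # weighted collection: optimum shifts to the weighted geometric mean
  coll <- connectome_collection(gs, weights = c(3, 1))
  gm <- diag(c(exp(0.75 * log(1) + 0.25 * log(4)),
               exp(0.75 * log(4) + 0.25 * log(1))))
  expect_equal(mspdnn_loss(spd_power(gm, -0.25), coll), 0, tolerance = 1e-14)
})

test_that("condition_fit is an estimator-agnostic stationarity residual", {
  expect_equal(condition_fit(diag(2), list(diag(exp(1), 2), diag(exp(1), 2))),
               0.5, tolerance = 1e-12)
  set.seed(202)
  gs <- replicate(4, rspd(3), simplify = FALSE)
  gd <- gradient_descent_mean(gs, tol = 1e-14)
  expect_lt(condition_fit(gd$mean, gs), 1e-20)
  # strictly positive away from the mean
  expect_gt(condition_fit(diag(3), gs), 1e-6)
  expect_error(condition_fit(diag(4), gs), "mismatch")
})

test_that("mspdnn_fit recovers the geodesic mean of a pair", {
  set.seed(203)
  A <- rspd(3)
  B <- rspd(3)
  mid <- geodesic_midpoint(A, B)
  fit <- mspdnn_fit(list(A, B), acc_cfg(1))
  expect_s3_class(fit, "mean_estimate")
  expect_equal(fit$method, "mspdnn")
  expect_lt(geodesic_distance(fit$mean, mid), 1e-6)
  expect_lt(fit$condition_fit, 1e-12)
  expect_true(fit$converged)
  tr <- fit$loss_trace
  expect_lt(tr[length(tr)], tr[1])  # training actually reduced the loss
})

test_that("mspdnn_fit is deterministic given init_seed and honors weights", {
  set.seed(204)
  gs <- replicate(3, rspd(2), simplify = FALSE)
  f1 <- mspdnn_fit(gs, acc_cfg(7))
  f2 <- mspdnn_fit(gs, acc_cfg(7))
  expect_identical(f1$mean, f2$mean)
  f3 <- mspdnn_fit(gs, acc_cfg(8))
  expect_false(identical(f1$mean, f3$mean))  # different start
  expect_lt(geodesic_distance(f1$mean, f3$mean), 1e-6)  # same optimum
  # integer weights match sample replication
  wfit <- mspdnn_fit(connectome_collection(gs[1:2], weights = c(2, 1)),
                     acc_cfg(7))
  rfit <- mspdnn_fit(list(gs[[1]], gs[[1]], gs[[2]]), acc_cfg(7))
  expect_lt(geodesic_distance(wfit$mean, rfit$mean), 1e-6)
})

test_that("mspdnn_fit leaves the caller's RNG stream untouched", {
  set.seed(205)
  gs <- replicate(2, rspd(2), simplify = FALSE)
  set.seed(99)
  a <- rnorm(3)
  set.seed(99)
  invisible(mspdnn_fit(gs, mspdnn_config(max_epochs = 5)))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("full-batch mode optimizes the same objective, order-invariantly", {
  set.seed(206)
  gs <- replicate(4, rspd(2), simplify = FALSE)
  cfg <- mspdnn_config(preset = "accurate", batch = "full", init_seed = 3)
  f <- mspdnn_fit(gs, cfg)
  expect_lt(f$condition_fit, 1e-12)
  # reordering only changes floating-point summation order
  g <- mspdnn_fit(gs[c(3, 1, 4, 2)], cfg)
  expect_lt(geodesic_distance(f$mean, g$mean), 1e-10)
})
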