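test_that("normalized_recovery_error matches its closed form", {
  # delta(I, diag(e,e))^2 = 2; ||diag(e,e)||_R^2 = 2 -> error 1
  expect_equal(normalized_recovery_error(diag(2), diag(exp(1), 2)), 1,
               tolerance = 1e-12)
  G <- diag(c(exp(2), exp(2)))
  expect_equal(normalized_recovery_error(G, G), 0, tolerance = 1e-15)
  expect_error(normalized_recovery_error(diag(2), diag(2)), "identity")
})

test_that("the scalability experiment records a full, tidy grid", {
  res <- run_scalability_experiment(vary = "N", values = c(3, 5), P_fixed = 4,
                                    n_replicates = 2,
                                    methods = c("gradient_descent", "ale"),
                                    seed = 5)
  expect_s3_class(res, "data.frame")
  expect_equal(nrow(res), 2 * 2 * 2)  # cells x replicates x methods
  expect_setequal(res$N, c(3, 5))
  expect_true(all(res$P == 4))
  expect_true(all(res$sigma == 0))
  expect_true(all(is.finite(res$condition_fit)))
  expect_true(all(is.finite(res$d_mean)))
  expect_true(all(res$runtime_seconds >= 0))
  # noiseless CPC: both classical estimators essentially recover the truth
  expect_lt(max(res$d_mean), 1e-6)
  # deterministic in the seed
  res2 <- run_scalability_experiment(vary = "N", values = c(3, 5), P_fixed = 4,
                                     n_replicates = 2,
                                     methods = c("gradient_descent", "ale"),
                                     seed = 5)
  expect_identical(res[setdiff(names(res), "runtime_seconds")],
                   res2[setdiff(names(res2), "runtime_seconds")])
  # vary = "P" varies the dimension instead
  resp <- run_scalability_experiment(vary = "P", values = c(3, 4), N_fixed = 3,
                                     n_replicates = 1, methods = "ale",
                                     seed = 5)
  expect_setequal(resp$P, c(3, 4))
  expect_true(all(resp$N == 3))
})

test_that("vary_across controls which factors change per replicate", {
  fixed_data <- run_scalability_experiment(vary = "N", values = 4, P_fixed = 3,
                                           n_replicates = 3, methods = "ale",
                                           seed = 9, vary_across = "init")
  expect_equal(length(unique(fixed_data$replicate_seed)), 1)
  both <- run_scalability_experiment(vary = "N", values = 4, P_fixed = 3,
                                     n_replicates = 3, methods = "ale",
                                     seed = 9, vary_across = "both")
  expect_equal(length(unique(both$replicate_seed)), 3)
})

test_that("the noise experiment sweeps sigma and never aborts on a fit", {
  res <- run_noise_experiment(P = 4, N = 5, sigma_grid = c(0, 0.5),
                              n_replicates = 2,
                              methods = c("gradient_descent", "ale"), seed = 3)
  expect_equal(nrow(res), 2 * 2 * 2)
  expect_setequal(res$sigma, c(0, 0.5))
  expect_true(all(is.na(res$d_mean)))  # no closed-form mean under noise
  expect_true(all(is.finite(res$condition_fit)))
  # gradient descent stays stationary under noise; ALE degrades
  gd <- res[res$method == "gradient_descent" & res$sigma == 0.5, ]
  al <- res[res$method == "ale" & res$sigma == 0.5, ]
  expect_lt(max(gd$condition_fit), 1e-12)
  expect_gt(min(al$condition_fit), 1e-12)
  expect_error(run_noise_experiment(P = 3, N = 3, sigma_grid = -0.1,
                                    n_replicates = 1, methods = "ale"))
})

test_that("initialization_concordance returns a symmetric distance matrix", {
  set.seed(401)
  gs <- replicate(3, rspd(3), simplify = FALSE)
  fits <- lapply(1:3, function(s) mspdnn_fit(gs, acc_cfg(s)))
  D <- initialization_concordance(fits)
  expect_equal(dim(D), c(3, 3))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_lt(max(D), 1e-6)  # all seeds reach the same optimum
  # plain matrices are accepted too, and real separation is reported
  D2 <- initialization_concordance(list(diag(2), diag(exp(1), 2)))
  expect_equal(D2[1, 2], sqrt(2), tolerance = 1e-10)
  expect_error(initialization_concordance(fits[1]), "at least two")
  expect_error(initialization_concordance(list(diag(2), diag(3))), "mismatch")
})
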