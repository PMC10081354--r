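#' Normalized recovery error against a reference mean
#'
#' \eqn{d_{mean} = \delta_R^2(G_{est}, G^*) / \|G^*\|_R^2}: the squared
#' geodesic distance to the reference, normalized by the reference's squared
#' Riemannian norm.
#'
#' @param G_est estimated SPD mean.
#' @param G_star reference SPD mean (for CPC data, [theoretical_cpc_mean()]).
#' @return nonnegative scalar.
#' @export
normalized_recovery_error <- function(G_est, G_star) {
  nrm2 <- riemannian_norm(G_star)^2
  if (nrm2 == 0) {
    stop(paste("reference mean is the identity (zero Riemannian norm);",
               "use the unnormalized geodesic distance instead"),
         call. = FALSE)
  }
  geodesic_distance(G_est, G_star)^2 / nrm2
}

fit_one <- function(method, coll, config, init_seed) {
  t0 <- proc.time()[["elapsed"]]
  est <- tryCatch(
    switch(method,
           mspdnn = {
             cfg <- config
             cfg$init_seed <- as.integer(init_seed)
             mspdnn_fit(coll, cfg)
           },
           gradient_descent = gradient_descent_mean(coll),
           ale = ale_mean(coll)),
    error = identity)
  list(est = est, runtime = proc.time()[["elapsed"]] - t0)
}

record_row <- function(method, P, N, sigma, rep_seed, fit, G_star = NULL) {
  est <- fit$est
  failed <- inherits(est, "error")
  data.frame(
    method = method, P = P, N = N, sigma = sigma,
    replicate_seed = rep_seed,
    condition_fit = if (failed) NA_real_ else est$condition_fit,
    d_mean = if (failed || is.null(G_star)) NA_real_ else
      normalized_recovery_error(est$mean, G_star),
    runtime_seconds = fit$runtime,
    converged = if (failed) FALSE else isTRUE(est$converged),
    stringsAsFactors = FALSE)
}

#' Scalability benchmark over dataset size or dimensionality
#'
#' Reruns the noiseless CPC benchmark on a grid: for each grid cell and
#' replicate, sample a CPC dataset, fit each requested estimator, and record
#' the condition fit, the normalized recovery error against the closed-form
#' CPC mean, runtime and convergence. Individual fit failures become
#' `converged = FALSE` rows and never abort the sweep.
#'
#' @param vary `"N"` (dimension fixed at `P_fixed`) or `"P"` (dataset size
#'   fixed at `N_fixed`).
#' @param values integer grid for the varying quantity; the defaults are
#'   the desk-scale profile `c(5, 10, 20)` (the full published grid
#'   `c(5, 10, 20, 50, 100, 200)` is available by passing it explicitly).
#' @param P_fixed,N_fixed the fixed quantity for each sweep type.
#' @param n_replicates replicates per cell.
#' @param methods subset of `c("mspdnn", "gradient_descent", "ale")`.
#' @param seed integer base seed.
#' @param config [mspdnn_config()] used for mSPD-NN fits (its `init_seed`
#'   is replaced per replicate).
#' @param vary_across `"both"` (default: new data and new initialization per
#'   replicate), `"init"` (one dataset, varying initializations), or
#'   `"data"` (new data, fixed initialization).
#' @return data.frame with one row per (method, cell, replicate).
#' @export
run_scalability_experiment <- function(vary = c("N", "P"),
                                       values = c(5, 10, 20),
                                       P_fixed = 30, N_fixed = 20,
                                       n_replicates = 10,
                                       methods = c("mspdnn",
                                                   "gradient_descent", "ale"),
                                       seed = 1,
                                       config = mspdnn_config(preset = "accurate"),
                                       vary_across = c("both", "init", "data")) {
  vary <- match.arg(vary)
  vary_across <- match.arg(vary_across)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(length(values) >= 1)
  rows <- list()
  for (ci in seq_along(values)) {
    P <- if (vary == "P") values[ci] else P_fixed
    N <- if (vary == "N") values[ci] else N_fixed
    for (r in seq_len(n_replicates)) {
      data_seed <- if (vary_across == "init") seed + 7919L * ci else
        seed + 7919L * ci + 13L * r
      init_seed <- if (vary_across == "data") seed else seed + 104729L * r
      d <- sample_cpc_dataset(P, N, data_seed)
      G_star <- theoretical_cpc_mean(d$truth)
      for (m in methods) {
        fit <- fit_one(m, d$collection, config, init_seed)
        rows[[length(rows) + 1]] <-
          record_row(m, P, N, 0, data_seed, fit, G_star)
      }
    }
  }
  do.call(rbind, rows)
}

#' Noise-robustness benchmark under structured CPC corruption
#'
#' For each noise level sigma and replicate, sample a CPC dataset, corrupt
#' it with rank-one structured noise, and record the condition fit of each
#' estimator. No closed-form mean exists under noise, so `d_mean` is `NA`.
#'
#' @param P,N dataset dimensions (defaults: the published setting 30 / 20).
#' @param sigma_grid noise levels; default 0.2 to 1.0 in steps of 0.1.
#' @inheritParams run_scalability_experiment
#' @return data.frame with one row per (method, sigma, replicate).
#' @export
run_noise_experiment <- function(P = 30, N = 20,
                                 sigma_grid = seq(0.2, 1.0, by = 0.1),
                                 n_replicates = 10,
                                 methods = c("mspdnn", "gradient_descent",
                                             "ale"),
                                 seed = 1,
                                 config = mspdnn_config(preset = "accurate")) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(sigma_grid >= 0))
  rows <- list()
  for (si in seq_along(sigma_grid)) {
    sigma <- sigma_grid[si]
    for (r in seq_len(n_replicates)) {
      data_seed <- seed + 7919L * si + 13L * r
      d <- sample_cpc_dataset(P, N, data_seed)
      coll <- if (sigma > 0) {
        add_structured_noise(d$truth, sigma, data_seed + 500000L)
      } else {
        d$collection
      }
      for (m in methods) {
        fit <- fit_one(m, coll, config, seed + 104729L * r)
        rows[[length(rows) + 1]] <-
          record_row(m, P, N, sigma, data_seed, fit, NULL)
      }
    }
  }
  do.call(rbind, rows)
}

#' Pairwise concordance of mean estimates across initializations
#'
#' Symmetric matrix of geodesic distances between the means recovered by
#' differently seeded fits of one dataset; a tight cluster (small maximum
#' off-diagonal) indicates the estimator converges to the same solution
#' regardless of initialization.
#'
#' @param estimates list of `"mean_estimate"` objects (or SPD matrices) of
#'   equal dimension, length >= 2.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
initialization_concordance <- function(estimates) {
  if (length(estimates) < 2) stop("need at least two estimates", call. = FALSE)
  mats <- lapply(estimates, function(e) {
    if (inherits(e, "mean_estimate")) e$mean else e
  })
  P <- nrow(mats[[1]])
  for (m in mats) {
    if (!all(dim(m) == c(P, P))) {
      stop("estimates have mismatched dimensions", call. = FALSE)
    }
  }
  K <- length(mats)
  D <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      D[i, j] <- D[j, i] <- geodesic_distance(mats[[i]], mats[[j]])
    }
  }
  D
}
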