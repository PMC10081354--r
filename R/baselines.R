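#' Riemannian gradient descent for the geodesic mean
#'
#' Classical fixed-step descent on the Frechet objective: from the
#' arithmetic mean `G0`, iterate
#' \deqn{G \leftarrow G^{1/2} \exp\!\Big(s\,\sum_n w_n
#'   \log(G^{-1/2}\Gamma_n G^{-1/2})\Big) G^{1/2}}
#' until the Frobenius norm of the tangent update falls below `tol`. The
#' method is sensitive to the step size `step`; `step = 1` solves commuting
#' collections in one iteration, smaller values are safer in general.
#'
#' @param collection a [connectome_collection()] or list of SPD matrices.
#' @param step positive step size.
#' @param tol convergence tolerance on the tangent-update norm.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE`
#'   rather than raising an error.
#' @return a `"mean_estimate"` (see [mspdnn_fit()]), `method =
#'   "gradient_descent"`; `loss_trace` holds the tangent-update norms.
#' @export
gradient_descent_mean <- function(collection, step = 0.5, tol = 1e-10,
                                  max_iter = 200) {
  coll <- connectome_collection(collection)
  if (!is.numeric(step) || step <= 0) {
    stop("'step' must be a positive number", call. = FALSE)
  }
  wn <- coll_weights(coll)
  G <- sym_part(Reduce(`+`, Map(`*`, coll$matrices, wn)))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    e <- eigen(G, symmetric = TRUE)
    h <- sym_part(e$vectors %*% (sqrt(e$values) * t(e$vectors)))
    ih <- sym_part(e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors)))
    Tg <- 0
    for (n in seq_len(coll$N)) {
      Tg <- Tg + wn[n] * matrix_logm(sym_part(ih %*% coll$matrices[[n]] %*% ih))
    }
    upd <- sqrt(sum(Tg^2))
    trace <- c(trace, upd)
    if (!is.finite(upd)) {
      stop(sprintf("gradient descent diverged at iteration %d", iter),
           call. = FALSE)
    }
    if (upd < tol) {
      converged <- TRUE
      break
    }
    G <- sym_part(h %*% matrix_expm(step * Tg) %*% h)
  }
  new_mean_estimate(unclass(spd(G)), coll, trace, iter, converged,
                    "gradient_descent")
}

#' Approximate joint diagonalization (Pham's algorithm)
#'
#' Jacobi-like sweeps minimizing the log-likelihood off-diagonality
#' criterion \eqn{\sum_n w_n [\log\det\mathrm{diag}(B^T\Gamma_n B) -
#' \log\det(B^T\Gamma_n B)]}, which is nonnegative and zero iff all
#' congruences are exactly diagonal. Returns an invertible `B` such that
#' every `t(B) %*% Gamma_n %*% B` is as diagonal as the criterion permits.
#'
#' @param collection a [connectome_collection()] or list of at least two
#'   SPD matrices.
#' @param tol per-rotation decrement tolerance (scaled by `P*(P-1)`).
#' @param max_sweeps maximum number of full sweeps over all index pairs.
#' @return list with elements `B` (the diagonalizer), `criterion` (final
#'   off-diagonality), `sweeps`, and `converged`.
#' @export
ajd_pham <- function(collection, tol = 1e-12, max_sweeps = 100) {
  coll <- connectome_collection(collection)
  if (coll$N < 2) stop("joint diagonalization needs N >= 2", call. = FALSE)
  P <- coll$P
  N <- coll$N
  A <- do.call(cbind, coll$matrices)  # P x (P*N), slice n in columns (n-1)*P + 1:P
  V <- diag(P)
  epsilon <- P * (P - 1) * tol
  converged <- FALSE
  sweeps <- 0
  for (sweep in seq_len(max_sweeps)) {
    sweeps <- sweep
    decr <- 0
    for (ii in 2:P) {
      for (jj in 1:(ii - 1)) {
        Ii <- seq(ii, P * N, by = P)
        Ij <- seq(jj, P * N, by = P)
        c1 <- A[ii, Ii]
        c2 <- A[jj, Ij]
        g12 <- mean(A[ii, Ij] / c1)
        g21 <- mean(A[ii, Ij] / c2)
        omega21 <- mean(c1 / c2)
        omega12 <- mean(c2 / c1)
        omega <- sqrt(omega12 * omega21)
        tmp <- sqrt(omega21 / omega12)
        tmp1 <- (tmp * g12 + g21) / (omega + 1)
        tmp2 <- (tmp * g12 - g21) / max(omega - 1, 1e-9)
        h12 <- tmp1 + tmp2
        h21 <- (tmp1 - tmp2) / tmp
        decr <- decr + N * (g12 * h12 + g21 * h21) / 2
        rad <- 1 - h12 * h21
        Tden <- 1 + sqrt(max(rad, .Machine$double.eps))
        tau <- matrix(c(1, -h21 / Tden, -h12 / Tden, 1), 2, 2)
        A[c(ii, jj), ] <- tau %*% A[c(ii, jj), ]
        Ci <- A[, Ii, drop = FALSE]
        Cj <- A[, Ij, drop = FALSE]
        A[, Ii] <- Ci * tau[1, 1] + Cj * tau[1, 2]
        A[, Ij] <- Ci * tau[2, 1] + Cj * tau[2, 2]
        V[c(ii, jj), ] <- tau %*% V[c(ii, jj), ]
      }
    }
    if (is.finite(decr) && decr < epsilon) {
      converged <- TRUE
      break
    }
  }
  # V C_n V^T ~ diagonal; report B with t(B) %*% C_n %*% B diagonal
  crit <- 0
  for (n in seq_len(N)) {
    D <- V %*% coll$matrices[[n]] %*% t(V)
    crit <- crit + (sum(log(diag(D))) - determinant(D)$modulus[1]) / N
  }
  list(B = t(V), criterion = as.numeric(crit), sweeps = sweeps,
       converged = converged)
}

#' ALE mean: approximate-joint-diagonalization log-Euclidean estimate
#'
#' Finds an approximate joint diagonalizer `B` of the collection with
#' [ajd_pham()], averages the logs of the diagonal parts in that basis, and
#' maps back:
#' \deqn{\hat G = B^{-T}\exp\!\Big(\sum_n w_n \log\,\mathrm{diag}
#'   (B^T\Gamma_n B)\Big) B^{-1}.}
#' When the collection follows an exact common-principal-components process
#' this equals the closed-form optimal geodesic mean.
#'
#' @inheritParams ajd_pham
#' @return a `"mean_estimate"` (see [mspdnn_fit()]), `method = "ale"`;
#'   `loss_trace` holds the final off-diagonality criterion.
#' @export
ale_mean <- function(collection, tol = 1e-12, max_sweeps = 100) {
  coll <- connectome_collection(collection)
  if (coll$N < 2) stop("ALE mean needs N >= 2", call. = FALSE)
  wn <- coll_weights(coll)
  jd <- ajd_pham(coll, tol = tol, max_sweeps = max_sweeps)
  B <- jd$B
  logd <- 0
  for (n in seq_len(coll$N)) {
    d <- diag(t(B) %*% coll$matrices[[n]] %*% B)
    if (any(d <= 0)) {
      stop("joint diagonalization produced a nonpositive diagonal", call. = FALSE)
    }
    logd <- logd + wn[n] * log(d)
  }
  Binv <- solve(B)
  G <- sym_part(t(Binv) %*% (exp(logd) * Binv))
  new_mean_estimate(unclass(spd(G)), coll,
                    loss_trace = jd$criterion,
                    n_iterations = jd$sweeps,
                    converged = jd$converged, method = "ale")
}

#' Estimate a geodesic mean by any of the supported methods
#'
#' Thin dispatcher over [mspdnn_fit()], [gradient_descent_mean()] and
#' [ale_mean()].
#'
#' @param collection a [connectome_collection()] or list of SPD matrices.
#' @param method estimator name.
#' @param ... passed to the chosen estimator.
#' @return a `"mean_estimate"`.
#' @export
estimate_mean <- function(collection,
                          method = c("mspdnn", "gradient_descent", "ale"),
                          ...) {
  method <- match.arg(method)
  switch(method,
         mspdnn = mspdnn_fit(collection, ...),
         gradient_descent = gradient_descent_mean(collection, ...),
         ale = ale_mean(collection, ...))
}
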