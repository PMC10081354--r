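#' Sample a common-principal-components (CPC) dataset
#'
#' Generates `N` SPD matrices sharing one component basis:
#' `Gamma_n = B C_n B^T` with `C_n = diag(c_n)`. Columns of `B` are i.i.d.
#' standard normal vectors; the component weights are squared standard
#' normal draws (`c_nk = z^2`, a chi-squared(1) variate, since positivity of
#' `C_n` forces the square), clipped below at 0.001 to avoid near-singular
#' inputs. A component basis `B` that is near-singular (condition number
#' above 1e12, or any resulting sample failing SPD validation) is
#' resampled with an incremented sub-seed; the coefficient draw is
#' unaffected.
#'
#' @param P matrix dimension (>= 2).
#' @param N number of samples (>= 1).
#' @param seed integer seed; the draw is fully determined by it.
#' @return list with `truth` (class `"cpc_truth"`: fields `B`,
#'   `coefficients` (N x P matrix), `sigma = 0`, `seed`) and `collection`
#'   (a [connectome_collection()]).
#' @export
#' @examples
#' d <- sample_cpc_dataset(P = 5, N = 4, seed = 1)
#' d$collection
sample_cpc_dataset <- function(P, N, seed) {
  stopifnot(P >= 2, N >= 1)
  seed <- as.integer(seed)
  coef <- withr_seed(seed + 1000L, {
    matrix(pmax(stats::rnorm(N * P)^2, 0.001), nrow = N, ncol = P)
  })
  sub <- 0L
  repeat {
    B <- withr_seed(seed + sub, matrix(stats::rnorm(P * P), P, P))
    mats <- if (kappa(B, exact = FALSE) < 1e12) {
      tryCatch(lapply(seq_len(N), function(n) {
        unclass(spd(sym_part(B %*% (coef[n, ] * t(B)))))
      }), error = function(e) NULL)
    }
    if (!is.null(mats)) break
    message(sprintf("near-singular component matrix at seed %d; resampling",
                    seed + sub))
    sub <- sub + 1L
  }
  truth <- structure(list(B = B, coefficients = coef, sigma = 0,
                          noise_vectors = NULL, seed = seed),
                     class = "cpc_truth")
  list(truth = truth,
       collection = connectome_collection(mats, validate = FALSE))
}

#' @export
print.cpc_truth <- function(x, ...) {
  cat(sprintf("cpc_truth: P=%d, N=%d, sigma=%g, seed=%d\n",
              nrow(x$B), nrow(x$coefficients), x$sigma, x$seed))
  invisible(x)
}

#' Add rank-one structured noise to a CPC dataset
#'
#' Perturbs each sample as `Gamma_n = B C_n B^T + (1/P) x_n x_n^T` with
#' `x_n ~ N(0, sigma^2 I_P)`. The perturbation is positive semidefinite, so
#' the outputs stay SPD; `sigma = 0` returns the noiseless collection.
#'
#' @param truth a `"cpc_truth"` from [sample_cpc_dataset()].
#' @param sigma noise scale, >= 0.
#' @param seed integer seed for the noise draws.
#' @return a [connectome_collection()] of the noisy matrices.
#' @export
add_structured_noise <- function(truth, sigma, seed) {
  stopifnot(inherits(truth, "cpc_truth"), sigma >= 0)
  P <- nrow(truth$B)
  N <- nrow(truth$coefficients)
  X <- withr_seed(as.integer(seed), {
    matrix(stats::rnorm(N * P, sd = sigma), nrow = P, ncol = N)
  })
  mats <- lapply(seq_len(N), function(n) {
    base <- sym_part(truth$B %*% (truth$coefficients[n, ] * t(truth$B)))
    unclass(spd(base + tcrossprod(X[, n]) / P))
  })
  connectome_collection(mats, validate = FALSE)
}

#' Closed-form optimal geodesic mean of a noiseless CPC dataset
#'
#' For an exact CPC collection the geodesic mean is available in closed
#' form: \eqn{G^* = B \exp\big(\frac{1}{N}\sum_n \log(B^{-1}\Gamma_n B^{-T})
#' \big) B^T}, which reduces to `B expm(mean of log C_n) B^T` since each
#' congruence recovers the diagonal weight matrix.
#'
#' @param truth a `"cpc_truth"`.
#' @return SPD matrix (class `"spd"`).
#' @export
theoretical_cpc_mean <- function(truth) {
  stopifnot(inherits(truth, "cpc_truth"))
  if (!is.finite(kappa(truth$B)) || kappa(truth$B) > 1e14) {
    stop("component matrix B is numerically singular", call. = FALSE)
  }
  mlog <- colMeans(log(truth$coefficients))
  spd(sym_part(truth$B %*% (exp(mlog) * t(truth$B))))
}

#' Sample clustered SPD cohorts with controlled separation
#'
#' Test-fixture generator emulating a multi-group connectome cohort. One
#' centroid per cohort is placed on the manifold at pairwise geodesic
#' distance approximately `separation` (exactly `separation/sqrt(2)` from a
#' common anchor along Frobenius-orthonormal tangent directions, so pairwise
#' distances are ~`separation` up to curvature). Members sit at geodesic
#' distance exactly `within_spread` from their centroid, along random
#' symmetric tangent directions.
#'
#' @param P matrix dimension.
#' @param sizes integer vector of cohort sizes (one per cohort).
#' @param separation target pairwise centroid distance, >= 0.
#' @param within_spread member-to-centroid distance, > 0.
#' @param seed integer seed.
#' @return a labelled [connectome_collection()] (labels `"g1"`, `"g2"`, ...)
#'   with attribute `"centroids"` holding the cohort centroids.
#' @export
sample_clustered_cohorts <- function(P, sizes, separation, within_spread,
                                     seed) {
  stopifnot(P >= 2, length(sizes) >= 1, all(sizes >= 1),
            separation >= 0, within_spread > 0)
  K <- length(sizes)
  out <- withr_seed(as.integer(seed), {
    anchor <- matrix_expm(rand_sym(P) / sqrt(P))
    ah <- spd_power(anchor, 0.5)
    dirs <- orthonormal_sym_dirs(P, K)
    centroids <- lapply(seq_len(K), function(k) {
      unclass(spd(sym_part(
        ah %*% matrix_expm((separation / sqrt(2)) * dirs[[k]]) %*% ah)))
    })
    mats <- list()
    labels <- character(0)
    for (k in seq_len(K)) {
      ch <- spd_power(centroids[[k]], 0.5)
      for (m in seq_len(sizes[k])) {
        E <- rand_sym(P)
        E <- within_spread * E / sqrt(sum(E^2))
        mats[[length(mats) + 1]] <-
          unclass(spd(sym_part(ch %*% matrix_expm(E) %*% ch)))
        labels <- c(labels, paste0("g", k))
      }
    }
    list(mats = mats, labels = labels, centroids = centroids)
  })
  coll <- connectome_collection(out$mats, labels = out$labels,
                                validate = FALSE)
  attr(coll, "centroids") <- out$centroids
  coll
}

# random symmetric matrix with i.i.d. N(0,1) upper triangle
rand_sym <- function(P) {
  Z <- matrix(stats::rnorm(P * P), P, P)
  sym_part(Z) * sqrt(2)  # keep entry variance ~1 after averaging
}

# K Frobenius-orthonormal symmetric directions via Gram-Schmidt
orthonormal_sym_dirs <- function(P, K) {
  stopifnot(K <= P * (P + 1) / 2)
  dirs <- list()
  while (length(dirs) < K) {
    D <- rand_sym(P)
    for (e in dirs) D <- D - sum(D * e) * e
    nrm <- sqrt(sum(D^2))
    if (nrm > 1e-8) dirs[[length(dirs) + 1]] <- D / nrm
  }
  dirs
}
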