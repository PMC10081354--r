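#' @useDynLib spdmean, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Symmetrize before any eigendecomposition: all matrix functions in this
# package go through the symmetric part, which keeps eigenvalues real and
# the decompositions deterministic.
sym_part <- function(A) (A + t(A)) / 2

#' Validate and construct an SPD matrix
#'
#' Checks that `x` is a square numeric matrix, symmetric within tolerance,
#' and has all eigenvalues strictly above a floor. Returns the symmetrized
#' matrix (class `"spd"`), so downstream eigendecompositions are exact.
#'
#' @param x square numeric matrix.
#' @param sym_tol relative symmetry tolerance: the maximum absolute
#'   asymmetry allowed is `sym_tol * (1 + max(abs(x)))`.
#' @param eig_floor smallest admissible eigenvalue. The default
#'   `NULL` uses `1e-10 * trace/P`, scaling the floor with the matrix.
#' @return the validated matrix with class `"spd"`.
#' @export
#' @examples
#' spd(diag(2, 3))
spd <- function(x, sym_tol = 1e-8, eig_floor = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'x' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) != ncol(x)) {
    stop(sprintf("matrix must be square, got %d x %d", nrow(x), ncol(x)),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("matrix contains non-finite entries", call. = FALSE)
  }
  asym <- max(abs(x - t(x)))
  scale <- 1 + max(abs(x))
  if (asym > sym_tol * scale) {
    stop(sprintf("matrix is not symmetric: max asymmetry %.3e exceeds tolerance %.3e",
                 asym, sym_tol * scale), call. = FALSE)
  }
  x <- sym_part(x)
  if (is.null(eig_floor)) eig_floor <- 1e-10 * sum(diag(x)) / nrow(x)
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(eig_floor, 0)) {
    stop(sprintf("matrix is not positive definite: smallest eigenvalue %.6e (floor %.3e)",
                 min(ev), eig_floor), call. = FALSE)
  }
  structure(x, class = c("spd", class(x)))
}

#' Test whether a matrix passes SPD validation
#' @inheritParams spd
#' @return logical scalar.
#' @export
is_spd <- function(x, sym_tol = 1e-8, eig_floor = NULL) {
  !inherits(tryCatch(spd(x, sym_tol, eig_floor), error = identity), "error")
}

# internal: validate unless already validated; strip class for arithmetic
as_spd_mat <- function(x, arg = "x") {
  if (inherits(x, "spd")) return(unclass(x))
  m <- tryCatch(spd(x), error = function(e) {
    stop(sprintf("'%s' is not SPD: %s", arg, conditionMessage(e)), call. = FALSE)
  })
  unclass(m)
}

check_symmetric <- function(V, arg = "V", sym_tol = 1e-8) {
  if (!is.matrix(V) || nrow(V) != ncol(V)) {
    stop(sprintf("'%s' must be a square matrix", arg), call. = FALSE)
  }
  if (max(abs(V - t(V))) > sym_tol * (1 + max(abs(V)))) {
    stop(sprintf("'%s' is not symmetric within tolerance", arg), call. = FALSE)
  }
  sym_part(V)
}

check_same_dim <- function(A, B) {
  if (!all(dim(A) == dim(B))) {
    stop(sprintf("dimension mismatch: %d x %d vs %d x %d",
                 nrow(A), ncol(A), nrow(B), ncol(B)), call. = FALSE)
  }
}

# Apply f to the eigenvalues of a symmetric matrix.
eig_apply <- function(A, f) {
  e <- eigen(sym_part(A), symmetric = TRUE)
  sym_part(e$vectors %*% (f(e$values) * t(e$vectors)))
}

#' Matrix logarithm of an SPD matrix
#'
#' Principal logarithm via symmetric eigendecomposition: for
#' \eqn{\Gamma = U \Lambda U^T}, returns \eqn{U \log(\Lambda) U^T}.
#' This is the log map to the tangent space at the identity.
#'
#' @param x SPD matrix.
#' @return symmetric matrix (tangent vector at the identity).
#' @export
matrix_logm <- function(x) {
  x <- sym_part(check_symmetric(x, "x"))
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) <= 0) {
    stop(sprintf("matrix_logm requires an SPD argument; smallest eigenvalue is %.6e",
                 min(e$values)), call. = FALSE)
  }
  sym_part(e$vectors %*% (log(e$values) * t(e$vectors)))
}

#' Matrix exponential of a symmetric matrix
#'
#' @param v symmetric matrix (tangent vector at the identity).
#' @return SPD matrix \eqn{U \exp(\Lambda) U^T}.
#' @export
matrix_expm <- function(v) {
  v <- check_symmetric(v, "v")
  eig_apply(v, exp)
}

# SPD power through the eigendecomposition (p = 1/2, -1/2, -1, -2 ...)
spd_power <- function(x, p) eig_apply(x, function(l) l^p)

#' Riemannian exponential map on the SPD manifold
#'
#' Maps a tangent vector `v` at base point `phi` to the manifold:
#' \eqn{\Phi^{1/2} \exp(\Phi^{-1/2} V \Phi^{-1/2}) \Phi^{1/2}}.
#'
#' @param phi SPD base point.
#' @param v symmetric tangent matrix of the same dimension.
#' @return SPD matrix.
#' @export
exp_map <- function(phi, v) {
  phi <- as_spd_mat(phi, "phi")
  v <- check_symmetric(v, "v")
  check_same_dim(phi, v)
  ph <- spd_power(phi, 0.5)
  phi_inv_h <- spd_power(phi, -0.5)
  sym_part(ph %*% matrix_expm(sym_part(phi_inv_h %*% v %*% phi_inv_h)) %*% ph)
}

#' Riemannian logarithm map on the SPD manifold
#'
#' Inverse of [exp_map()]: the tangent vector at `phi` pointing to `gamma`,
#' \eqn{\Phi^{1/2} \log(\Phi^{-1/2} \Gamma \Phi^{-1/2}) \Phi^{1/2}}.
#'
#' @param phi SPD base point.
#' @param gamma SPD target point.
#' @return symmetric tangent matrix.
#' @export
log_map <- function(phi, gamma) {
  phi <- as_spd_mat(phi, "phi")
  gamma <- as_spd_mat(gamma, "gamma")
  check_same_dim(phi, gamma)
  ph <- spd_power(phi, 0.5)
  phi_inv_h <- spd_power(phi, -0.5)
  sym_part(ph %*% matrix_logm(sym_part(phi_inv_h %*% gamma %*% phi_inv_h)) %*% ph)
}

#' Affine-invariant geodesic distance between SPD matrices
#'
#' The Fisher-information distance
#' \eqn{\delta_R(\Gamma_1,\Gamma_2) = \|\log(\Gamma_1^{-1}\Gamma_2)\|_F},
#' computed in the congruence form
#' \eqn{\|\log(\Gamma_1^{-1/2}\Gamma_2\Gamma_1^{-1/2})\|_F} whose argument
#' is symmetric (equal in norm, numerically stable).
#'
#' @param gamma1,gamma2 SPD matrices of equal dimension.
#' @return nonnegative scalar.
#' @export
geodesic_distance <- function(gamma1, gamma2) {
  g1 <- as_spd_mat(gamma1, "gamma1")
  g2 <- as_spd_mat(gamma2, "gamma2")
  check_same_dim(g1, g2)
  ih <- spd_power(g1, -0.5)
  sqrt(sum(matrix_logm(sym_part(ih %*% g2 %*% ih))^2))
}

#' Riemannian norm of an SPD matrix
#'
#' \eqn{\|\Gamma\|_R = \|\log(\Gamma)\|_F}, the geodesic distance from the
#' identity.
#'
#' @param gamma SPD matrix.
#' @return nonnegative scalar.
#' @export
riemannian_norm <- function(gamma) {
  g <- as_spd_mat(gamma, "gamma")
  sqrt(sum(matrix_logm(g)^2))
}

#' Closed-form geodesic mean of two SPD matrices
#'
#' The midpoint of the geodesic joining `gamma1` and `gamma2`:
#' \eqn{\Gamma_1^{1/2}(\Gamma_1^{-1/2}\Gamma_2\Gamma_1^{-1/2})^{1/2}\Gamma_1^{1/2}}.
#' This is the unique minimizer of the Frechet objective for two matrices and
#' serves as an exact oracle for the iterative estimators.
#'
#' @inheritParams geodesic_distance
#' @return SPD matrix equidistant from both arguments.
#' @export
geodesic_midpoint <- function(gamma1, gamma2) {
  g1 <- as_spd_mat(gamma1, "gamma1")
  g2 <- as_spd_mat(gamma2, "gamma2")
  check_same_dim(g1, g2)
  h <- spd_power(g1, 0.5)
  ih <- spd_power(g1, -0.5)
  spd(sym_part(h %*% spd_power(sym_part(ih %*% g2 %*% ih), 0.5) %*% h))
}
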