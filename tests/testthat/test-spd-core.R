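test_that("SPD validation accepts valid input and rejects asymmetry and indefiniteness", {
  expect_s3_class(spd(diag(2, 3)), "spd")
  A <- diag(3)
  A[1, 2] <- 0.5  # asymmetric beyond tolerance
  expect_error(spd(A), "not symmetric")
  B <- diag(c(1, -0.5, 2))
  expect_error(spd(B), "positive definite")
  expect_error(spd(B), "-5\\.0")  # names the offending eigenvalue
  expect_false(is_spd(B))
  # configurable floor
  expect_true(is_spd(diag(c(1e-6, 1)), eig_floor = 1e-8))
  expect_false(is_spd(diag(c(1e-6, 1)), eig_floor = 1e-3))
})

test_that("matrix logarithm and exponential match their diagonal closed forms", {
  expect_equal(matrix_logm(diag(3)), matrix(0, 3, 3))
  expect_equal(matrix_logm(diag(c(exp(1), exp(2)))), diag(c(1, 2)))
  expect_equal(matrix_expm(matrix(0, 4, 4)), diag(4))
  expect_equal(matrix_expm(diag(c(1, 0))), diag(c(exp(1), 1)))
  expect_error(matrix_logm(diag(c(1, -1))), "eigenvalue")
  expect_error(matrix_expm(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("expm and logm are mutual inverses on random draws", {
  set.seed(11)
  for (k in 1:5) {
    G <- rspd(5)
    expect_equal(matrix_expm(matrix_logm(G)), unclass(G), tolerance = 1e-10)
    V <- rsym(5)
    expect_equal(matrix_logm(matrix_expm(V)), V, tolerance = 1e-10)
  }
})

test_that("exponential and logarithm maps are mutual inverses at arbitrary base points", {
  set.seed(21)
  for (k in 1:5) {
    Phi <- rspd(6)
    Gamma <- rspd(6)
    expect_equal(exp_map(Phi, log_map(Phi, Gamma)), unclass(Gamma),
                 tolerance = 1e-8)
  }
  Phi <- rspd(4)
  expect_equal(exp_map(Phi, matrix(0, 4, 4)), unclass(Phi), tolerance = 1e-12)
  V <- rsym(4)
  expect_equal(exp_map(diag(4), V), matrix_expm(V), tolerance = 1e-12)
  expect_equal(log_map(Phi, Phi), matrix(0, 4, 4), tolerance = 1e-10)
  G <- rspd(4)
  expect_equal(log_map(diag(4), G), matrix_logm(G), tolerance = 1e-12)
  expect_error(exp_map(Phi, matrix(0, 5, 5)), "mismatch")
})

test_that("log map norm at the base point equals the geodesic distance", {
  set.seed(31)
  for (k in 1:5) {
    Phi <- rspd(5)
    Gamma <- rspd(5)
    ih <- matrix_expm(-0.5 * matrix_logm(Phi))
    v <- ih %*% log_map(Phi, Gamma) %*% ih
    expect_equal(sqrt(sum(v^2)), geodesic_distance(Phi, Gamma),
                 tolerance = 1e-8)
  }
})

test_that("geodesic distance is a symmetric, affine-invariant metric", {
  G <- rspd(3)
  expect_equal(geodesic_distance(G, G), 0, tolerance = 1e-10)
  expect_equal(geodesic_distance(diag(2), diag(c(exp(2), exp(2)))),
               2 * sqrt(2), tolerance = 1e-10)
  set.seed(41)
  for (k in 1:5) {
    A <- rspd(10)
    B <- rspd(10)
    expect_lt(abs(geodesic_distance(A, B) - geodesic_distance(B, A)), 1e-8)
    expect_gt(geodesic_distance(A, B), 0)
    # affine invariance under congruence by a random invertible matrix
    M <- matrix(rnorm(100), 10, 10) + 3 * diag(10)
    expect_equal(geodesic_distance(M %*% A %*% t(M), M %*% B %*% t(M)),
                 geodesic_distance(A, B), tolerance = 1e-7)
  }
})

test_that("Riemannian norm is the distance from the identity", {
  expect_equal(riemannian_norm(diag(5)), 0)
  expect_equal(riemannian_norm(diag(c(exp(1), exp(-1)))), sqrt(2),
               tolerance = 1e-12)
  set.seed(51)
  for (k in 1:5) {
    G <- rspd(6)
    expect_equal(riemannian_norm(G), geodesic_distance(diag(6), G),
                 tolerance = 1e-10)
  }
})

test_that("geodesic midpoint is equidistant and satisfies the matrix-normal equation", {
  G <- rspd(4)
  expect_equal(unclass(geodesic_midpoint(G, G)), unclass(G), tolerance = 1e-10)
  expect_equal(unclass(geodesic_midpoint(diag(c(1, 1)), diag(c(4, 16)))),
               diag(c(2, 4)), tolerance = 1e-10)
  set.seed(61)
  for (k in 1:5) {
    A <- rspd(5)
    B <- rspd(5)
    mid <- geodesic_midpoint(A, B)
    expect_lt(abs(geodesic_distance(A, mid) - geodesic_distance(B, mid)), 1e-8)
    imh <- matrix_expm(-0.5 * matrix_logm(mid))
    res <- matrix_logm(imh %*% A %*% imh) + matrix_logm(imh %*% B %*% imh)
    expect_lt(max(abs(res)), 1e-8)
  }
})
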