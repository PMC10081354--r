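# fixtures built in code: random SPD draws with moderate spectra
rsym <- function(P) {
  Z <- matrix(rnorm(P * P), P, P)
  (Z + t(Z)) / 2
}

# SPD matrix with eigenvalue spread controlled by `scale` (log-spectrum sd)
rspd <- function(P, scale = 1) {
  matrix_expm(scale * rsym(P) / sqrt(P))
}

# elementwise geometric mean of a list of diagonal matrices
diag_geomean <- function(mats) {
  diag(exp(Reduce(`+`, lapply(mats, function(m) log(diag(m)))) / length(mats)))
}

# two-cohort fixture whose centroids differ in exactly one edge
planted_edge_cohort <- function(P, n_per_group, edge = c(1, 2), delta = 0.5,
                                spread = 0.01, seed = 1) {
  set.seed(seed)
  C1 <- diag(P) + 0.1 * tcrossprod(rep(1, P)) / P
  C2 <- C1
  C2[edge[1], edge[2]] <- C2[edge[1], edge[2]] + delta
  C2[edge[2], edge[1]] <- C2[edge[1], edge[2]]
  stopifnot(min(eigen(C2, symmetric = TRUE, only.values = TRUE)$values) > 0)
  mats <- list()
  labels <- character(0)
  for (g in 1:2) {
    cen <- if (g == 1) C1 else C2
    for (m in seq_len(n_per_group)) {
      E <- rsym(P)
      E <- spread * E / sqrt(sum(E^2))
      mats[[length(mats) + 1]] <- exp_map(cen, E)
      labels <- c(labels, paste0("g", g))
    }
  }
  connectome_collection(mats, labels = labels)
}

acc_cfg <- function(seed = 1L) {
  mspdnn_config(preset = "accurate", init_seed = as.integer(seed))
}
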