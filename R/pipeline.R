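#' Regularized Pearson correlation connectome from ROI time series
#'
#' Computes the Pearson correlation matrix of a T x P time-series matrix and
#' shrinks it toward the identity, `(1 - s) C + s I`, to guarantee full
#' rank; the result is validated SPD.
#'
#' @param timeseries numeric matrix, T rows (time points) x P columns
#'   (regions), T >= 2.
#' @param shrinkage shrinkage intensity in `[0, 1)`; default 0.05.
#' @return SPD matrix (class `"spd"`).
#' @export
correlation_connectome <- function(timeseries, shrinkage = 0.05) {
  if (!is.matrix(timeseries) || nrow(timeseries) < 2) {
    stop("'timeseries' must be a matrix with at least two rows", call. = FALSE)
  }
  stopifnot(shrinkage >= 0, shrinkage < 1)
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop(sprintf("constant column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  C <- stats::cor(timeseries)
  R <- (1 - shrinkage) * C + shrinkage * diag(ncol(C))
  tryCatch(spd(R), error = function(e) {
    stop(sprintf(paste0("regularized correlation matrix is not positive ",
                        "definite (%s); increase 'shrinkage'"),
                 conditionMessage(e)), call. = FALSE)
  })
}

group_mean_fit <- function(coll, estimator, config, init_seed = NULL) {
  switch(estimator,
         mspdnn = {
           cfg <- config
           if (!is.null(init_seed)) cfg$init_seed <- as.integer(init_seed)
           mspdnn_fit(coll, cfg)$mean
         },
         gradient_descent = gradient_descent_mean(coll)$mean,
         ale = ale_mean(coll)$mean)
}

#' Bootstrapped separation between two group geodesic means
#'
#' Per trial, subsamples `subjects_per_boot` members without replacement
#' from each group, estimates each group's geodesic mean, and records the
#' geodesic distance between the two means ("between"). As a matched null,
#' each trial also splits a same-group subsample into two disjoint halves
#' and records the distance between their means ("within", averaged over
#' the two groups when both are large enough). A one-sided paired Wilcoxon
#' signed-rank test asks whether between-group distances exceed the matched
#' within-group distances.
#'
#' @param cohort labelled [connectome_collection()].
#' @param group_pair character vector of two labels.
#' @param n_boot number of bootstrap trials.
#' @param subjects_per_boot subjects drawn per group per trial (default 25).
#' @param estimator mean estimator for the group means.
#' @param config [mspdnn_config()] used when `estimator = "mspdnn"`.
#' @param seed integer seed.
#' @return list of class `"group_distance_test"` with `between`, `within`
#'   (numeric vectors of length `n_boot`), `p_value` (NA when `n_boot < 2`),
#'   and the call parameters.
#' @export
bootstrap_group_distance <- function(cohort, group_pair, n_boot = 50,
                                     subjects_per_boot = 25,
                                     estimator = c("mspdnn",
                                                   "gradient_descent", "ale"),
                                     config = mspdnn_config(),
                                     seed = 1) {
  estimator <- match.arg(estimator)
  cohort <- connectome_collection(cohort)
  if (is.null(cohort$labels)) stop("cohort has no labels", call. = FALSE)
  stopifnot(length(group_pair) == 2, n_boot >= 1)
  groups <- split_by_group(cohort)
  for (g in group_pair) {
    if (!g %in% names(groups)) {
      stop(sprintf("no group labelled '%s'", g), call. = FALSE)
    }
    if (groups[[g]]$N < subjects_per_boot) {
      stop(sprintf("group '%s' has %d members, fewer than subjects_per_boot = %d",
                   g, groups[[g]]$N, subjects_per_boot), call. = FALSE)
    }
  }
  g1 <- groups[[group_pair[1]]]
  g2 <- groups[[group_pair[2]]]
  between <- within <- numeric(n_boot)
  withr_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      i1 <- sample(g1$N, subjects_per_boot)
      i2 <- sample(g2$N, subjects_per_boot)
      m1 <- group_mean_fit(g1[i1], estimator, config, init_seed = seed + b)
      m2 <- group_mean_fit(g2[i2], estimator, config,
                           init_seed = seed + b + 100000L)
      between[b] <- geodesic_distance(m1, m2)
      # matched within-group split-half distance
      wd <- numeric(0)
      for (gg in list(g1, g2)) {
        half <- min(subjects_per_boot, floor(gg$N / 2))
        if (half < 1) next
        idx <- sample(gg$N, 2 * half)
        ma <- group_mean_fit(gg[idx[seq_len(half)]], estimator, config,
                             init_seed = seed + b + 200000L)
        mb <- group_mean_fit(gg[idx[half + seq_len(half)]], estimator,
                             config, init_seed = seed + b + 300000L)
        wd <- c(wd, geodesic_distance(ma, mb))
      }
      within[b] <- mean(wd)
    }
  })
  p <- if (n_boot >= 2) {
    stats::wilcox.test(between, within, paired = TRUE,
                       alternative = "greater", exact = FALSE)$p.value
  } else {
    NA_real_
  }
  structure(list(between = between, within = within, p_value = p,
                 group_pair = group_pair, n_boot = n_boot,
                 subjects_per_boot = subjects_per_boot,
                 estimator = estimator, seed = seed),
            class = "group_distance_test")
}

#' @export
print.group_distance_test <- function(x, ...) {
  cat(sprintf("group_distance_test: %s vs %s, %d trials\n",
              x$group_pair[1], x$group_pair[2], x$n_boot))
  cat(sprintf("median between = %.4f, median within = %.4f, p = %s\n",
              stats::median(x$between), stats::median(x$within),
              format.pval(x$p_value)))
  invisible(x)
}

#' Permutation test for group-discriminative connectome edges
#'
#' The observed statistic per edge is the absolute entrywise difference of
#' the two group geodesic means. The null is built by permuting the group
#' labels and re-estimating both means per shuffle; per-edge p-values use
#' the standard add-one estimator `(1 + #(null >= observed)) /
#' (1 + n_permutations)` and are Benjamini-Hochberg adjusted over the
#' off-diagonal upper triangle.
#'
#' @inheritParams bootstrap_group_distance
#' @param n_permutations number of label permutations, >= 100.
#' @param alpha FDR level for the selection mask (default 0.001).
#' @param subjects_per_estimate `NULL` (default): every mean estimate uses
#'   the full group. An integer switches to bootstrapped mean estimates:
#'   each estimate (observed and per shuffle) is computed from a
#'   without-replacement subsample of that many subjects per group.
#' @return object of class `"edge_selection"`: `p_values` (symmetric P x P,
#'   diagonal 1), `selected` (symmetric logical mask, diagonal FALSE),
#'   `observed` (the observed statistic), `alpha`, `n_permutations`.
#' @export
permutation_edge_selection <- function(cohort, group_pair,
                                       n_permutations = 1000, alpha = 0.001,
                                       estimator = c("mspdnn",
                                                     "gradient_descent",
                                                     "ale"),
                                       config = mspdnn_config(),
                                       seed = 1,
                                       subjects_per_estimate = NULL) {
  estimator <- match.arg(estimator)
  cohort <- connectome_collection(cohort)
  if (is.null(cohort$labels)) stop("cohort has no labels", call. = FALSE)
  if (n_permutations < 100) {
    stop("'n_permutations' must be at least 100", call. = FALSE)
  }
  stopifnot(length(group_pair) == 2, alpha > 0, alpha < 1)
  keep <- cohort$labels %in% group_pair
  sub <- cohort[which(keep)]
  lab <- sub$labels
  P <- sub$P
  if (!is.null(subjects_per_estimate)) {
    spe <- as.integer(subjects_per_estimate)
    stopifnot(spe >= 1)
    if (min(table(lab)[group_pair]) < spe) {
      stop(sprintf("a group has fewer than subjects_per_estimate = %d members",
                   spe), call. = FALSE)
    }
  }
  # subsample when bootstrapped mean estimates were requested (draws from
  # the surrounding seeded RNG block)
  pick <- function(idx) {
    if (is.null(subjects_per_estimate)) idx else
      sample(idx, as.integer(subjects_per_estimate))
  }
  stat_for <- function(labels, init_off) {
    m1 <- group_mean_fit(sub[pick(which(labels == group_pair[1]))], estimator,
                         config, init_seed = seed + init_off)
    m2 <- group_mean_fit(sub[pick(which(labels == group_pair[2]))], estimator,
                         config, init_seed = seed + init_off + 1L)
    abs(m1 - m2)
  }
  exceed <- matrix(0, P, P)
  observed <- NULL
  withr_seed(as.integer(seed), {
    observed <- stat_for(lab, 0L)
    for (b in seq_len(n_permutations)) {
      perm <- sample(lab)
      nullstat <- stat_for(perm, 2L * b)
      exceed <- exceed + (nullstat >= observed)
    }
  })
  pmat <- (1 + exceed) / (1 + n_permutations)
  diag(pmat) <- 1
  ut <- upper.tri(pmat)
  padj <- stats::p.adjust(pmat[ut], method = "BH")
  sel <- matrix(FALSE, P, P)
  sel[ut] <- padj < alpha
  sel <- sel | t(sel)
  pad_full <- matrix(1, P, P)
  pad_full[ut] <- padj
  pad_full <- pmin(pad_full, t(pad_full))
  diag(pad_full) <- 1
  structure(list(p_values = pmin(pmat, t(pmat)), p_adjusted = pad_full,
                 selected = sel, observed = observed, alpha = alpha,
                 n_permutations = n_permutations, group_pair = group_pair,
                 estimator = estimator, seed = seed,
                 subjects_per_estimate = subjects_per_estimate),
            class = "edge_selection")
}

#' @export
print.edge_selection <- function(x, ...) {
  P <- nrow(x$selected)
  cat(sprintf("edge_selection: %s vs %s, %d permutations, FDR alpha = %g\n",
              x$group_pair[1], x$group_pair[2], x$n_permutations, x$alpha))
  cat(sprintf("selected %d of %d edges\n", sum(x$selected[upper.tri(x$selected)]),
              P * (P - 1) / 2))
  invisible(x)
}

# vectorize the selected upper-triangle entries of each subject
selected_features <- function(coll, selection) {
  mask <- selection$selected & upper.tri(selection$selected)
  if (!any(mask)) {
    stop("edge selection is empty; rerun with a laxer 'alpha'", call. = FALSE)
  }
  k <- sum(mask)
  feats <- vapply(coll$matrices, function(m) m[mask], numeric(k))
  # vapply drops to a plain vector when a single edge is selected
  if (k == 1) matrix(feats, ncol = 1) else t(feats)
}

#' Classify subjects from selected connectome edges
#'
#' Thin supervised stage: vectorizes each subject's selected edges, fits an
#' off-the-shelf random forest on the training cohort, and reports held-out
#' accuracy and AUROC on the test cohort.
#'
#' @param train,test labelled [connectome_collection()]s with two groups.
#' @param selection an `"edge_selection"` with a nonempty mask.
#' @param n_trees forest size.
#' @param seed integer seed for the forest.
#' @return list with `accuracy`, `auroc`, `predicted`, and the fitted
#'   `model`.
#' @export
classify_with_selected_features <- function(train, test, selection,
                                            n_trees = 500, seed = 1) {
  train <- connectome_collection(train)
  test <- connectome_collection(test)
  if (is.null(train$labels) || is.null(test$labels)) {
    stop("train and test cohorts must be labelled", call. = FALSE)
  }
  xtr <- selected_features(train, selection)
  xte <- selected_features(test, selection)
  ytr <- factor(train$labels)
  if (nlevels(ytr) != 2) stop("training cohort must have two groups", call. = FALSE)
  yte <- factor(test$labels, levels = levels(ytr))
  model <- withr_seed(as.integer(seed), {
    randomForest::randomForest(x = xtr, y = ytr, ntree = n_trees)
  })
  pred <- stats::predict(model, xte)
  prob <- stats::predict(model, xte, type = "prob")[, levels(ytr)[2]]
  acc <- mean(pred == yte)
  auroc <- if (length(unique(yte)) == 2) {
    as.numeric(pROC::auc(pROC::roc(response = yte, predictor = prob,
                                   levels = levels(ytr), direction = "<",
                                   quiet = TRUE)))
  } else {
    NA_real_
  }
  list(accuracy = acc, auroc = auroc, predicted = pred, model = model)
}

#' Geodesic EM clustering with mSPD-NN centroids
#'
#' Alternates an E-step assigning each subject to the geodesically nearest
#' centroid (ties broken to the lowest cluster index) with an M-step
#' re-estimating each cluster centroid as the geodesic mean of its members.
#' Stops when the assignments no longer change or after `max_iter`
#' iterations. Clusters that become empty keep their previous centroid (a
#' message is emitted).
#'
#' @param collection a [connectome_collection()] or list of SPD matrices.
#' @param init_centroids list of SPD matrices (the initial centroids).
#' @param max_iter positive iteration cap.
#' @param estimator centroid estimator (default mSPD-NN).
#' @param config [mspdnn_config()] for mSPD-NN centroids.
#' @return object of class `"spd_em"`: `centroids`, `assignments` (integers
#'   in `1..K`), `iteration`, `converged`.
#' @export
mspd_em_cluster <- function(collection, init_centroids, max_iter = 20,
                            estimator = c("mspdnn", "gradient_descent",
                                          "ale"),
                            config = mspdnn_config()) {
  estimator <- match.arg(estimator)
  coll <- connectome_collection(collection)
  if (!is.numeric(max_iter) || max_iter <= 0) {
    stop("'max_iter' must be a positive integer", call. = FALSE)
  }
  if (is.matrix(init_centroids)) init_centroids <- list(init_centroids)
  K <- length(init_centroids)
  if (K < 1) stop("need at least one initial centroid", call. = FALSE)
  centroids <- lapply(seq_along(init_centroids), function(k) {
    m <- init_centroids[[k]]
    if (!all(dim(m) == c(coll$P, coll$P))) {
      stop(sprintf("centroid %d has wrong dimension", k), call. = FALSE)
    }
    unclass(spd(m))
  })
  assign_step <- function() {
    D <- vapply(centroids, function(ck) {
      vapply(coll$matrices, function(g) geodesic_distance(g, ck), 0)
    }, numeric(coll$N))
    D <- matrix(D, nrow = coll$N, ncol = K)
    apply(D, 1, which.min)  # which.min takes the first (lowest index) on ties
  }
  assignments <- assign_step()
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (k in seq_len(K)) {
      members <- which(assignments == k)
      if (length(members) == 0) {
        message(sprintf("cluster %d is empty at iteration %d; keeping its centroid",
                        k, iter))
        next
      }
      centroids[[k]] <- group_mean_fit(coll[members], estimator, config,
                                       init_seed = 1000L * iter + k)
    }
    new_assign <- assign_step()
    if (all(new_assign == assignments)) {
      converged <- TRUE
      break
    }
    assignments <- new_assign
  }
  structure(list(centroids = centroids, assignments = assignments,
                 iteration = iter, converged = converged),
            class = "spd_em")
}

#' @export
print.spd_em <- function(x, ...) {
  cat(sprintf("spd_em: %d clusters, %d subjects, %d iterations, converged=%s\n",
              length(x$centroids), length(x$assignments), x$iteration,
              x$converged))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Cluster purity against ground-truth labels
#'
#' Per cluster, the fraction of members carrying the cluster's modal true
#' label; overall purity is the size-weighted mean over non-empty clusters.
#' Clusters with no members have undefined purity and are excluded with a
#' warning.
#'
#' @param assignments integer cluster indices (1..K) or an `"spd_em"`.
#' @param labels true labels, same length.
#' @param K number of clusters; defaults to `max(assignments)`.
#' @return list with `per_cluster` (named numeric, NA for empty clusters)
#'   and `overall`.
#' @export
cluster_purity <- function(assignments, labels, K = NULL) {
  if (inherits(assignments, "spd_em")) assignments <- assignments$assignments
  if (length(assignments) != length(labels)) {
    stop("'assignments' and 'labels' must have equal length", call. = FALSE)
  }
  if (is.null(K)) K <- max(assignments)
  per <- rep(NA_real_, K)
  sizes <- integer(K)
  for (k in seq_len(K)) {
    members <- labels[assignments == k]
    sizes[k] <- length(members)
    if (sizes[k] > 0) per[k] <- max(table(members)) / sizes[k]
  }
  if (any(sizes == 0)) {
    warning(sprintf("empty cluster(s) excluded from overall purity: %s",
                    paste(which(sizes == 0), collapse = ", ")))
  }
  names(per) <- paste0("cluster", seq_len(K))
  overall <- sum(per[sizes > 0] * sizes[sizes > 0]) / sum(sizes)
  list(per_cluster = per, overall = overall)
}

#' Seeded per-group train/test split of a labelled cohort
#'
#' @param cohort labelled [connectome_collection()].
#' @param n_train_per_group subjects per group assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `test` collections.
#' @export
split_train_test <- function(cohort, n_train_per_group, seed = 1) {
  cohort <- connectome_collection(cohort)
  if (is.null(cohort$labels)) stop("cohort has no labels", call. = FALSE)
  idx <- split(seq_len(cohort$N), cohort$labels)
  tr <- withr_seed(as.integer(seed), {
    unlist(lapply(idx, function(i) {
      if (length(i) <= n_train_per_group) {
        stop("a group is too small for the requested training size",
             call. = FALSE)
      }
      sample(i, n_train_per_group)
    }))
  })
  list(train = cohort[sort(tr)], test = cohort[setdiff(seq_len(cohort$N), tr)])
}
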