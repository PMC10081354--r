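#' A collection of same-dimension SPD connectomes
#'
#' Bundles `N` validated SPD matrices with optional group labels and
#' optional strictly positive weights.
#'
#' @param matrices list of SPD matrices, all of the same dimension.
#' @param labels optional character/factor vector of length `N`.
#' @param weights optional numeric vector of length `N`, all strictly
#'   positive (used by the weighted Frechet mean).
#' @param validate set `FALSE` to skip SPD validation (trusted callers).
#' @return an object of class `"connectome_collection"`: a list with
#'   elements `matrices`, `labels`, `weights`, `P`, `N`.
#' @export
connectome_collection <- function(matrices, labels = NULL, weights = NULL,
                                  validate = TRUE) {
  if (inherits(matrices, "connectome_collection")) return(matrices)
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!is.list(matrices) || length(matrices) < 1) {
    stop("'matrices' must be a non-empty list of SPD matrices", call. = FALSE)
  }
  N <- length(matrices)
  P <- nrow(matrices[[1]])
  for (n in seq_len(N)) {
    m <- matrices[[n]]
    if (!is.matrix(m) || !all(dim(m) == c(P, P))) {
      stop(sprintf("matrix %d has dimension %s, expected %d x %d",
                   n, paste(dim(m), collapse = " x "), P, P), call. = FALSE)
    }
    if (validate) {
      matrices[[n]] <- tryCatch(unclass(spd(m)), error = function(e) {
        stop(sprintf("matrix %d failed SPD validation: %s",
                     n, conditionMessage(e)), call. = FALSE)
      })
    }
  }
  if (!is.null(labels)) {
    if (length(labels) != N) stop("'labels' must have length N", call. = FALSE)
    labels <- as.character(labels)
    if (any(is.na(labels) | !nzchar(labels))) {
      stop("labels must be non-empty and non-missing", call. = FALSE)
    }
  }
  if (!is.null(weights)) {
    if (length(weights) != N || !is.numeric(weights) || any(weights <= 0) ||
        any(!is.finite(weights))) {
      stop("'weights' must be N strictly positive finite numbers", call. = FALSE)
    }
  }
  structure(list(matrices = matrices, labels = labels, weights = weights,
                 P = P, N = N),
            class = "connectome_collection")
}

#' @export
print.connectome_collection <- function(x, ...) {
  cat(sprintf("connectome_collection: N = %d matrices of dimension %d x %d\n",
              x$N, x$P, x$P))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("labels:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  if (!is.null(x$weights)) cat("weighted: yes\n")
  invisible(x)
}

#' @export
length.connectome_collection <- function(x) x$N

#' @export
`[.connectome_collection` <- function(x, i) {
  connectome_collection(x$matrices[i],
                        labels = if (!is.null(x$labels)) x$labels[i],
                        weights = if (!is.null(x$weights)) x$weights[i],
                        validate = FALSE)
}

# internal: coerce list-or-collection and return the plain list of matrices
coll_matrices <- function(x) {
  connectome_collection(x)$matrices
}

# internal: stack collection into a P x P x N array
coll_cube <- function(coll) {
  array(unlist(coll$matrices), dim = c(coll$P, coll$P, coll$N))
}

# internal: normalized weights (uniform when absent)
coll_weights <- function(coll) {
  w <- if (is.null(coll$weights)) rep(1, coll$N) else coll$weights
  w / sum(w)
}

#' Split a labelled collection by group
#'
#' @param cohort a `connectome_collection` with labels.
#' @return named list of `connectome_collection`, one per distinct label.
#' @export
split_by_group <- function(cohort) {
  cohort <- connectome_collection(cohort)
  if (is.null(cohort$labels)) stop("collection has no labels", call. = FALSE)
  idx <- split(seq_len(cohort$N), cohort$labels)
  lapply(idx, function(i) cohort[i])
}
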