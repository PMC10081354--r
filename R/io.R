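#' Write a single matrix to a delimited text file
#'
#' Whitespace-delimited, row-major, full round-trip precision (17
#' significant digits), preceded by a one-line `# P <dim>` header comment.
#'
#' @param x numeric square matrix.
#' @param path output file path.
#' @export
write_matrix_file <- function(x, path) {
  stopifnot(is.matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# P %d", nrow(x)), con)
  write.table(format_num(x), con, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

format_num <- function(x) {
  m <- matrix(formatC(x, digits = 17, format = "g"), nrow = nrow(x))
  m
}

#' Read a single matrix from a delimited text file
#'
#' Accepts comma- or whitespace-delimited values; lines starting with `#`
#' are ignored.
#'
#' @param path file path.
#' @param validate validate the matrix as SPD (default `TRUE`); on failure
#'   the error names the file and the failing check.
#' @return numeric matrix.
#' @export
read_matrix_file <- function(path, validate = TRUE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]])
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    stop(sprintf("'%s': ragged rows (widths %s)", path,
                 paste(unique(lens), collapse = ", ")), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("'%s': matrix is %d x %d, expected square", path,
                 nrow(m), ncol(m)), call. = FALSE)
  }
  if (validate) {
    m <- tryCatch(unclass(spd(m)), error = function(e) {
      stop(sprintf("'%s': %s", path, conditionMessage(e)), call. = FALSE)
    })
  }
  m
}

#' Write a collection to a stacked text container
#'
#' One text file holding all matrices: a `# spd-collection P <P> N <N>`
#' header, then for each sample a `# sample <id>` line followed by its P
#' rows. An optional sidecar labels table can be written with
#' [write_labels_table()].
#'
#' @param collection a [connectome_collection()] or list of SPD matrices.
#' @param path output file path.
#' @param ids sample identifiers; default `sample001`, `sample002`, ...
#' @export
write_matrix_collection <- function(collection, path, ids = NULL) {
  coll <- connectome_collection(collection)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(coll$N))
  stopifnot(length(ids) == coll$N, !anyDuplicated(ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spd-collection P %d N %d", coll$P, coll$N), con)
  for (n in seq_len(coll$N)) {
    writeLines(sprintf("# sample %s", ids[n]), con)
    write.table(format_num(coll$matrices[[n]]), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a collection of SPD matrices
#'
#' `path` may be a stacked container file written by
#' [write_matrix_collection()], or a directory of per-subject matrix files
#' (identifier = file name without extension). Samples are ordered
#' lexicographically by identifier. Every matrix is SPD-validated; failures
#' name the offending sample and check. When `labels` is a path to a
#' two-column tab-separated table (`subject_id`, `label`), labels are
#' joined; a missing label is an error.
#'
#' @param path container file or directory.
#' @param labels optional path to a labels table.
#' @return a [connectome_collection()] with an `"ids"` attribute.
#' @export
read_matrix_collection <- function(path, labels = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0) stop(sprintf("'%s' contains no files", path),
                                 call. = FALSE)
    ids <- sub("\\.[^.]*$", "", basename(files))
    ord <- order(ids, method = "radix")
    ids <- ids[ord]
    mats <- lapply(files[ord], read_matrix_file)
  } else {
    lines <- readLines(path)
    starts <- grep("^# sample ", lines)
    if (length(starts) == 0) {
      stop(sprintf("'%s' is not an spd-collection container", path),
           call. = FALSE)
    }
    ids <- sub("^# sample ", "", lines[starts])
    ends <- c(starts[-1] - 1, length(lines))
    blocks <- Map(function(s, e) lines[(s + 1):e], starts, ends)
    ord <- order(ids, method = "radix")
    ids <- ids[ord]
    mats <- lapply(seq_along(ord), function(k) {
      b <- blocks[[ord[k]]]
      tmp <- tempfile()
      on.exit(unlink(tmp))
      writeLines(b, tmp)
      tryCatch(read_matrix_file(tmp), error = function(e) {
        stop(sprintf("sample '%s': %s", ids[k],
                     sub("^'[^']*': ", "", conditionMessage(e))),
             call. = FALSE)
      })
    })
  }
  lab <- NULL
  if (!is.null(labels)) {
    tb <- utils::read.table(labels, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("subject_id", "label") %in% names(tb))) {
      stop("labels table needs columns 'subject_id' and 'label'",
           call. = FALSE)
    }
    miss <- setdiff(ids, tb$subject_id)
    if (length(miss) > 0) {
      stop(sprintf("missing label for subject(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    lab <- tb$label[match(ids, tb$subject_id)]
  }
  coll <- connectome_collection(mats, labels = lab)
  attr(coll, "ids") <- ids
  coll
}

#' Write a sidecar labels table
#' @param ids subject identifiers.
#' @param labels group labels, same length.
#' @param path output path (tab-separated, header `subject_id`, `label`).
#' @export
write_labels_table <- function(ids, labels, path) {
  stopifnot(length(ids) == length(labels))
  utils::write.table(data.frame(subject_id = ids, label = labels),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write experiment records as a tab-separated table
#'
#' Header row, one row per record, floats at 17 significant digits,
#' deterministic row order (as given).
#'
#' @param records data.frame of homogeneous records.
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 17,
                                                 format = "g")
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a JSON run manifest
#'
#' Records the command name, all resolved parameters, every seed used, a
#' timestamp and the package version, so a run can be reproduced exactly.
#'
#' @param command character command name.
#' @param config named list of resolved parameters.
#' @param seeds integer vector of all seeds used by the run.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(command, config, seeds, path) {
  manifest <- list(command = command, config = config,
                   seeds = as.integer(seeds),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   artifact_version =
                     as.character(utils::packageVersion("spdmean")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
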