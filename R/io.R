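infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a TSV (default) or CSV file with one header row and one ID column and
#' returns a validated \code{\link{beta_matrix}} in the canonical
#' samples-as-rows orientation. Files stored CpGs-as-rows (the common 450K
#' export layout) are transposed on read.
#'
#' @param path file path.
#' @param orientation \code{"samples-as-rows"} (default) or
#'   \code{"cpgs-as-rows"}, describing the file on disk.
#' @param missing_tokens strings parsed as missing; default \code{"NA"},
#'   \code{"NaN"} and the empty string.
#' @param sep field separator; inferred from the file extension when
#'   \code{NULL} (\code{.csv} gives comma, anything else tab).
#' @return a \code{beta_matrix}.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples-as-rows", "cpgs-as-rows"),
                             missing_tokens = c("NA", "NaN", ""),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- infer_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           na.strings = character(0))
  if (ncol(raw) < 1) stopf("empty matrix file: %s", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stopf("duplicate row IDs in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(raw)[-1]
  if (anyDuplicated(cols))
    stopf("duplicate column IDs in %s: %s", path,
          paste(unique(cols[duplicated(cols)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells_trim <- trimws(cells)
  is_missing <- cells_trim %in% missing_tokens
  parsed <- suppressWarnings(as.numeric(cells_trim))
  bad <- which(is.na(parsed) & !is_missing)
  if (length(bad) > 0) {
    b <- arrayInd(bad[1], dim(cells))
    stopf("malformed numeric cell in %s at row '%s', column '%s': '%s'",
          path, ids[b[1]], cols[b[2]], cells[b[1], b[2]])
  }
  parsed[is_missing] <- NA_real_
  values <- matrix(parsed, nrow = nrow(cells), ncol = ncol(cells),
                   dimnames = list(ids, cols))
  if (orientation == "cpgs-as-rows") values <- t(values)
  beta_matrix(values)
}

#' Write a beta-value matrix to delimited text
#'
#' Samples as rows, CpGs as columns, missing entries as \code{NA}. Values are
#' written with 17 significant digits so a read/write round trip is lossless.
#'
#' @param m a \code{beta_matrix}.
#' @param path output file path.
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @export
write_beta_matrix <- function(m, path, sep = NULL) {
  validate_beta_matrix(m)
  sep <- infer_sep(path, sep)
  v <- unclass(m)
  body <- matrix("NA", nrow = nrow(v), ncol = ncol(v))
  ok <- !is.na(v)
  body[ok] <- sprintf("%.17g", v[ok])
  header <- paste(c("sample_id", colnames(v)), collapse = sep)
  lines <- if (nrow(v) == 0) {
    character(0)
  } else if (ncol(v) == 0) {
    rownames(v)
  } else {
    paste(rownames(v), apply(body, 1, paste, collapse = sep), sep = sep)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Read per-sample condition labels
#'
#' Reads a two-column (sample ID, condition) delimited file and returns a
#' \code{\link{condition_vector}} aligned to the requested sample order, with
#' a lexicographically sorted vocabulary.
#'
#' @param path file path; first row is a header.
#' @param samples character vector of sample IDs the labels must cover, in the
#'   order the result should follow.
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @return a \code{condition_vector}.
#' @export
read_labels <- function(path, samples, sep = NULL) {
  sep <- infer_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(raw) < 2) stopf("label file %s needs two columns (sample, condition)", path)
  map <- stats::setNames(raw[[2]], raw[[1]])
  missing <- setdiff(samples, names(map))
  if (length(missing) > 0)
    stopf("samples missing from label mapping %s: %s", path,
          paste(missing, collapse = ", "))
  condition_vector(unname(map[samples]))
}

#' Write per-sample condition labels
#' @param cv a \code{condition_vector}.
#' @param sample_ids sample IDs, parallel to \code{cv$labels}.
#' @param path output file path.
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @export
write_labels <- function(cv, sample_ids, path, sep = NULL) {
  stopifnot(length(sample_ids) == length(cv$labels))
  sep <- infer_sep(path, sep)
  utils::write.table(
    data.frame(sample_id = sample_ids, condition = cv$labels),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a matrix/label pair
#'
#' Validation entry point used by the command-line \code{validate} subcommand:
#' reports shape, per-condition sample counts and a missing-value summary.
#'
#' @param m a \code{beta_matrix}.
#' @param cv optional \code{condition_vector} aligned to \code{m}.
#' @return a list with elements \code{n_samples}, \code{n_cpgs},
#'   \code{n_missing}, \code{missing_fraction}, \code{all_missing_cpgs} and
#'   (when labels are given) \code{condition_counts}.
#' @export
validate_inputs <- function(m, cv = NULL) {
  validate_beta_matrix(m)
  out <- list(
    n_samples = nrow(m), n_cpgs = ncol(m),
    n_missing = sum(is.na(m)),
    missing_fraction = if (length(m) > 0) mean(is.na(m)) else 0,
    all_missing_cpgs = colnames(m)[colSums(!is.na(m)) == 0]
  )
  if (!is.null(cv)) {
    if (length(cv$labels) != nrow(m))
      stopf("labels (%d) do not match samples (%d)", length(cv$labels), nrow(m))
    out$condition_counts <- table(factor(cv$labels, levels = cv$vocabulary))
  }
  class(out) <- "methgen_validation"
  out
}

#' @export
print.methgen_validation <- function(x, ...) {
  cat(sprintf("%d samples x %d CpGs; %d missing entries (%.2f%%)\n",
              x$n_samples, x$n_cpgs, x$n_missing, 100 * x$missing_fraction))
  if (length(x$all_missing_cpgs) > 0)
    cat(sprintf("CpGs missing in all samples: %d\n", length(x$all_missing_cpgs)))
  if (!is.null(x$condition_counts)) {
    cat("samples per condition:\n")
    print(x$condition_counts)
  }
  invisible(x)
}
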