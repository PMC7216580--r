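#' Remove CpG sites missing in every sample
#'
#' First preprocessing step: a CpG column whose entries are all missing
#' carries no information and is dropped. Columns are otherwise kept in their
#' input order.
#'
#' @param m a \code{\link{beta_matrix}}.
#' @return list with \code{matrix} (the filtered \code{beta_matrix}) and
#'   \code{removed} (character vector of dropped CpG IDs).
#' @export
drop_all_missing_cpgs <- function(m) {
  validate_beta_matrix(m)
  all_missing <- colSums(!is.na(m)) == 0 & nrow(m) > 0
  removed <- colnames(m)[all_missing]
  if (ncol(m) > 0 && all(all_missing)) stopf("no CpGs remain")
  list(matrix = m[, !all_missing], removed = removed)
}

#' Split a beta matrix into consecutive CpG chunks
#'
#' The dataset is divided into subsets of \code{chunk_size} CpGs each (default
#' 10,000) so that downstream outlier removal can retain samples that are
#' complete within a chunk even if they have missing values elsewhere. The
#' last chunk holds the remainder; chunk boundaries follow input column order.
#'
#' @param m a \code{beta_matrix}.
#' @param chunk_size positive integer, CpGs per chunk.
#' @return a \code{chunked_dataset}: list with \code{chunks} (list of
#'   \code{beta_matrix}) and \code{chunk_size}.
#' @export
chunk_cpgs <- function(m, chunk_size = 10000) {
  stopifnot(chunk_size >= 1)
  validate_beta_matrix(m)
  p <- ncol(m)
  n_chunks <- if (p == 0) 0 else ceiling(p / chunk_size)
  chunks <- lapply(seq_len(n_chunks), function(i) {
    j <- ((i - 1) * chunk_size + 1):min(i * chunk_size, p)
    m[, j]
  })
  structure(list(chunks = chunks, chunk_size = as.integer(chunk_size)),
            class = "chunked_dataset")
}

#' @export
print.chunked_dataset <- function(x, ...) {
  cat(sprintf("chunked_dataset: %d chunks (chunk_size %d)\n",
              length(x$chunks), x$chunk_size))
  for (i in seq_along(x$chunks))
    cat(sprintf("  chunk %d: %d samples x %d CpGs, %d missing\n", i,
                nrow(x$chunks[[i]]), ncol(x$chunks[[i]]), sum(is.na(x$chunks[[i]]))))
  invisible(x)
}

#' Remove samples with outlying missing-value counts (Tukey fence)
#'
#' Within a chunk, samples carrying a significant number of missing values are
#' discarded. Per-sample missing counts are summarized by their quartiles
#' (type-7 linear interpolation, the \code{\link[stats]{quantile}} default)
#' and samples whose count exceeds the upper Tukey fence
#' \code{Q3 + whisker * IQR} are removed. The rule is one-sided: unusually
#' complete samples are never penalized.
#'
#' @param chunk a \code{beta_matrix} (one CpG chunk).
#' @param whisker fence multiplier, default 1.5.
#' @return list with \code{matrix} (retained samples) and \code{removed}
#'   (character vector of removed sample IDs).
#' @export
remove_outlier_samples_iqr <- function(chunk, whisker = 1.5) {
  validate_beta_matrix(chunk)
  counts <- rowSums(is.na(chunk))
  if (nrow(chunk) == 0) return(list(matrix = chunk, removed = character(0)))
  q <- stats::quantile(counts, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + whisker * (q[2] - q[1])
  drop <- counts > fence
  if (all(drop)) stopf("no samples remain in chunk")
  list(matrix = chunk[!drop, ], removed = rownames(chunk)[drop])
}

#' Impute remaining missing values with per-CpG medians
#'
#' Each missing entry is replaced by the median of that CpG's observed values
#' within the chunk, across all retained samples.
#'
#' @param chunk a \code{beta_matrix} in which every CpG has at least one
#'   observed value.
#' @return list with \code{matrix} (fully observed \code{beta_matrix}) and
#'   \code{n_imputed} (number of entries filled in).
#' @export
impute_median <- function(chunk) {
  validate_beta_matrix(chunk)
  v <- unclass(chunk)
  miss <- is.na(v)
  n_imputed <- sum(miss)
  if (n_imputed > 0) {
    no_obs <- colSums(!miss) == 0
    if (any(no_obs))
      stopf("CpG(s) with zero observed values in chunk: %s",
            paste(colnames(v)[no_obs], collapse = ", "))
    med <- apply(v, 2, stats::median, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    v[idx] <- med[idx[, 2]]
  }
  list(matrix = beta_matrix(v), n_imputed = n_imputed)
}

#' Four-step missing-value preprocessing pipeline
#'
#' Controls the bias a high frequency of missing values would introduce into
#' model training: (1) drop CpGs missing in all samples, (2) split the matrix
#' into consecutive chunks of \code{chunk_size} CpGs, (3) within each chunk
#' remove samples whose missing-value count lies above the upper Tukey fence,
#' (4) impute the remaining missing entries with per-CpG within-chunk medians.
#' Sample removal is per chunk, so a sample dropped from one chunk can still
#' contribute to others.
#'
#' If outlier removal leaves a CpG with no observed value inside some chunk,
#' that CpG is dropped from the chunk (recorded in the report) rather than
#' imputed from nothing; this can only happen under extreme missingness.
#'
#' @param m a \code{beta_matrix}.
#' @param labels optional \code{condition_vector} aligned to \code{m}; when
#'   given, per-chunk label vectors restricted to the retained samples are
#'   returned.
#' @param chunk_size CpGs per chunk, default 10,000.
#' @param whisker Tukey fence multiplier, default 1.5.
#' @return list with \code{chunks} (a \code{chunked_dataset}, fully observed),
#'   \code{labels} (list of per-chunk \code{condition_vector}, or \code{NULL}),
#'   and \code{report} (a \code{preprocess_report}).
#' @export
preprocess_pipeline <- function(m, labels = NULL, chunk_size = 10000, whisker = 1.5) {
  validate_beta_matrix(m)
  if (!is.null(labels) && length(labels$labels) != nrow(m))
    stopf("labels (%d) do not align with samples (%d)", length(labels$labels), nrow(m))

  step1 <- drop_all_missing_cpgs(m)
  chunked <- chunk_cpgs(step1$matrix, chunk_size)

  removed_samples <- vector("list", length(chunked$chunks))
  imputed <- integer(length(chunked$chunks))
  guard_dropped <- character(0)
  out_chunks <- vector("list", length(chunked$chunks))
  out_labels <- if (is.null(labels)) NULL else vector("list", length(chunked$chunks))

  for (i in seq_along(chunked$chunks)) {
    ch <- chunked$chunks[[i]]
    step3 <- tryCatch(remove_outlier_samples_iqr(ch, whisker),
                      error = function(e) stopf("chunk %d: %s", i, conditionMessage(e)))
    kept <- step3$matrix
    # chunk-level guard: a CpG can lose all its observations with its samples
    no_obs <- colSums(!is.na(kept)) == 0 & nrow(kept) > 0
    if (any(no_obs)) {
      guard_dropped <- c(guard_dropped, colnames(kept)[no_obs])
      kept <- kept[, !no_obs]
    }
    step4 <- tryCatch(impute_median(kept),
                      error = function(e) stopf("chunk %d: %s", i, conditionMessage(e)))
    out_chunks[[i]] <- step4$matrix
    removed_samples[[i]] <- step3$removed
    imputed[i] <- step4$n_imputed
    if (!is.null(labels)) {
      idx <- match(rownames(step4$matrix), rownames(m))
      out_labels[[i]] <- subset_conditions(labels, idx)
    }
  }

  report <- structure(list(
    removed_cpgs = c(step1$removed, guard_dropped),
    removed_samples_per_chunk = removed_samples,
    imputed_count_per_chunk = imputed,
    thresholds = list(chunk_size = chunk_size, whisker = whisker)
  ), class = "preprocess_report")

  list(chunks = structure(list(chunks = out_chunks,
                               chunk_size = as.integer(chunk_size)),
                          class = "chunked_dataset"),
       labels = out_labels,
       report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report (chunk_size %d, whisker %.2f)\n",
              x$thresholds$chunk_size, x$thresholds$whisker))
  cat(sprintf("  CpGs removed: %d\n", length(x$removed_cpgs)))
  cat(sprintf("  samples removed per chunk: %s\n",
              paste(lengths(x$removed_samples_per_chunk), collapse = ", ")))
  cat(sprintf("  values imputed per chunk: %s\n",
              paste(x$imputed_count_per_chunk, collapse = ", ")))
  invisible(x)
}
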