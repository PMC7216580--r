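#' Construct a beta-value matrix
#'
#' The package's universal exchange container for methylation data: a numeric
#' matrix of beta values in \code{[0, 1]} with samples as rows and CpG sites as
#' columns. Missing entries are \code{NA}. Row and column names carry the
#' sample and CpG identifiers and must be unique.
#'
#' @param values numeric matrix (samples x CpGs); entries in \code{[0, 1]} or
#'   \code{NA}.
#' @param sample_ids,cpg_ids optional character vectors overriding the
#'   dimnames of \code{values}.
#' @param tol values outside \code{[0, 1]} by at most \code{tol} are clamped to
#'   the boundary; beyond that a validation error is raised.
#' @return an object of class \code{beta_matrix} (a classed numeric matrix).
#' @examples
#' m <- beta_matrix(matrix(c(0.1, 0.9, NA, 0.5), 2,
#'   dimnames = list(c("s1", "s2"), c("cg1", "cg2"))))
#' dim(m)
#' @export
beta_matrix <- function(values, sample_ids = NULL, cpg_ids = NULL, tol = 1e-9) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (!is.null(cpg_ids)) colnames(values) <- cpg_ids
  if (nrow(values) > 0 && is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (ncol(values) > 0 && is.null(colnames(values)))
    colnames(values) <- paste0("cpg_", seq_len(ncol(values)))
  # clamp sub-tolerance numerical overshoot only; real out-of-range is an error
  values[!is.na(values) & values < 0 & values >= -tol] <- 0
  values[!is.na(values) & values > 1 & values <= 1 + tol] <- 1
  m <- structure(values, class = c("beta_matrix", "matrix", "array"))
  validate_beta_matrix(m, tol = tol)
  m
}

validate_beta_matrix <- function(m, tol = 1e-9) {
  v <- unclass(m)
  bad <- which(!is.na(v) & (v < -tol | v > 1 + tol), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf(
      "beta values outside [0, 1]: first offender %s / %s = %g",
      rownames(v)[bad[1, 1]] %||% bad[1, 1],
      colnames(v)[bad[1, 2]] %||% bad[1, 2],
      v[bad[1, 1], bad[1, 2]]
    )
  }
  if (anyDuplicated(rownames(v)))
    stopf("duplicate sample IDs: %s",
          paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stopf("duplicate CpG IDs: %s",
          paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  invisible(m)
}

#' @export
`[.beta_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  structure(out, class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d samples x %d CpGs, %d missing entries\n",
              nrow(x), ncol(x), sum(is.na(x))))
  if (nrow(x) > 0 && ncol(x) > 0) {
    show <- unclass(x)[seq_len(min(4, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE]
    print(round(show, 4))
    if (nrow(x) > 4 || ncol(x) > 6) cat("...\n")
  }
  invisible(x)
}

#' Sample and CpG identifiers of a beta matrix
#' @param m a \code{beta_matrix}.
#' @return character vector of IDs.
#' @export
sample_ids <- function(m) rownames(m)

#' @rdname sample_ids
#' @export
cpg_ids <- function(m) colnames(m)

#' Construct a per-sample condition vector
#'
#' Categorical condition labels (e.g. cancer types) with a fixed vocabulary
#' and a derived one-hot encoding; this is the condition the generative models
#' are trained on and sampled from.
#'
#' @param labels character vector, one label per sample.
#' @param vocabulary optional ordered unique label set; defaults to the sorted
#'   unique labels. Every label must appear in it.
#' @return an object of class \code{condition_vector} with fields
#'   \code{labels}, \code{vocabulary} and \code{one_hot} (n x K indicator
#'   matrix, rows summing to 1).
#' @examples
#' cv <- condition_vector(c("BRCA", "LUAD", "BRCA"))
#' cv$vocabulary
#' colSums(cv$one_hot)
#' @export
condition_vector <- function(labels, vocabulary = NULL) {
  labels <- as.character(labels)
  if (is.null(vocabulary)) vocabulary <- sort(unique(labels))
  vocabulary <- as.character(vocabulary)
  if (anyDuplicated(vocabulary)) stopf("vocabulary contains duplicates")
  unknown <- setdiff(labels, vocabulary)
  if (length(unknown) > 0)
    stopf("labels not in vocabulary: %s", paste(unique(unknown), collapse = ", "))
  oh <- matrix(0, nrow = length(labels), ncol = length(vocabulary),
               dimnames = list(NULL, vocabulary))
  if (length(labels) > 0)
    oh[cbind(seq_along(labels), match(labels, vocabulary))] <- 1
  structure(list(labels = labels, vocabulary = vocabulary, one_hot = oh),
            class = "condition_vector")
}

#' @export
print.condition_vector <- function(x, ...) {
  cat(sprintf("condition_vector: %d samples, %d conditions\n",
              length(x$labels), length(x$vocabulary)))
  print(table(factor(x$labels, levels = x$vocabulary)))
  invisible(x)
}

#' Decode a one-hot condition encoding back to labels
#' @param one_hot indicator matrix with vocabulary column names.
#' @param vocabulary optional vocabulary; defaults to the matrix column names.
#' @return character vector of labels.
#' @export
decode_one_hot <- function(one_hot, vocabulary = colnames(one_hot)) {
  if (any(abs(rowSums(one_hot) - 1) > 1e-12))
    stopf("one-hot rows must sum to 1")
  vocabulary[max.col(one_hot, ties.method = "first")]
}

# restrict a condition vector to a subset of its samples (by index),
# keeping the full vocabulary
subset_conditions <- function(cv, idx) {
  condition_vector(cv$labels[idx], vocabulary = cv$vocabulary)
}
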