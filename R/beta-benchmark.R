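#' Method-of-moments fit of a beta distribution
#'
#' Matches the sample mean \code{m} and variance \code{v} of clipped values to
#' the analytic moments of \code{Beta(alpha, beta)}:
#' \code{alpha = m * c}, \code{beta = (1 - m) * c} with
#' \code{c = m (1 - m) / v - 1}. The fitted distribution's analytic mean and
#' variance equal the sample moments exactly.
#'
#' @param values numeric vector of observed beta values in \code{[0, 1]}
#'   (missing entries are removed).
#' @param eps boundary clip applied before computing moments; beta moments
#'   degenerate at exact 0/1, which occur in array data.
#' @param min_n minimum number of observations required.
#' @return list with positive \code{alpha} and \code{beta}.
#' @examples
#' fit_beta_mom(c(0.5 - sqrt(0.1) / 2, 0.5 + sqrt(0.1) / 2))  # Beta(2, 2)
#' @export
fit_beta_mom <- function(values, eps = 1e-6, min_n = 2) {
  x <- clip_unit(values[!is.na(values)], eps)
  if (length(x) < min_n)
    stopf("need at least %d observed values, got %d", min_n, length(x))
  m <- mean(x)
  v <- stats::var(x)
  if (v <= 0) stopf("degenerate distribution: zero variance")
  if (v >= m * (1 - m))
    stopf("moment-infeasible: variance %g >= m(1-m) = %g", v, m * (1 - m))
  conc <- m * (1 - m) / v - 1
  list(alpha = m * conc, beta = (1 - m) * conc)
}

new_beta_param_table <- function(df) {
  stopifnot(all(c("cpg_id", "condition", "alpha", "beta", "n_obs",
                  "fit_method", "fallback") %in% names(df)))
  if (any(df$alpha <= 0) || any(df$beta <= 0))
    stopf("beta parameters must be strictly positive")
  structure(df, class = c("beta_param_table", "data.frame"))
}

#' Fit per-(CpG, condition) beta distributions
#'
#' The benchmark generator's model: for every CpG site and every condition, a
#' \code{Beta(alpha, beta)} distribution is fitted to the observed values by
#' the method of moments. Cells with too few observations, zero variance or
#' moment-infeasible variance receive a mean-preserving point-mass surrogate
#' \code{Beta(m * kappa, (1 - m) * kappa)} with a large concentration
#' \code{kappa}, and are flagged.
#'
#' @param data a \code{beta_matrix}, or a \code{chunked_dataset} (chunks are
#'   recombined; a sample contributes to the CpGs of every chunk that retained
#'   it).
#' @param labels a \code{\link{condition_vector}} aligned to \code{data}, or a
#'   per-chunk list when \code{data} is chunked.
#' @param min_n minimum observations for a method-of-moments fit (default 3).
#' @param eps boundary clip before fitting.
#' @param fallback_concentration \code{kappa} of the surrogate (default 1000).
#' @return a \code{beta_param_table}: data frame with columns \code{cpg_id},
#'   \code{condition}, \code{alpha}, \code{beta}, \code{n_obs},
#'   \code{fit_method}, \code{fallback}.
#' @export
fit_table <- function(data, labels, min_n = 3, eps = 1e-6,
                      fallback_concentration = 1000) {
  if (inherits(data, "chunked_dataset")) {
    if (inherits(labels, "condition_vector"))
      labels <- rep(list(labels), length(data$chunks))
    parts <- Map(function(ch, cv) fit_table(ch, cv, min_n = min_n, eps = eps,
                                            fallback_concentration = fallback_concentration),
                 data$chunks, labels)
    return(new_beta_param_table(do.call(rbind, parts)))
  }
  stopifnot(inherits(data, "beta_matrix"), inherits(labels, "condition_vector"))
  if (length(labels$labels) != nrow(data))
    stopf("labels do not align with samples")
  vocab <- labels$vocabulary
  counts <- table(factor(labels$labels, levels = vocab))
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0)
    stopf("condition(s) with zero samples: %s", paste(empty, collapse = ", "))

  res <- vector("list", length(vocab))
  for (k in seq_along(vocab)) {
    sub <- unclass(data)[labels$labels == vocab[k], , drop = FALSE]
    subc <- clip_unit(sub, eps)
    n_obs <- colSums(!is.na(sub))
    m <- colMeans(subc, na.rm = TRUE)
    v <- apply(subc, 2, stats::var, na.rm = TRUE)
    m[is.nan(m)] <- 0.5                       # cell with zero observations
    v[is.na(v)] <- 0
    feasible <- n_obs >= min_n & v > 0 & v < m * (1 - m)
    conc <- ifelse(feasible, m * (1 - m) / v - 1, fallback_concentration)
    res[[k]] <- data.frame(
      cpg_id = colnames(data), condition = vocab[k],
      alpha = m * conc, beta = (1 - m) * conc, n_obs = n_obs,
      fit_method = ifelse(feasible, "mom", "fallback"),
      fallback = !feasible, row.names = NULL)
  }
  new_beta_param_table(do.call(rbind, res))
}

#' @export
print.beta_param_table <- function(x, ...) {
  cat(sprintf("beta_param_table: %d CpGs x %d conditions, %d fallback cells\n",
              length(unique(x$cpg_id)), length(unique(x$condition)), sum(x$fallback)))
  NextMethod()
}

#' Sample simulated methylomes from a fitted beta-parameter table
#'
#' Each cell of the output is drawn independently from the
#' \code{Beta(alpha, beta)} distribution of its (CpG, condition) entry.
#'
#' @param table a \code{beta_param_table}.
#' @param condition condition to simulate; must be present in the table.
#' @param n_samples number of samples.
#' @param seed integer seed; identical inputs give identical matrices.
#' @return a \code{\link{beta_matrix}} (rows \code{"<condition>_sim_<k>"}),
#'   values strictly inside (0, 1).
#' @export
sample_benchmark <- function(table, condition, n_samples, seed = 1) {
  stopifnot(inherits(table, "beta_param_table"), n_samples >= 0)
  conds <- unique(table$condition)
  if (!(condition %in% conds))
    stopf("unknown condition '%s'; table covers: %s", condition,
          paste(conds, collapse = ", "))
  sub <- table[table$condition == condition, , drop = FALSE]
  sub <- sub[match(unique(table$cpg_id), sub$cpg_id), , drop = FALSE]
  p <- nrow(sub)
  set.seed(as.integer(seed))
  # column-major fill: all n draws for CpG 1, then CpG 2, ...
  draws <- stats::rbeta(n_samples * p,
                        shape1 = rep(sub$alpha, each = n_samples),
                        shape2 = rep(sub$beta, each = n_samples))
  values <- matrix(pmin(pmax(draws, 1e-12), 1 - 1e-12), nrow = n_samples, ncol = p)
  colnames(values) <- sub$cpg_id
  rownames(values) <- if (n_samples > 0)
    sprintf("%s_sim_%d", condition, seq_len(n_samples)) else character(0)
  beta_matrix(values)
}

#' Read / write a beta-parameter table as TSV
#' @param table a \code{beta_param_table}.
#' @param path file path.
#' @return \code{read_beta_param_table} returns the table.
#' @export
write_beta_param_table <- function(table, path) {
  stopifnot(inherits(table, "beta_param_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_param_table
#' @export
read_beta_param_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$fallback <- as.logical(df$fallback)
  new_beta_param_table(df)
}
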