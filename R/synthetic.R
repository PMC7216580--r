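#' Specification for a synthetic ground-truth methylome dataset
#'
#' Describes a dataset with the statistical structure the generators assume:
#' per-CpG, per-condition beta-distributed values whose means separate the
#' conditions at a controllable fraction of "informative" CpGs, optionally
#' with injected missingness. Used to test every other module without any
#' external download.
#'
#' At an informative CpG the conditions receive K equally spaced means
#' (spacing \code{mean_separation}, randomly permuted across conditions), so
#' \code{mean_separation} is the minimum pairwise mean difference there.
#' Feasibility requires \code{mean_separation * (n_conditions - 1) <= 0.9}
#' (means are kept inside \code{[0.05, 0.95]}). Uninformative CpGs share one
#' set of parameters across all conditions.
#'
#' @param n_conditions number of condition labels.
#' @param n_cpgs number of CpG sites.
#' @param n_samples_per_condition samples per condition; a single number or a
#'   vector of per-condition counts (unequal class sizes, as in real cohorts).
#' @param mean_separation target minimum |mean difference| between conditions
#'   at informative CpGs, in \code{[0, 1]}.
#' @param frac_informative fraction of CpGs that separate the conditions.
#' @param concentration_range range of \code{alpha + beta} of the generating
#'   beta distributions, drawn uniformly per CpG. The default 20-60 gives
#'   within-condition standard deviations of roughly 0.05-0.11 at
#'   intermediate means, typical of 450K beta values.
#' @param missing_rate background fraction of entries masked at random.
#' @param outlier_samples number of samples given inflated missingness.
#' @param outlier_rate missingness rate of the outlier samples.
#' @param seed integer seed.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_conditions = 4,
                           n_cpgs = 200,
                           n_samples_per_condition = 150,
                           mean_separation = 0.3,
                           frac_informative = 0.5,
                           concentration_range = c(20, 60),
                           missing_rate = 0,
                           outlier_samples = 0,
                           outlier_rate = 0.6,
                           seed = 1L) {
  stopifnot(n_conditions >= 1, n_cpgs >= 0,
            all(n_samples_per_condition >= 0),
            mean_separation >= 0, mean_separation <= 1,
            frac_informative >= 0, frac_informative <= 1,
            length(concentration_range) == 2, all(concentration_range > 0),
            missing_rate >= 0, missing_rate < 1,
            outlier_samples >= 0, outlier_rate >= 0, outlier_rate < 1)
  margin <- 0.05
  if (n_conditions > 1 && mean_separation * (n_conditions - 1) > 1 - 2 * margin + 1e-12)
    stopf("infeasible spec: mean_separation %.3g with %d conditions needs a mean span of %.3g > %.2f",
          mean_separation, n_conditions, mean_separation * (n_conditions - 1),
          1 - 2 * margin)
  n_per <- rep_len(as.integer(n_samples_per_condition), n_conditions)
  structure(list(n_conditions = as.integer(n_conditions),
                 n_cpgs = as.integer(n_cpgs),
                 n_samples_per_condition = n_per,
                 mean_separation = mean_separation,
                 frac_informative = frac_informative,
                 concentration_range = concentration_range,
                 missing_rate = missing_rate,
                 outlier_samples = as.integer(outlier_samples),
                 outlier_rate = outlier_rate,
                 seed = as.integer(seed), margin = margin),
            class = "synthetic_spec")
}

condition_names <- function(k) {
  if (k <= 26) paste0("cond", LETTERS[seq_len(k)]) else paste0("cond", seq_len(k))
}

#' Generate a ground-truth synthetic methylome dataset
#'
#' Draws generating \code{Beta(alpha, beta)} parameters for every
#' (CpG, condition) cell per the spec, samples all values, optionally injects
#' missingness, and returns the true parameter table so that recovery can be
#' tested. Fully reproducible under \code{spec$seed}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{matrix} (a \code{beta_matrix}), \code{labels} (a
#'   \code{condition_vector}), \code{true_params} (a \code{beta_param_table}
#'   with \code{fit_method = "truth"}), \code{informative_cpgs} (character),
#'   and, when missingness was injected, \code{mask} / \code{outlier_ids} /
#'   \code{all_missing_cpg} from \code{\link{inject_missing}}.
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  K <- spec$n_conditions
  p <- spec$n_cpgs
  conds <- condition_names(K)
  n_per <- spec$n_samples_per_condition
  labels <- rep(conds, times = n_per)
  n <- length(labels)
  s <- spec$mean_separation
  margin <- spec$margin

  n_inf <- round(spec$frac_informative * p)
  informative <- sort(sample.int(p, n_inf))
  is_inf <- seq_len(p) %in% informative

  conc <- stats::runif(p, spec$concentration_range[1], spec$concentration_range[2])
  means <- matrix(0, nrow = p, ncol = K)   # per-CpG per-condition true means
  hi <- 1 - margin - s * (K - 1)
  for (j in seq_len(p)) {
    if (is_inf[j] && K > 1) {
      base <- stats::runif(1, margin, max(margin, hi))
      means[j, ] <- (base + s * (seq_len(K) - 1))[sample.int(K)]
    } else {
      means[j, ] <- stats::runif(1, margin, 1 - margin)
    }
  }

  cpgs <- sprintf("cg%05d", seq_len(p))
  values <- matrix(NA_real_, n, p, dimnames = list(NULL, cpgs))
  for (k in seq_len(K)) {
    rows <- which(labels == conds[k])
    a <- means[, k] * conc
    b <- (1 - means[, k]) * conc
    draws <- stats::rbeta(length(rows) * p,
                          shape1 = rep(a, each = length(rows)),
                          shape2 = rep(b, each = length(rows)))
    values[rows, ] <- matrix(pmin(pmax(draws, 1e-12), 1 - 1e-12),
                             nrow = length(rows))
  }
  rownames(values) <- sprintf("%s_s%03d", labels, stats::ave(seq_len(n), labels,
                                                             FUN = seq_along))
  m <- beta_matrix(values)
  cv <- condition_vector(labels, vocabulary = sort(conds))

  true_params <- new_beta_param_table(data.frame(
    cpg_id = rep(cpgs, times = K),
    condition = rep(conds, each = p),
    alpha = as.vector(means * rep(conc, K)),
    beta = as.vector((1 - means) * rep(conc, K)),
    n_obs = rep(n_per, each = p),
    fit_method = "truth", fallback = FALSE, row.names = NULL))

  out <- list(matrix = m, labels = cv, true_params = true_params,
              informative_cpgs = cpgs[is_inf], spec = spec)
  if (spec$missing_rate > 0 || spec$outlier_samples > 0) {
    inj <- inject_missing(m, spec$missing_rate, spec$outlier_samples,
                          spec$outlier_rate, seed = make_seed(spec$seed, 7919))
    out$matrix <- inj$matrix
    out$mask <- inj$mask
    out$outlier_ids <- inj$outlier_ids
  }
  out
}

#' Inject controlled missingness into a beta matrix
#'
#' Masks entries completely at random at \code{missing_rate}, except for a
#' designated set of outlier samples masked at the higher
#' \code{outlier_rate} — exactly the structure the preprocessing pipeline is
#' built to detect. Optionally one randomly chosen CpG is masked across all
#' samples (to exercise all-missing-CpG removal).
#'
#' @param m a \code{beta_matrix} without missing values.
#' @param missing_rate background masking rate in \code{[0, 1)}.
#' @param outlier_samples number of randomly chosen outlier samples.
#' @param outlier_rate masking rate for outlier samples; must exceed
#'   \code{missing_rate} when outliers are requested.
#' @param seed integer seed.
#' @param mask_full_cpg also mask one CpG across all samples.
#' @return list with \code{matrix} (masked \code{beta_matrix}), \code{mask}
#'   (logical matrix of masked positions), \code{outlier_ids} (sample IDs) and
#'   \code{all_missing_cpg} (CpG ID or \code{NA}).
#' @export
inject_missing <- function(m, missing_rate, outlier_samples = 0,
                           outlier_rate = 0.6, seed = 1, mask_full_cpg = FALSE) {
  stopifnot(inherits(m, "beta_matrix"),
            missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1)
  if (outlier_samples > nrow(m))
    stopf("outlier_samples (%d) exceeds sample count (%d)", outlier_samples, nrow(m))
  if (outlier_samples > 0 && outlier_rate <= missing_rate)
    stopf("outlier_rate must exceed missing_rate")
  set.seed(as.integer(seed))
  n <- nrow(m); p <- ncol(m)
  out_idx <- if (outlier_samples > 0) sample.int(n, outlier_samples) else integer(0)
  rate <- rep(missing_rate, n)
  rate[out_idx] <- outlier_rate
  mask <- matrix(stats::runif(n * p), n, p) < rate   # row rates recycle column-major
  full_cpg <- NA_character_
  if (mask_full_cpg && p > 0) {
    j <- sample.int(p, 1)
    mask[, j] <- TRUE
    full_cpg <- colnames(m)[j]
  }
  v <- unclass(m)
  v[mask] <- NA_real_
  dimnames(mask) <- dimnames(v)
  list(matrix = beta_matrix(v), mask = mask,
       outlier_ids = rownames(m)[out_idx], all_missing_cpg = full_cpg)
}
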