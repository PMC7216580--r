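mk <- function(v, samples = NULL, cpgs = NULL) {
  beta_matrix(v, sample_ids = samples %||% paste0("s", seq_len(nrow(v))),
              cpg_ids = cpgs %||% paste0("cg", seq_len(ncol(v))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("all-missing CpGs are removed and partially missing ones kept", {
  v <- matrix(c(0.1, 0.2, 0.3,  NA, NA, NA,  NA, NA, 0.9), 3)
  r <- drop_all_missing_cpgs(mk(v))
  expect_equal(r$removed, "cg2")
  expect_equal(cpg_ids(r$matrix), c("cg1", "cg3"))  # order preserved, cg3 kept

  clean <- mk(matrix(runif(6), 2))
  r2 <- drop_all_missing_cpgs(clean)
  expect_identical(unclass(r2$matrix), unclass(clean))
  expect_length(r2$removed, 0)

  expect_error(drop_all_missing_cpgs(mk(matrix(NA_real_, 2, 2))), "no CpGs remain")
})

test_that("chunking produces consecutive blocks with a remainder", {
  m <- mk(matrix(runif(2 * 25000), 2))
  ch <- chunk_cpgs(m, 10000)
  expect_equal(vapply(ch$chunks, ncol, 1L), c(10000L, 10000L, 5000L))
  expect_identical(unlist(lapply(ch$chunks, cpg_ids), use.names = FALSE), cpg_ids(m))

  small <- chunk_cpgs(mk(matrix(runif(20), 2)), 10000)
  expect_length(small$chunks, 1)
  expect_equal(ncol(small$chunks[[1]]), 10L)

  none <- chunk_cpgs(beta_matrix(matrix(numeric(0), 3, 0,
                                        dimnames = list(paste0("s", 1:3), NULL))), 10)
  expect_length(none$chunks, 0)
})

test_that("IQR outlier removal uses the one-sided type-7 Tukey fence", {
  # missing counts 1,2,3,4,100: Q1 = 2, Q3 = 4, fence = 4 + 1.5*2 = 7
  v <- matrix(runif(5 * 100), 5)
  for (i in 1:5) v[i, seq_len(c(1, 2, 3, 4, 100)[i])] <- NA
  r <- remove_outlier_samples_iqr(mk(v))
  expect_equal(r$removed, "s5")
  expect_equal(nrow(r$matrix), 4)

  # identical counts: IQR = 0, fence = count, nothing removed
  u <- matrix(runif(4 * 10), 4); u[, 1] <- NA
  expect_length(remove_outlier_samples_iqr(mk(u))$removed, 0)

  # no missing values at all
  expect_length(remove_outlier_samples_iqr(mk(matrix(runif(40), 4)))$removed, 0)
})

test_that("median imputation fills per-CpG within-chunk medians", {
  v <- cbind(c(0.2, NA, 0.4), c(0.1, 0.1, 0.9), c(0.5, 0.5, 0.5))
  v2 <- v; v2[3, 2] <- NA  # column becomes 0.1, 0.1, NA -> but use 4-sample case below
  r <- impute_median(mk(v))
  expect_equal(unclass(r$matrix)[2, 1], 0.3)
  expect_equal(r$n_imputed, 1)
  expect_equal(unclass(r$matrix)[, 3], c(0.5, 0.5, 0.5), ignore_attr = TRUE)

  w <- matrix(c(0.1, 0.1, NA, 0.9), 4, 1)
  expect_equal(unclass(impute_median(mk(w))$matrix)[3, 1], 0.1)

  none <- mk(matrix(runif(9), 3))
  rn <- impute_median(none)
  expect_identical(unclass(rn$matrix), unclass(none))
  expect_equal(rn$n_imputed, 0)

  bad <- mk(cbind(c(0.1, 0.2), c(NA, NA)))
  expect_error(impute_median(bad), "zero observed")
})

test_that("pipeline is a no-op on clean data and matches the naive oracle on noisy data", {
  clean <- generate_ground_truth(synthetic_spec(
    n_conditions = 2, n_cpgs = 30, n_samples_per_condition = 10, seed = 5))
  res <- preprocess_pipeline(clean$matrix, clean$labels, chunk_size = 20)
  expect_length(res$report$removed_cpgs, 0)
  expect_equal(sum(lengths(res$report$removed_samples_per_chunk)), 0)
  expect_equal(sum(res$report$imputed_count_per_chunk), 0)
  expect_identical(do.call(cbind, lapply(res$chunks$chunks, unclass)),
                   unclass(clean$matrix))

  for (seed in 1:5) {
    gt <- generate_ground_truth(synthetic_spec(
      n_conditions = 2, n_cpgs = 80, n_samples_per_condition = 15,
      missing_rate = 0.02, outlier_samples = 2, outlier_rate = 0.6, seed = seed))
    res <- preprocess_pipeline(gt$matrix, gt$labels, chunk_size = 30)
    ora <- naive_preprocess(gt$matrix, chunk_size = 30)
    expect_identical(res$report$removed_cpgs, ora$removed_cpgs)
    expect_identical(res$report$removed_samples_per_chunk, ora$removed_samples)
    expect_identical(unname(res$report$imputed_count_per_chunk), unname(ora$imputed))
    for (i in seq_along(ora$chunks))
      expect_identical(unclass(res$chunks$chunks[[i]]), ora$chunks[[i]])
    expect_false(any(vapply(res$chunks$chunks, anyNA, TRUE)))
  }
})

test_that("a pervasively missing sample is removed from every chunk", {
  set.seed(9)
  v <- matrix(runif(20 * 60), 20)
  v[cbind(sample(1:19, 10, TRUE), sample(1:60, 10, TRUE))] <- NA  # <1% background
  v[20, sample(60, 54)] <- NA                                     # 90% missing
  res <- preprocess_pipeline(mk(v), chunk_size = 20)
  for (rm in res$report$removed_samples_per_chunk) expect_true("s20" %in% rm)
})

test_that("pipeline is idempotent and preserves retained values bit-for-bit", {
  gt <- generate_ground_truth(synthetic_spec(
    n_conditions = 2, n_cpgs = 50, n_samples_per_condition = 12,
    missing_rate = 0.05, outlier_samples = 1, seed = 8))
  res <- preprocess_pipeline(gt$matrix, gt$labels, chunk_size = 25)
  for (i in seq_along(res$chunks$chunks)) {
    ch <- res$chunks$chunks[[i]]
    again <- preprocess_pipeline(ch, res$labels[[i]], chunk_size = 25)
    expect_identical(unclass(again$chunks$chunks[[1]]), unclass(ch))
    expect_equal(sum(again$report$imputed_count_per_chunk), 0)
    expect_length(unlist(again$report$removed_samples_per_chunk), 0)

    # retained cells bit-identical to the input where observed
    orig <- unclass(gt$matrix)[rownames(ch), colnames(ch)]
    obs <- !is.na(orig)
    expect_identical(unclass(ch)[obs], orig[obs])
    # monotonicity
    expect_true(all(rownames(ch) %in% sample_ids(gt$matrix)))
    expect_true(all(colnames(ch) %in% cpg_ids(gt$matrix)))
  }
})
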