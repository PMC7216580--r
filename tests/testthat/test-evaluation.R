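# shared separable fixture: 3 conditions, modest size, trained classifiers
eval_fix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- generate_ground_truth(synthetic_spec(
        n_conditions = 3, n_cpgs = 50, n_samples_per_condition = 40,
        mean_separation = 0.4, frac_informative = 0.6, seed = 19))
      sp <- split_data(gt$matrix, gt$labels, seed = 19)
      clfs <- train_classifiers(sp$classifier$matrix, sp$classifier$labels, seed = 19)
      cache <<- list(gt = gt, sp = sp, clfs = clfs)
    }
    cache
  }
})

test_that("stratified splitting is disjoint, exhaustive and proportional", {
  fx <- eval_fix()
  sp <- fx$sp
  gids <- sample_ids(sp$generator$matrix)
  cids <- sample_ids(sp$classifier$matrix)
  expect_length(intersect(gids, cids), 0)
  expect_setequal(c(gids, cids), sample_ids(fx$gt$matrix))
  for (cond in fx$gt$labels$vocabulary) {
    n_gen <- sum(sp$generator$labels$labels == cond)
    expect_lte(abs(n_gen - 0.7 * 40), 1)
  }
  # reproducible under the seed
  sp2 <- split_data(fx$gt$matrix, fx$gt$labels, seed = 19)
  expect_identical(sample_ids(sp2$generator$matrix), gids)

  tiny <- beta_matrix(matrix(runif(3 * 4), 3, dimnames = list(paste0("s", 1:3), NULL)))
  expect_error(split_data(tiny, condition_vector(c("A", "A", "B"))),
               "fewer than 2.*B")
})

test_that("classifiers train on separable data and beat chance on their training set", {
  fx <- eval_fix()
  train <- fx$sp$classifier
  gen_list <- lapply(fx$gt$labels$vocabulary, function(cond) {
    list(matrix = train$matrix[train$labels$labels == cond, ], condition = cond)
  })
  ev <- evaluate_generated(fx$clfs, gen_list)
  for (alg in names(ev$per_classifier))
    expect_gt(ev$per_classifier[[alg]]$accuracy, 1 / 3)
  expect_gte(ev$per_classifier$SVM$accuracy, 0.95)

  expect_error(train_classifiers(train$matrix, train$labels, algorithms = "XGB"),
               "unknown algorithm")
  one <- condition_vector(rep("A", nrow(train$matrix)))
  expect_error(train_classifiers(train$matrix, one), "at least 2 conditions")
})

test_that("one-vs-rest AUC matches the exhaustive pair-counting oracle", {
  s <- matrix(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), ncol = 1, dimnames = list(NULL, "A"))
  intended <- c("A", "A", "A", "B", "B", "B")
  expect_equal(unname(one_vs_rest_auc(s, intended)["A"]), 1.0)

  flat <- matrix(1, 6, 1, dimnames = list(NULL, "A"))
  expect_equal(unname(one_vs_rest_auc(flat, intended)["A"]), 0.5)

  # hand-worked 6-sample list with a tie
  s2 <- matrix(c(0.9, 0.4, 0.65, 0.65, 0.2, 0.5), ncol = 1, dimnames = list(NULL, "A"))
  i2 <- c("A", "A", "A", "B", "B", "B")
  expect_equal(unname(one_vs_rest_auc(s2, i2)["A"]),
               auc_paircount(s2[, 1], i2 == "A"))

  set.seed(23)
  for (r in 1:20) {
    sc <- matrix(sample(seq(0, 1, 0.1), 12, replace = TRUE), ncol = 1,
                 dimnames = list(NULL, "X"))
    lab <- sample(c("X", "Y"), 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(unname(one_vs_rest_auc(sc, lab)["X"]),
                 auc_paircount(sc[, 1], lab == "X"))
  }

  # missing class -> NA
  s3 <- matrix(runif(8), 4, 2, dimnames = list(NULL, c("A", "B")))
  expect_true(is.na(one_vs_rest_auc(s3, rep("A", 4))["B"]))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  sc <- matrix(runif(40), ncol = 1, dimnames = list(NULL, "A"))
  lab <- sample(c("A", "B"), 40, replace = TRUE)
  ours <- unname(one_vs_rest_auc(sc, lab)["A"])
  ref <- as.numeric(pROC::auc(pROC::roc(lab == "A", sc[, 1], quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("evaluation metrics conserve counts and expose mislabeled generators", {
  fx <- eval_fix()
  held <- fx$sp$generator  # samples the classifiers never saw
  a_mat <- held$matrix[held$labels$labels == "condA", ]

  # real condA samples presented as condB: per-condition accuracy for B ~ 0
  ev <- evaluate_generated(fx$clfs, list(list(matrix = a_mat, condition = "condB")))
  for (alg in c("SVM", "RF")) {
    r <- ev$per_classifier[[alg]]
    expect_lte(r$per_condition_accuracy[["condB"]], 0.1)
    expect_equal(sum(r$confusion), nrow(a_mat))
    expect_equal(unname(rowSums(r$confusion)["condB"]), nrow(a_mat))
    expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
    expect_true(all(r$confusion >= 0))
  }

  wrong <- beta_matrix(unclass(a_mat)[, 1:10])
  expect_error(evaluate_generated(fx$clfs, list(list(matrix = wrong, condition = "condA"))),
               "CpG set mismatch")
})

test_that("the comparison protocol reports per-repetition accuracy for both generators", {
  fx <- eval_fix()
  cfg <- cvae_config(encoder_hidden = c(16, 8), latent_dim = 4, epochs = 120,
                     batch_size = 30, seed = 1)
  rep <- compare_generators(fx$gt$matrix, fx$gt$labels,
                            n_generated_per_condition = 15, repetitions = 2,
                            seed = 29, cvae_config = cfg,
                            classifiers = c("SVM", "RF"))
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$accuracy), 2 * 2 * 2)  # generator x classifier x repetition
  expect_setequal(unique(rep$accuracy$generator), c("cvae", "benchmark"))
  expect_true(all(rep$accuracy$accuracy >= 0 & rep$accuracy$accuracy <= 1))
  svm_mean <- tapply(rep$accuracy$accuracy[rep$accuracy$classifier == "SVM"],
                     rep$accuracy$generator[rep$accuracy$classifier == "SVM"], mean)
  expect_true(all(svm_mean > 0.8))  # strongly separated fixture
  for (g in c("cvae", "benchmark"))
    expect_equal(sum(rep$confusion[[g]][["SVM"]]), 2 * 3 * 15)

  single <- condition_vector(rep("A", nrow(fx$gt$matrix)))
  expect_error(compare_generators(fx$gt$matrix, single, cvae_config = cfg),
               "at least 2 conditions|fewer than 2")
})

test_that("the t-SNE diagnostic embeds every sample with provenance tags", {
  fx <- eval_fix()
  real <- fx$gt$matrix[1:24, ]
  labs <- condition_vector(fx$gt$labels$labels[1:24], fx$gt$labels$vocabulary)
  gen <- list(cvae = list(matrix = fx$gt$matrix[25:36, ], condition = "condA"))
  emb <- embed_tsne(real, labs, gen, dims = 3, perplexity = 5, max_iter = 60,
                    seed = 3)
  expect_equal(nrow(emb), 36)
  expect_setequal(unique(emb$source), c("real", "cvae"))
  expect_equal(ncol(emb), 3 + 3)
  expect_equal(formals(embed_tsne)$dims, 3)

  emb2 <- embed_tsne(real, labs, gen, dims = 3, perplexity = 5, max_iter = 60,
                     seed = 3)
  expect_identical(emb$dim1, emb2$dim1)

  expect_error(embed_tsne(real[1:6, ], condition_vector(labs$labels[1:6]),
                          perplexity = 10), "perplexity")
})
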