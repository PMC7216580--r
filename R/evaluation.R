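#' Stratified generator/classifier split
#'
#' Randomly partitions the samples per condition into a generator-training
#' partition (default 70\%, used to fit the generative models) and a
#' classifier-training partition (the remaining 30\%), the split used by the
#' evaluation protocol.
#'
#' @param m a \code{beta_matrix}.
#' @param labels a \code{\link{condition_vector}} aligned to \code{m}.
#' @param train_fraction fraction per condition assigned to the generator
#'   partition, strictly between 0 and 1 (default 0.7).
#' @param seed integer seed.
#' @return list with elements \code{generator} and \code{classifier}, each a
#'   list with \code{matrix} and \code{labels}.
#' @export
split_data <- function(m, labels, train_fraction = 0.7, seed = 1) {
  stopifnot(inherits(m, "beta_matrix"), inherits(labels, "condition_vector"),
            train_fraction > 0, train_fraction < 1)
  if (length(labels$labels) != nrow(m)) stopf("labels do not align with samples")
  counts <- table(factor(labels$labels, levels = labels$vocabulary))
  small <- names(counts)[counts < 2]
  if (length(small) > 0)
    stopf("condition(s) with fewer than 2 samples: %s", paste(small, collapse = ", "))
  set.seed(as.integer(seed))
  gen_idx <- integer(0)
  for (cond in labels$vocabulary) {
    idx <- which(labels$labels == cond)
    n_train <- min(max(round(train_fraction * length(idx)), 1), length(idx) - 1)
    gen_idx <- c(gen_idx, sample(idx, n_train))
  }
  gen_idx <- sort(gen_idx)
  cls_idx <- setdiff(seq_len(nrow(m)), gen_idx)
  list(
    generator = list(matrix = m[gen_idx, ], labels = subset_conditions(labels, gen_idx)),
    classifier = list(matrix = m[cls_idx, ], labels = subset_conditions(labels, cls_idx))
  )
}

classifier_algorithms <- c("DT", "NB", "RF", "KNN", "SVM")

#' Train multi-class classifiers on real data
#'
#' Fits the evaluation protocol's classifiers — decision tree (DT), naive
#' Bayes (NB), random forest (RF), k-nearest neighbours (KNN) and support
#' vector machine (SVM) — each able to emit per-condition scores for
#' one-vs-rest AUC. Library defaults are used throughout; the SVM is a set of
#' one-vs-rest binary machines whose decision values provide both the scores
#' and (by argmax) the multi-class prediction.
#'
#' @param train a \code{beta_matrix} (fully observed).
#' @param labels a \code{\link{condition_vector}} aligned to \code{train},
#'   with at least 2 conditions present.
#' @param algorithms subset of \code{c("DT","NB","RF","KNN","SVM")}.
#' @param seed integer seed (random forest bootstrap etc.).
#' @param knn_k neighbours for KNN (default 5, capped at the training size).
#' @return an object of class \code{classifier_set}.
#' @export
train_classifiers <- function(train, labels, algorithms = classifier_algorithms,
                              seed = 1, knn_k = 5) {
  stopifnot(inherits(train, "beta_matrix"), inherits(labels, "condition_vector"))
  unknown <- setdiff(algorithms, classifier_algorithms)
  if (length(unknown) > 0)
    stopf("unknown algorithm(s): %s (available: %s)",
          paste(unknown, collapse = ", "), paste(classifier_algorithms, collapse = ", "))
  if (length(unique(labels$labels)) < 2)
    stopf("need at least 2 conditions present to train classifiers")
  if (anyNA(train)) stopf("training matrix contains missing values")

  x <- unclass(train)
  feat <- paste0("f", seq_len(ncol(x)))
  colnames(x) <- feat
  yf <- factor(labels$labels, levels = labels$vocabulary)
  df <- data.frame(x, check.names = FALSE)

  models <- list()
  for (alg in algorithms) {
    set.seed(make_seed(seed, match(alg, classifier_algorithms)))
    models[[alg]] <- switch(alg,
      DT = rpart::rpart(.y ~ ., data = cbind(df, .y = yf), method = "class"),
      NB = e1071::naiveBayes(df, yf),
      RF = randomForest::randomForest(x, yf),
      KNN = list(x = x, y = yf, k = min(knn_k, nrow(x))),
      SVM = lapply(labels$vocabulary, function(cond) {
        ybin <- factor(ifelse(labels$labels == cond, "pos", "neg"),
                       levels = c("pos", "neg"))
        e1071::svm(x, ybin, kernel = "radial")
      })
    )
  }
  structure(list(models = models, vocabulary = labels$vocabulary,
                 cpg_ids = cpg_ids(train), seed = seed, knn_k = knn_k),
            class = "classifier_set")
}

#' @export
print.classifier_set <- function(x, ...) {
  cat(sprintf("classifier_set: %s; %d conditions, %d CpGs\n",
              paste(names(x$models), collapse = ", "),
              length(x$vocabulary), length(x$cpg_ids)))
  invisible(x)
}

# per-condition score matrix + argmax prediction for one algorithm
predict_condition_scores <- function(clfset, alg, newdata) {
  stopifnot(inherits(clfset, "classifier_set"))
  if (!(alg %in% names(clfset$models))) stopf("no trained model for %s", alg)
  ids <- cpg_ids(newdata)
  if (!identical(ids, clfset$cpg_ids)) {
    diff <- union(setdiff(ids, clfset$cpg_ids), setdiff(clfset$cpg_ids, ids))
    stopf("CpG set mismatch between data and classifier; differing IDs: %s%s",
          paste(utils::head(diff, 5), collapse = ", "),
          if (length(diff) > 5) ", ..." else
            if (length(diff) == 0) "(same IDs, different order)" else "")
  }
  x <- unclass(newdata)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  vocab <- clfset$vocabulary
  model <- clfset$models[[alg]]
  df <- data.frame(x, check.names = FALSE)

  raw <- switch(alg,
    DT = predict(model, df, type = "prob"),
    NB = predict(model, df, type = "raw"),
    RF = predict(model, df, type = "prob"),
    KNN = {
      tr <- model$x
      d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * tcrossprod(x, tr)
      votes <- matrix(0, nrow(x), length(vocab), dimnames = list(NULL, vocab))
      for (i in seq_len(nrow(x))) {
        nb <- order(d2[i, ])[seq_len(model$k)]
        tab <- table(factor(model$y[nb], levels = vocab))
        votes[i, ] <- as.numeric(tab) / model$k
      }
      votes
    },
    SVM = {
      dv <- vapply(model, function(mk) {
        pr <- predict(mk, x, decision.values = TRUE)
        d <- attr(pr, "decision.values")
        # e1071 orients the binary decision value by order of appearance in
        # the training data, reported in the column name ("pos/neg" vs
        # "neg/pos"); flip so positive always means the target condition
        if (startsWith(colnames(d)[1], "neg")) d <- -d
        as.numeric(d)
      }, numeric(nrow(x)))
      dv <- matrix(dv, nrow = nrow(x), dimnames = list(NULL, vocab))
      dv
    })

  scores <- matrix(0, nrow(x), length(vocab), dimnames = list(NULL, vocab))
  shared <- intersect(colnames(raw) %||% vocab, vocab)
  scores[, shared] <- as.matrix(raw)[, shared, drop = FALSE]
  pred <- vocab[max.col(scores, ties.method = "first")]
  list(scores = scores, pred = pred)
}

#' One-vs-rest AUC from per-condition scores
#'
#' Rank-based (Mann-Whitney) area under the ROC curve for each condition,
#' scoring that condition's samples against all others using the condition's
#' score column. Ties are handled by midranks. Conditions without both a
#' positive and a negative sample get \code{NA}.
#'
#' @param scores numeric matrix, one row per sample, one named column per
#'   condition.
#' @param intended character vector of intended conditions, one per row.
#' @return named numeric vector of per-condition AUCs.
#' @export
one_vs_rest_auc <- function(scores, intended) {
  stopifnot(is.matrix(scores), nrow(scores) == length(intended),
            !is.null(colnames(scores)))
  if (!all(is.finite(scores))) stopf("scores must be finite")
  vapply(colnames(scores), function(cond) {
    pos <- intended == cond
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, cond])             # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' Classify generated samples against their intended condition
#'
#' Runs every trained classifier on a collection of generated matrices, each
#' tagged with the condition it was generated for; a prediction is correct
#' iff it equals that intended condition. Reports overall and per-condition
#' accuracy, the confusion matrix (intended x predicted) and per-condition
#' one-vs-rest AUC.
#'
#' @param classifiers a \code{\link{train_classifiers}} result.
#' @param generated list of \code{list(matrix = <beta_matrix>,
#'   condition = <string>)} entries sharing the classifiers' CpG set.
#' @return an object of class \code{eval_result}: per-classifier list with
#'   \code{accuracy}, \code{per_condition_accuracy}, \code{confusion},
#'   \code{auc} and \code{n}.
#' @export
evaluate_generated <- function(classifiers, generated) {
  stopifnot(inherits(classifiers, "classifier_set"), length(generated) > 0)
  vocab <- classifiers$vocabulary
  mats <- lapply(generated, `[[`, "matrix")
  intended <- unlist(Map(function(g) rep(g$condition, nrow(g$matrix)), generated))
  stacked <- beta_matrix(do.call(rbind, lapply(mats, function(m) {
    v <- unclass(m); rownames(v) <- NULL; v
  })), sample_ids = paste0("gen_", seq_along(intended)))
  if (!all(intended %in% vocab))
    stopf("intended condition(s) outside classifier vocabulary: %s",
          paste(setdiff(intended, vocab), collapse = ", "))

  out <- lapply(names(classifiers$models), function(alg) {
    ps <- predict_condition_scores(classifiers, alg, stacked)
    confusion <- table(factor(intended, levels = vocab),
                       factor(ps$pred, levels = vocab))
    acc <- mean(ps$pred == intended)
    per_cond <- vapply(vocab, function(cond) {
      sel <- intended == cond
      if (!any(sel)) NA_real_ else mean(ps$pred[sel] == cond)
    }, numeric(1))
    list(accuracy = acc, per_condition_accuracy = per_cond,
         confusion = unclass(confusion),
         auc = one_vs_rest_auc(ps$scores, intended), n = length(intended))
  })
  names(out) <- names(classifiers$models)
  structure(list(per_classifier = out, intended = intended, vocabulary = vocab),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  for (alg in names(x$per_classifier)) {
    r <- x$per_classifier[[alg]]
    cat(sprintf("%-4s accuracy %.3f (n = %d); mean AUC %.3f\n", alg,
                r$accuracy, r$n, mean(r$auc, na.rm = TRUE)))
  }
  invisible(x)
}

#' Compare the CVAE and benchmark generators by classification
#'
#' The full evaluation protocol: per repetition, split the data 70/30
#' (stratified by condition), fit the requested generators on the 70\%
#' partition, train the classifiers on the 30\% partition, generate
#' \code{n_generated_per_condition} samples per condition per generator, and
#' classify them against their intended condition. Both the split and the
#' generation seeds are re-drawn each repetition.
#'
#' @param data a fully observed \code{beta_matrix} (run
#'   \code{\link{preprocess_pipeline}} first if needed).
#' @param labels a \code{\link{condition_vector}} aligned to \code{data} with
#'   at least 2 conditions.
#' @param generators subset of \code{c("cvae", "benchmark")}.
#' @param n_generated_per_condition generated samples per condition per
#'   generator (default 100).
#' @param repetitions number of repetitions (default 10).
#' @param seed master seed; all per-repetition seeds derive from it.
#' @param cvae_config a \code{\link{cvae_config}} for the CVAE arm (its
#'   \code{seed} is re-derived per repetition).
#' @param classifiers algorithm tags for \code{\link{train_classifiers}}.
#' @param train_fraction generator-partition fraction (default 0.7).
#' @param min_n minimum per-cell observations for the benchmark fit.
#' @return an object of class \code{eval_report}: \code{accuracy} (data frame
#'   generator x classifier x repetition, boxplot-ready), \code{per_condition}
#'   (adds condition-level accuracy and one-vs-rest AUC), \code{confusion}
#'   (summed over repetitions per generator and classifier) and
#'   \code{settings}.
#' @export
compare_generators <- function(data, labels,
                               generators = c("cvae", "benchmark"),
                               n_generated_per_condition = 100,
                               repetitions = 10,
                               seed = 1,
                               cvae_config = methgen::cvae_config(),
                               classifiers = classifier_algorithms,
                               train_fraction = 0.7,
                               min_n = 3) {
  stopifnot(inherits(data, "beta_matrix"), inherits(labels, "condition_vector"))
  generators <- match.arg(generators, c("cvae", "benchmark"), several.ok = TRUE)
  if (anyNA(data)) stopf("data contains missing values; run preprocess_pipeline() first")
  if (length(unique(labels$labels)) < 2)
    stopf("need at least 2 conditions for the classification protocol")
  vocab <- labels$vocabulary

  acc_rows <- list(); cond_rows <- list()
  confusion <- stats::setNames(
    lapply(generators, function(g) stats::setNames(
      lapply(classifiers, function(a) matrix(0, length(vocab), length(vocab),
                                             dimnames = list(vocab, vocab))),
      classifiers)),
    generators)

  for (r in seq_len(repetitions)) {
    rs <- make_seed(seed, r)
    sp <- split_data(data, labels, train_fraction, seed = rs)
    clfs <- train_classifiers(sp$classifier$matrix, sp$classifier$labels,
                              classifiers, seed = rs)
    fitted <- list()
    if ("cvae" %in% generators) {
      cfg <- cvae_config
      cfg$seed <- make_seed(rs, 1)
      fitted$cvae <- train_cvae(sp$generator$matrix, sp$generator$labels, cfg)
    }
    if ("benchmark" %in% generators)
      fitted$benchmark <- fit_table(sp$generator$matrix, sp$generator$labels,
                                    min_n = min_n)

    for (g in generators) {
      gen_list <- lapply(seq_along(vocab), function(ci) {
        gseed <- make_seed(rs, 100 * match(g, c("cvae", "benchmark")) + ci)
        mat <- if (g == "cvae")
          generate(fitted$cvae, vocab[ci], n_generated_per_condition, seed = gseed)
        else
          sample_benchmark(fitted$benchmark, vocab[ci], n_generated_per_condition,
                           seed = gseed)
        list(matrix = mat, condition = vocab[ci])
      })
      ev <- evaluate_generated(clfs, gen_list)
      for (alg in classifiers) {
        res <- ev$per_classifier[[alg]]
        acc_rows[[length(acc_rows) + 1]] <- data.frame(
          generator = g, classifier = alg, repetition = r, accuracy = res$accuracy)
        cond_rows[[length(cond_rows) + 1]] <- data.frame(
          generator = g, classifier = alg, repetition = r, condition = vocab,
          accuracy = unname(res$per_condition_accuracy), auc = unname(res$auc))
        confusion[[g]][[alg]] <- confusion[[g]][[alg]] + res$confusion
      }
    }
  }

  structure(list(
    accuracy = do.call(rbind, acc_rows),
    per_condition = do.call(rbind, cond_rows),
    confusion = confusion,
    settings = list(generators = generators, classifiers = classifiers,
                    n_generated_per_condition = n_generated_per_condition,
                    repetitions = repetitions, train_fraction = train_fraction,
                    seed = seed, cvae_config = cvae_config, min_n = min_n)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d repetition(s), %d generated per condition\n",
              x$settings$repetitions, x$settings$n_generated_per_condition))
  agg <- stats::aggregate(accuracy ~ generator + classifier, x$accuracy, mean)
  wide <- stats::reshape(agg, idvar = "classifier", timevar = "generator",
                         direction = "wide")
  print(wide, row.names = FALSE)
  invisible(x)
}
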