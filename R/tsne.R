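# Exact (non-approximate) t-SNE, sufficient for the diagnostic embedding of a
# few hundred samples. Perplexity calibration by bisection on the Gaussian
# kernel bandwidth per point; gradient descent with momentum and early
# exaggeration, as in the original algorithm.

tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    d <- D2[i, -i]
    for (tr in seq_len(max_tries)) {
      p <- exp(-d * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(d * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

run_tsne <- function(X, dims, perplexity, max_iter, seed) {
  n <- nrow(X)
  # PCA compression first: standard preprocessing, removes redundant variance
  if (ncol(X) > 50) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 50)
    X <- pc$x
  }
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  exaggeration <- 4
  for (iter in seq_len(max_iter)) {
    mom <- if (iter < 250) 0.5 else 0.8
    Pe <- if (iter <= 100) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
    dY <- mom * dY - 200 * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Joint t-SNE embedding of real and generated samples
#'
#' Compresses real and generated methylomes into a shared low-dimensional
#' (default three-dimensional) t-SNE space, tagging every point with its
#' source and condition, for visual inspection of whether generated samples
#' cluster with the real samples of their intended condition.
#'
#' @param real a \code{beta_matrix} of real samples.
#' @param real_labels a \code{\link{condition_vector}} aligned to \code{real}.
#' @param generated list of \code{list(matrix =, condition =)} entries (as in
#'   \code{\link{evaluate_generated}}), sharing the real matrix's CpG set;
#'   names of the list are used as source tags (default \code{"generated"}).
#' @param dims embedding dimension, default 3.
#' @param perplexity Gaussian-kernel perplexity; default
#'   \code{min(30, floor((n - 1) / 3))}. Must satisfy
#'   \code{3 * perplexity < n}.
#' @param max_iter gradient-descent iterations, default 300.
#' @param seed integer seed; identical seeds give identical embeddings.
#' @return data frame with \code{sample_id}, \code{source}, \code{condition}
#'   and coordinate columns \code{dim1..dimK}.
#' @export
embed_tsne <- function(real, real_labels, generated = list(), dims = 3,
                       perplexity = NULL, max_iter = 300, seed = 1) {
  stopifnot(inherits(real, "beta_matrix"), dims >= 1)
  mats <- c(list(unclass(real)), lapply(generated, function(g) unclass(g$matrix)))
  for (g in generated)
    if (!identical(cpg_ids(g$matrix), cpg_ids(real)))
      stopf("generated matrices must share the real matrix's CpG set")
  X <- do.call(rbind, mats)
  n <- nrow(X)
  src_names <- names(generated) %||% rep("generated", length(generated))
  if (length(generated) > 0 && is.null(names(generated)))
    src_names <- rep("generated", length(generated))
  source <- c(rep("real", nrow(real)),
              unlist(Map(function(g, nm) rep(nm, nrow(g$matrix)),
                         generated, src_names)))
  condition <- c(real_labels$labels,
                 unlist(lapply(generated, function(g) rep(g$condition, nrow(g$matrix)))))
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor((n - 1) / 3)))
  if (3 * perplexity >= n)
    stopf("too few samples (%d) for perplexity %g; use a smaller perplexity", n, perplexity)
  Y <- run_tsne(X, dims, perplexity, max_iter, seed)
  out <- data.frame(sample_id = rownames(X) %||% paste0("s", seq_len(n)),
                    source = source, condition = condition)
  coords <- as.data.frame(Y)
  names(coords) <- paste0("dim", seq_len(dims))
  cbind(out, coords)
}
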