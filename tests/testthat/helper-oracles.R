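# Independent oracles, written naively on purpose so they share no code with
# the implementation they check.

# the four preprocessing rules, applied directly with loops
naive_preprocess <- function(m, chunk_size, whisker = 1.5) {
  v <- unclass(m)
  keep_cpg <- apply(v, 2, function(col) any(!is.na(col)))
  removed_cpgs <- colnames(v)[!keep_cpg]
  v <- v[, keep_cpg, drop = FALSE]
  p <- ncol(v)
  n_chunks <- if (p == 0) 0 else ceiling(p / chunk_size)
  chunks <- list(); removed_samples <- list(); imputed <- integer(0)
  for (i in seq_len(n_chunks)) {
    cols <- ((i - 1) * chunk_size + 1):min(i * chunk_size, p)
    ch <- v[, cols, drop = FALSE]
    counts <- apply(ch, 1, function(r) sum(is.na(r)))
    q1 <- unname(stats::quantile(counts, 0.25))
    q3 <- unname(stats::quantile(counts, 0.75))
    fence <- q3 + whisker * (q3 - q1)
    rm <- counts > fence
    removed_samples[[i]] <- rownames(ch)[rm]
    ch <- ch[!rm, , drop = FALSE]
    n_imp <- 0L
    for (j in seq_len(ncol(ch))) {
      mis <- is.na(ch[, j])
      if (any(mis)) {
        ch[mis, j] <- stats::median(ch[!mis, j])
        n_imp <- n_imp + sum(mis)
      }
    }
    imputed[i] <- n_imp
    chunks[[i]] <- ch
  }
  list(removed_cpgs = removed_cpgs, removed_samples = removed_samples,
       imputed = imputed, chunks = chunks)
}

# KL[N(mu, e^logvar) || N(0,1)] by numerical integration, per dimension
kl_quadrature <- function(mu, logvar) {
  sum(mapply(function(m, lv) {
    s <- exp(0.5 * lv)
    f <- function(z) stats::dnorm(z, m, s) *
      (stats::dnorm(z, m, s, log = TRUE) - stats::dnorm(z, log = TRUE))
    stats::integrate(f, m - 12 * s - 12, m + 12 * s + 12,
                     rel.tol = 1e-10, abs.tol = 1e-10)$value
  }, mu, logvar))
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
auc_paircount <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# small separable two-condition fixture plus a reduced trained CVAE, shared
# by several cvae tests (training it once keeps the suite fast)
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- generate_ground_truth(synthetic_spec(
        n_conditions = 2, n_cpgs = 20, n_samples_per_condition = 40,
        mean_separation = 0.4, frac_informative = 1, seed = 33))
      cfg <- cvae_config(encoder_hidden = c(16, 8), latent_dim = 4,
                         epochs = 300, batch_size = 40, seed = 33)
      cache <<- list(gt = gt, cfg = cfg,
                     model = train_cvae(gt$matrix, gt$labels, cfg))
    }
    cache
  }
})
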