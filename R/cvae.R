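#' Configuration for the conditional variational autoencoder
#'
#' Defaults follow the reference architecture: encoder hidden layers of 500
#' and 250 fully connected nodes, 125 latent variables, a decoder mirroring
#' the encoder, Adam with learning rate 1e-3, and 10,000 training epochs.
#' Hidden layers use ELU and tanh activations (first and second layer
#' respectively, mirrored in the decoder); the output layer is a sigmoid so
#' reconstructions stay inside (0, 1).
#'
#' @param encoder_hidden positive integers, encoder hidden layer widths.
#' @param latent_dim number of latent variables.
#' @param decoder_hidden decoder hidden widths; defaults to the reversed
#'   encoder widths (symmetrical structure).
#' @param learning_rate Adam step size.
#' @param epochs training epochs (full passes over the data).
#' @param batch_size minibatch size (capped at the sample count during
#'   training).
#' @param seed integer controlling weight initialization, shuffling and the
#'   reparameterization noise.
#' @param activations activation names (\code{"elu"} or \code{"tanh"}) for the
#'   encoder hidden layers, recycled to their number; the decoder uses the
#'   reversed plan.
#' @param reconstruction_loss \code{"cross_entropy"} (elementwise binary
#'   cross-entropy, the default for sigmoid outputs on \code{[0,1]} data) or
#'   \code{"mse"}.
#' @return an object of class \code{cvae_config}.
#' @export
cvae_config <- function(encoder_hidden = c(500, 250),
                        latent_dim = 125,
                        decoder_hidden = rev(encoder_hidden),
                        learning_rate = 1e-3,
                        epochs = 10000,
                        batch_size = 100,
                        seed = 1L,
                        activations = c("elu", "tanh"),
                        reconstruction_loss = c("cross_entropy", "mse")) {
  reconstruction_loss <- match.arg(reconstruction_loss)
  stopifnot(all(encoder_hidden >= 1), all(decoder_hidden >= 1),
            latent_dim >= 1, learning_rate > 0, epochs >= 1, batch_size >= 1)
  activations <- match.arg(activations, c("elu", "tanh"), several.ok = TRUE)
  structure(list(
    encoder_hidden = as.integer(encoder_hidden),
    latent_dim = as.integer(latent_dim),
    decoder_hidden = as.integer(decoder_hidden),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed),
    activations = activations,
    reconstruction_loss = reconstruction_loss
  ), class = "cvae_config")
}

#' @export
print.cvae_config <- function(x, ...) {
  cat(sprintf(
    "cvae_config: encoder [%s] -> latent %d -> decoder [%s]; lr %g, %d epochs, batch %d, %s loss\n",
    paste(x$encoder_hidden, collapse = ", "), x$latent_dim,
    paste(x$decoder_hidden, collapse = ", "), x$learning_rate, x$epochs,
    x$batch_size, x$reconstruction_loss))
  invisible(x)
}

#' Gaussian variational posterior
#'
#' The encoder's output: a diagonal Gaussian over the latent variables,
#' parameterized by its mean and log-variance.
#'
#' @param mu,logvar finite numeric vectors (or matrices, rows = samples) of
#'   equal shape.
#' @return an object of class \code{gaussian_posterior}.
#' @export
gaussian_posterior <- function(mu, logvar) {
  if (length(mu) != length(logvar)) stopf("mu and logvar differ in length")
  if (!all(is.finite(mu)) || !all(is.finite(logvar)))
    stopf("non-finite posterior parameters")
  structure(list(mu = mu, logvar = logvar), class = "gaussian_posterior")
}

#' KL divergence of a diagonal Gaussian from the standard normal prior
#'
#' Closed form of the regularizer in the variational lower bound:
#' \deqn{KL[N(\mu, diag(e^{logvar}))\,\|\,N(0, I)] =
#'   -\tfrac12 \sum_d (1 + logvar_d - \mu_d^2 - e^{logvar_d}),}
#' always non-negative and zero exactly when the posterior equals the prior.
#' For matrix-valued posteriors the divergences are summed over rows.
#'
#' @param q a \code{\link{gaussian_posterior}}.
#' @return non-negative scalar.
#' @examples
#' kl_gaussian_vs_standard_normal(gaussian_posterior(0, 0))      # 0
#' kl_gaussian_vs_standard_normal(gaussian_posterior(1, 0))      # 0.5
#' @export
kl_gaussian_vs_standard_normal <- function(q) {
  stopifnot(inherits(q, "gaussian_posterior"))
  -0.5 * sum(1 + q$logvar - q$mu^2 - exp(q$logvar))
}

#' Evidence lower bound loss for one sample
#'
#' Computes the (negated) variational lower bound that training minimizes:
#' a reconstruction term plus the KL regularizer. The reconstruction term is
#' elementwise binary cross-entropy summed over CpGs (default; inputs clipped
#' to \code{[1e-6, 1 - 1e-6]}) or summed squared error.
#'
#' @param x observed beta-value vector in \code{[0, 1]}.
#' @param x_recon reconstruction in \code{(0, 1)}, same length.
#' @param q the \code{\link{gaussian_posterior}} for this sample.
#' @param reconstruction_loss \code{"cross_entropy"} or \code{"mse"}.
#' @return list with \code{total}, \code{recon} and \code{kl};
#'   \code{total == recon + kl}.
#' @export
elbo_loss <- function(x, x_recon, q,
                      reconstruction_loss = c("cross_entropy", "mse")) {
  reconstruction_loss <- match.arg(reconstruction_loss)
  if (length(x) != length(x_recon))
    stopf("x (%d) and x_recon (%d) differ in length", length(x), length(x_recon))
  recon <- if (reconstruction_loss == "cross_entropy") {
    xc <- clip_unit(x, 1e-6)
    xr <- clip_unit(x_recon, 1e-6)
    -sum(xc * log(xr) + (1 - xc) * log(1 - xr))
  } else {
    sum((x - x_recon)^2)
  }
  kl <- kl_gaussian_vs_standard_normal(q)
  list(total = recon + kl, recon = recon, kl = kl)
}

#' Reparameterized sample from a Gaussian posterior
#'
#' Draws \code{z = mu + exp(logvar / 2) * eps} with standard-normal
#' \code{eps}, the stochastic-gradient variational Bayes trick that lets
#' gradients flow through the sampling step.
#'
#' @param q a \code{\link{gaussian_posterior}} with vector parameters.
#' @param seed optional integer; when given, seeds the RNG so the draw is
#'   reproducible. When \code{NULL} the current RNG stream is used.
#' @return an object of class \code{latent_sample} with field \code{z}.
#' @export
reparameterize <- function(q, seed = NULL) {
  stopifnot(inherits(q, "gaussian_posterior"))
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length(q$mu))
  structure(list(z = q$mu + exp(0.5 * q$logvar) * eps), class = "latent_sample")
}

# ---- internal network machinery -------------------------------------------

enc_acts <- function(cfg) rep(cfg$activations, length.out = length(cfg$encoder_hidden))
dec_acts <- function(cfg) rep(rev(enc_acts(cfg)), length.out = length(cfg$decoder_hidden))

addbias <- function(M, b) M + rep(b, each = nrow(M))

# fan-in-scaled normal initialization under the current RNG state
init_cvae_params <- function(n_cpgs, n_conditions, cfg) {
  rw <- function(fin, fout) matrix(stats::rnorm(fin * fout, sd = 1 / sqrt(fin)), fin, fout)
  p <- list()
  dims <- c(n_cpgs + n_conditions, cfg$encoder_hidden)
  for (l in seq_along(cfg$encoder_hidden)) {
    p[[paste0("encW", l)]] <- rw(dims[l], dims[l + 1])
    p[[paste0("encb", l)]] <- numeric(dims[l + 1])
  }
  last <- dims[length(dims)]
  p$encWmu <- rw(last, cfg$latent_dim); p$encbmu <- numeric(cfg$latent_dim)
  p$encWlv <- rw(last, cfg$latent_dim); p$encblv <- numeric(cfg$latent_dim)
  ddims <- c(cfg$latent_dim + n_conditions, cfg$decoder_hidden)
  for (l in seq_along(cfg$decoder_hidden)) {
    p[[paste0("decW", l)]] <- rw(ddims[l], ddims[l + 1])
    p[[paste0("decb", l)]] <- numeric(ddims[l + 1])
  }
  dlast <- ddims[length(ddims)]
  p$decWout <- rw(dlast, n_cpgs); p$decbout <- numeric(n_cpgs)
  p
}

encoder_forward <- function(p, X, Y, cfg) {
  acts <- enc_acts(cfg)
  A <- cbind(X, Y)
  enc_in <- A
  pre <- h <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    pre[[l]] <- addbias(A %*% p[[paste0("encW", l)]], p[[paste0("encb", l)]])
    h[[l]] <- act_apply(pre[[l]], acts[l])
    A <- h[[l]]
  }
  list(enc_in = enc_in, pre = pre, h = h,
       MU = addbias(A %*% p$encWmu, p$encbmu),
       LV = addbias(A %*% p$encWlv, p$encblv))
}

decoder_forward <- function(p, Z, Y, cfg) {
  acts <- dec_acts(cfg)
  A <- cbind(Z, Y)
  dec_in <- A
  pre <- h <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    pre[[l]] <- addbias(A %*% p[[paste0("decW", l)]], p[[paste0("decb", l)]])
    h[[l]] <- act_apply(pre[[l]], acts[l])
    A <- h[[l]]
  }
  logits <- addbias(A %*% p$decWout, p$decbout)
  list(dec_in = dec_in, pre = pre, h = h, logits = logits, XR = sigmoid(logits))
}

# one forward+backward pass on a minibatch; returns grads and loss components
cvae_step <- function(p, X, Xc, Y, EPS, cfg) {
  B <- nrow(X)
  ef <- encoder_forward(p, X, Y, cfg)
  S <- exp(0.5 * ef$LV)
  Z <- ef$MU + S * EPS
  df <- decoder_forward(p, Z, Y, cfg)

  if (cfg$reconstruction_loss == "cross_entropy") {
    recon_sum <- sum(Xc * softplus(-df$logits) + (1 - Xc) * softplus(df$logits))
    dlogits <- (df$XR - Xc) / B
  } else {
    recon_sum <- sum((df$XR - X)^2)
    dlogits <- 2 * (df$XR - X) * df$XR * (1 - df$XR) / B
  }
  kl_sum <- -0.5 * sum(1 + ef$LV - ef$MU^2 - exp(ef$LV))

  g <- list()
  dacts <- dec_acts(cfg)
  nd <- length(dacts)
  A_last <- if (nd > 0) df$h[[nd]] else df$dec_in
  g$decWout <- crossprod(A_last, dlogits)
  g$decbout <- colSums(dlogits)
  dH <- dlogits %*% t(p$decWout)
  for (l in rev(seq_len(nd))) {
    dpre <- dH * act_grad(df$pre[[l]], df$h[[l]], dacts[l])
    inp <- if (l == 1) df$dec_in else df$h[[l - 1]]
    g[[paste0("decW", l)]] <- crossprod(inp, dpre)
    g[[paste0("decb", l)]] <- colSums(dpre)
    dH <- dpre %*% t(p[[paste0("decW", l)]])
  }
  L <- cfg$latent_dim
  dZ <- dH[, seq_len(L), drop = FALSE]
  dMU <- dZ + ef$MU / B
  dLV <- dZ * (0.5 * S * EPS) + 0.5 * (exp(ef$LV) - 1) / B

  eacts <- enc_acts(cfg)
  ne <- length(eacts)
  E_last <- if (ne > 0) ef$h[[ne]] else ef$enc_in
  g$encWmu <- crossprod(E_last, dMU); g$encbmu <- colSums(dMU)
  g$encWlv <- crossprod(E_last, dLV); g$encblv <- colSums(dLV)
  dH <- dMU %*% t(p$encWmu) + dLV %*% t(p$encWlv)
  for (l in rev(seq_len(ne))) {
    dpre <- dH * act_grad(ef$pre[[l]], ef$h[[l]], eacts[l])
    inp <- if (l == 1) ef$enc_in else ef$h[[l - 1]]
    g[[paste0("encW", l)]] <- crossprod(inp, dpre)
    g[[paste0("encb", l)]] <- colSums(dpre)
    dH <- dpre %*% t(p[[paste0("encW", l)]])
  }
  list(grads = g, recon = recon_sum / B, kl = kl_sum / B,
       total = (recon_sum + kl_sum) / B)
}

adam_update <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^t)
    vhat <- st$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, st = st)
}

one_hot_for <- function(condition, vocabulary, n = 1) {
  if (is.character(condition)) {
    if (length(condition) != 1 || !(condition %in% vocabulary))
      stopf("unknown condition '%s'; vocabulary: %s",
            paste(condition, collapse = ","), paste(vocabulary, collapse = ", "))
    y <- as.numeric(vocabulary == condition)
  } else {
    y <- as.numeric(condition)
    if (length(y) != length(vocabulary) || abs(sum(y) - 1) > 1e-12)
      stopf("one-hot condition must have length %d and sum to 1", length(vocabulary))
  }
  matrix(rep(y, each = n), nrow = n)
}

# ---- training and generation ----------------------------------------------

#' Train the conditional variational autoencoder
#'
#' Fits one independent CVAE per CpG chunk by minibatch Adam on the negated
#' conditional variational lower bound (reconstruction error plus KL
#' divergence of the encoder's Gaussian posterior from the standard normal
#' prior). The condition's one-hot encoding is concatenated to the encoder
#' input and to the decoder input. All randomness (initialization, shuffling,
#' reparameterization noise) derives from \code{config$seed}, so two runs
#' with identical inputs produce identical weights.
#'
#' @param data a \code{chunked_dataset} from
#'   \code{\link{preprocess_pipeline}}, or a fully observed
#'   \code{beta_matrix} (treated as a single chunk). Missing values are an
#'   error.
#' @param labels a list of per-chunk \code{\link{condition_vector}}s (as
#'   returned by the pipeline) or a single \code{condition_vector} shared by
#'   all chunks.
#' @param config a \code{\link{cvae_config}}.
#' @param verbose print the loss every few hundred epochs.
#' @return an object of class \code{cvae_model}: per-chunk weights, the label
#'   vocabulary, the chunk-to-CpG mapping, the config, and per-chunk
#'   per-epoch loss traces.
#' @export
train_cvae <- function(data, labels, config = cvae_config(), verbose = FALSE) {
  if (inherits(data, "beta_matrix"))
    data <- structure(list(chunks = list(data), chunk_size = ncol(data)),
                      class = "chunked_dataset")
  stopifnot(inherits(data, "chunked_dataset"))
  if (inherits(labels, "condition_vector"))
    labels <- rep(list(labels), length(data$chunks))
  if (length(labels) != length(data$chunks))
    stopf("need one condition_vector per chunk (%d chunks, %d label sets)",
          length(data$chunks), length(labels))
  if (length(data$chunks) == 0) stopf("no chunks to train on")

  vocab <- labels[[1]]$vocabulary
  warnings <- character(0)
  chunks_out <- vector("list", length(data$chunks))
  traces <- vector("list", length(data$chunks))

  for (ci in seq_along(data$chunks)) {
    ch <- data$chunks[[ci]]
    cv <- labels[[ci]]
    if (!identical(cv$vocabulary, vocab))
      stopf("chunk %d has a different label vocabulary", ci)
    if (anyNA(ch))
      stopf("chunk %d contains missing values; run preprocess_pipeline() first", ci)
    n <- nrow(ch)
    if (n < 2) stopf("chunk %d has %d sample(s); need at least 2", ci, n)
    if (length(cv$labels) != n)
      stopf("chunk %d: labels do not align with samples", ci)
    absent <- setdiff(vocab, unique(cv$labels))
    if (length(absent) > 0)
      warnings <- c(warnings, sprintf(
        "chunk %d: condition(s) %s absent after sample removal",
        ci, paste(absent, collapse = ", ")))

    X <- unclass(ch)
    Xc <- clip_unit(X, 1e-6)
    Y <- cv$one_hot
    K <- length(vocab)
    bs <- min(config$batch_size, n)
    Ld <- config$latent_dim

    set.seed(make_seed(config$seed, ci))
    p <- init_cvae_params(ncol(X), K, config)
    st <- list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0))
    t_step <- 0
    trace <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = bs)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1, n)]
        nb <- length(idx)
        EPS <- matrix(stats::rnorm(nb * Ld), nb, Ld)
        step <- cvae_step(p, X[idx, , drop = FALSE], Xc[idx, , drop = FALSE],
                          Y[idx, , drop = FALSE], EPS, config)
        t_step <- t_step + 1
        upd <- adam_update(p, step$grads, st, config$learning_rate, t_step)
        p <- upd$p; st <- upd$st
        ep_loss <- ep_loss + step$total * nb
      }
      trace[epoch] <- ep_loss / n
      if (verbose && (epoch %% 200 == 0 || epoch == 1))
        message(sprintf("chunk %d epoch %d: loss %.4f", ci, epoch, trace[epoch]))
    }
    chunks_out[[ci]] <- list(params = p, cpg_ids = colnames(ch))
    traces[[ci]] <- trace
  }

  structure(list(chunks = chunks_out, vocabulary = vocab, config = config,
                 loss_trace = traces, warnings = warnings),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cat(sprintf("cvae_model: %d chunk(s), %d CpGs total, %d conditions (%s)\n",
              length(x$chunks), sum(vapply(x$chunks, function(c) length(c$cpg_ids), 1L)),
              length(x$vocabulary), paste(x$vocabulary, collapse = ", ")))
  fin <- vapply(x$loss_trace, function(tr) tr[length(tr)], 1.0)
  cat(sprintf("  final loss per chunk: %s\n", paste(sprintf("%.3f", fin), collapse = ", ")))
  if (length(x$warnings) > 0) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Encode an observation into its Gaussian posterior
#'
#' Deterministic map from a beta-value vector and its condition through the
#' trained inference network to the latent posterior parameters.
#'
#' @param x numeric vector of length equal to the chunk's CpG count (or a
#'   matrix with samples as rows).
#' @param y condition label (string in the model vocabulary) or one-hot
#'   vector.
#' @param model a trained \code{cvae_model}.
#' @param chunk chunk index, default 1.
#' @return a \code{\link{gaussian_posterior}}.
#' @export
encode <- function(x, y, model, chunk = 1) {
  stopifnot(inherits(model, "cvae_model"))
  ch <- model$chunks[[chunk]]
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(ch$cpg_ids))
    stopf("x has %d values; chunk %d covers %d CpGs", ncol(X), chunk, length(ch$cpg_ids))
  Y <- one_hot_for(y, model$vocabulary, n = nrow(X))
  ef <- encoder_forward(ch$params, X, Y, model$config)
  if (is.matrix(x)) gaussian_posterior(ef$MU, ef$LV)
  else gaussian_posterior(drop(ef$MU), drop(ef$LV))
}

#' Decode a latent sample into a beta-value vector
#'
#' Deterministic map from latent variables and a condition through the trained
#' generative network; the sigmoid output layer guarantees values in (0, 1).
#'
#' @param z a \code{latent_sample}, numeric vector of length
#'   \code{latent_dim}, or matrix with samples as rows.
#' @param y condition label or one-hot vector.
#' @param model a trained \code{cvae_model}.
#' @param chunk chunk index, default 1.
#' @return numeric vector (or matrix) of reconstructed beta values in (0, 1).
#' @export
decode <- function(z, y, model, chunk = 1) {
  stopifnot(inherits(model, "cvae_model"))
  if (inherits(z, "latent_sample")) z <- z$z
  ch <- model$chunks[[chunk]]
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(Z) != model$config$latent_dim)
    stopf("z has %d entries; latent_dim is %d", ncol(Z), model$config$latent_dim)
  Y <- one_hot_for(y, model$vocabulary, n = nrow(Z))
  df <- decoder_forward(ch$params, Z, Y, model$config)
  out <- pmin(pmax(df$XR, 1e-12), 1 - 1e-12)
  if (is.matrix(z)) out else drop(out)
}

#' Generate methylome samples for a specified condition
#'
#' For each requested sample, latent variables are drawn from the standard
#' normal prior per chunk, decoded with the condition's one-hot encoding, and
#' the chunk outputs concatenated in chunk-to-CpG order.
#'
#' @param model a trained \code{cvae_model}.
#' @param condition condition label, must be in the model vocabulary.
#' @param n_samples number of samples to generate.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return a \code{\link{beta_matrix}} with rows named
#'   \code{"<condition>_sim_<k>"} and all values strictly inside (0, 1).
#' @export
generate <- function(model, condition, n_samples, seed = 1) {
  stopifnot(inherits(model, "cvae_model"), n_samples >= 0)
  if (!(condition %in% model$vocabulary))
    stopf("unknown condition '%s'; vocabulary: %s", condition,
          paste(model$vocabulary, collapse = ", "))
  set.seed(as.integer(seed))
  Ld <- model$config$latent_dim
  parts <- lapply(model$chunks, function(ch) {
    Z <- matrix(stats::rnorm(n_samples * Ld), n_samples, Ld)
    Y <- one_hot_for(condition, model$vocabulary, n = n_samples)
    df <- decoder_forward(ch$params, Z, Y, model$config)
    out <- pmin(pmax(df$XR, 1e-12), 1 - 1e-12)
    colnames(out) <- ch$cpg_ids
    out
  })
  values <- do.call(cbind, parts)
  rownames(values) <- if (n_samples > 0)
    sprintf("%s_sim_%d", condition, seq_len(n_samples)) else character(0)
  beta_matrix(values)
}

#' Save / load a trained CVAE model
#'
#' The model is stored as a single versioned container; a load/save round
#' trip reproduces \code{\link{generate}} output bit-for-bit given the same
#' seed.
#'
#' @param state a \code{cvae_model}.
#' @param path file path.
#' @return \code{load_state} returns the restored \code{cvae_model}.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "cvae_model"))
  saveRDS(list(format = "methgen_cvae_state", version = 1L, state = state), path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stopf("cannot read model state from %s: corrupt or truncated file (%s)",
          path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "methgen_cvae_state"))
    stopf("%s is not a methgen CVAE model state", path)
  if (!identical(obj$version, 1L))
    stopf("unsupported model state version: %s", obj$version)
  obj$state
}
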