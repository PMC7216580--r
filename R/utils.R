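# internal numerical helpers

sigmoid <- function(a) stats::plogis(a)

# log(1 + exp(a)) without overflow for large |a|
softplus <- function(a) {
  pmax(a, 0) + log1p(exp(-abs(a)))
}

elu <- function(a) ifelse(a > 0, a, expm1(a))
elu_grad <- function(a) ifelse(a > 0, 1, exp(a))

act_apply <- function(a, name) {
  switch(name,
    elu = elu(a),
    tanh = tanh(a),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

# gradient wrt pre-activation; `h` is the activated value, `a` the pre-activation
act_grad <- function(a, h, name) {
  switch(name,
    elu = elu_grad(a),
    tanh = 1 - h^2,
    stop("unknown activation: ", name, call. = FALSE)
  )
}

clip_unit <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

# derive a per-component RNG seed from a base seed; stays inside 32-bit range
make_seed <- function(base, k) {
  as.integer((as.numeric(base) * 1009 + 97 * as.numeric(k)) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
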