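# Numerically stable pieces shared across the package.

# log(1 + exp(x)) without overflow; vectorized.
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  # x > 33.3: log1p(exp(x)) == x to double precision
  out
}

# Bernoulli log-density on the logit scale: y*x - log(1+exp(x)); never +/-Inf
# for finite x.
bernoulli_loglik_logit <- function(y, x) {
  y * x - log1pexp(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score columns, returning centers/scales for later reuse (prediction,
# cross-validation folds).
zscore <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
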