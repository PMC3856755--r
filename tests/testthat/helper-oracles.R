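# Independent brute-force oracles used across the suite. These are written
# against the definitions, not against the package internals.

# cell-by-cell masked Bernoulli log-likelihood
oracle_loglik <- function(web, params, traits) {
  total <- 0
  for (i in seq_len(nrow(web$links))) {
    for (j in seq_len(ncol(web$links))) {
      if (web$mask[i, j] == 1) {
        p <- link_probability(params, traits, i, j)
        a <- web$links[i, j]
        total <- total + a * log(p) + (1 - a) * log(1 - p)
      }
    }
  }
  total
}

# all-pairs AUC with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Wilcoxon signed-rank V plus exact two-sided p by enumerating all 2^n sign
# patterns (requires no zero differences and no ties in |d|)
oracle_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ranks <- rank(abs(d))
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(ranks[signs == 1])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  p <- mean(abs(vs - mu) >= abs(V - mu))
  list(V = V, p = p)
}

random_params <- function(P, B, plant_ids = NULL, butterfly_ids = NULL) {
  V <- matrix(rnorm(P * 2), P, 2)
  Fm <- matrix(rnorm(B * 2), B, 2)
  rownames(V) <- plant_ids %||% sprintf("plant_%02d", 1:P)
  rownames(Fm) <- butterfly_ids %||% sprintf("butterfly_%02d", 1:B)
  d <- sort(abs(rnorm(2)), decreasing = TRUE)
  link_params(rnorm(1), rnorm(1), rnorm(1), d, V, Fm)
}

random_traits <- function(P) {
  data.frame(nitrogen = rnorm(P), avg_height = rnorm(P))
}

random_web <- function(P, B, p_link = 0.4, p_mask = 0.7) {
  trophic_web(matrix(rbinom(P * B, 1, p_link), P, B),
              matrix(rbinom(P * B, 1, p_mask), P, B))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small 3-taxon worked tree used in several oracles
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
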