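#' Parameters of the latent-trait link model
#'
#' The probability of a trophic link between plant i and butterfly j is
#' modelled on the logit scale as
#' \deqn{logit(p_{ij}) = \alpha + \beta_1 N_i + \beta_2 AvH_i
#'   + \delta_1 v_i^{(1)} f_j^{(1)} + \delta_2 v_i^{(2)} f_j^{(2)}}
#' where N and AvH are the plant's leaf nitrogen content and average canopy
#' height, v are per-plant latent susceptibility traits, f per-butterfly
#' latent foraging traits, and \eqn{\delta_1 \ge \delta_2 \ge 0} are scaling
#' factors (the ordering resolves label switching between the two latent
#' dimensions).
#'
#' @param alpha intercept on the logit scale.
#' @param beta_nitrogen,beta_height slopes of the two measured plant traits.
#' @param delta length-2 non-negative vector, decreasing.
#' @param plant_latents numeric matrix, one row per plant, two columns
#'   (rownames = plant ids).
#' @param butterfly_latents numeric matrix, one row per butterfly, two
#'   columns (rownames = butterfly ids).
#' @return an object of class `link_params`.
#' @export
link_params <- function(alpha, beta_nitrogen, beta_height, delta,
                        plant_latents, butterfly_latents) {
  delta <- as.numeric(delta)
  if (length(delta) != 2 || delta[1] < delta[2] || delta[2] < 0)
    stopf("delta must satisfy delta[1] >= delta[2] >= 0")
  plant_latents <- as.matrix(plant_latents)
  butterfly_latents <- as.matrix(butterfly_latents)
  if (ncol(plant_latents) != 2 || ncol(butterfly_latents) != 2)
    stopf("latent trait matrices must have two columns")
  vals <- c(alpha, beta_nitrogen, beta_height, delta,
            plant_latents, butterfly_latents)
  if (!all(is.finite(vals))) stopf("all parameters must be finite")
  structure(
    list(alpha = alpha, beta_nitrogen = beta_nitrogen,
         beta_height = beta_height, delta = delta,
         plant_latents = plant_latents,
         butterfly_latents = butterfly_latents),
    class = "link_params")
}

#' @export
print.link_params <- function(x, ...) {
  cat("Latent-trait link model parameters\n")
  cat(sprintf("  alpha = %.4f, beta_N = %.4f, beta_AvH = %.4f\n",
              x$alpha, x$beta_nitrogen, x$beta_height))
  cat(sprintf("  delta = (%.4f, %.4f)\n", x$delta[1], x$delta[2]))
  cat(sprintf("  latent traits: %d plants, %d butterflies (2 dimensions)\n",
              nrow(x$plant_latents), nrow(x$butterfly_latents)))
  invisible(x)
}

# Full matrix of logits for all plant x butterfly pairs.
# traits: data.frame/matrix with columns nitrogen, avg_height aligned with
# the rows of params$plant_latents.
link_logit_matrix <- function(params, traits) {
  n <- traits[["nitrogen"]]
  h <- traits[["avg_height"]]
  if (length(n) != nrow(params$plant_latents))
    stopf("trait table has %d rows but %d plants have latent traits",
          length(n), nrow(params$plant_latents))
  if (!all(is.finite(n)) || !all(is.finite(h)))
    stopf("non-finite trait value")
  lin <- params$alpha + params$beta_nitrogen * n + params$beta_height * h
  lin +
    params$delta[1] * tcrossprod(params$plant_latents[, 1],
                                 params$butterfly_latents[, 1]) +
    params$delta[2] * tcrossprod(params$plant_latents[, 2],
                                 params$butterfly_latents[, 2])
}

#' Probability of a trophic link for given plant/butterfly pairs
#'
#' Evaluates the latent-trait logistic model for the requested cells.
#' Indices recycle against each other, so a single plant against all
#' butterflies (or vice versa) works.
#'
#' @param params a [link_params].
#' @param traits data frame with columns `nitrogen` and `avg_height`, one row
#'   per plant, aligned with `params$plant_latents`.
#' @param plant,butterfly row/column indices (or species labels).
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @examples
#' pars <- link_params(0, 0.145, 0, c(0, 0),
#'   matrix(0, 1, 2), matrix(0, 1, 2))
#' link_probability(pars, data.frame(nitrogen = 2, avg_height = 0), 1, 1)
#' @export
link_probability <- function(params, traits, plant, butterfly) {
  if (is.character(plant))
    plant <- match(plant, rownames(params$plant_latents))
  if (is.character(butterfly))
    butterfly <- match(butterfly, rownames(params$butterfly_latents))
  np <- nrow(params$plant_latents)
  nb <- nrow(params$butterfly_latents)
  if (anyNA(plant) || any(plant < 1) || any(plant > np))
    stopf("plant index out of range (1..%d)", np)
  if (anyNA(butterfly) || any(butterfly < 1) || any(butterfly > nb))
    stopf("butterfly index out of range (1..%d)", nb)
  n <- traits[["nitrogen"]][plant]
  h <- traits[["avg_height"]][plant]
  if (!all(is.finite(n)) || !all(is.finite(h)))
    stopf("non-finite trait value for requested plant")
  x <- params$alpha + params$beta_nitrogen * n + params$beta_height * h +
    params$delta[1] * params$plant_latents[plant, 1] *
      params$butterfly_latents[butterfly, 1] +
    params$delta[2] * params$plant_latents[plant, 2] *
      params$butterfly_latents[butterfly, 2]
  unname(stats::plogis(x))
}

#' Masked Bernoulli log-likelihood of a trophic web
#'
#' Sum over knowable cells (`mask == 1`) of the Bernoulli log-density of the
#' observed link under the latent-trait model; masked cells contribute
#' exactly zero. Computed on the logit scale, so finite parameters never
#' yield infinite terms.
#'
#' @inheritParams link_probability
#' @param web a [trophic_web].
#' @return scalar log-likelihood.
#' @export
web_loglik <- function(web, params, traits) {
  if (nrow(web$links) != nrow(params$plant_latents) ||
      ncol(web$links) != nrow(params$butterfly_latents))
    stopf("web shape does not match parameter dimensions")
  x <- link_logit_matrix(params, traits)
  sum(web$mask * bernoulli_loglik_logit(web$links, x))
}

# Log prior density under the identifiable weakly-informative prior:
# latents ~ N(0,1); alpha, beta ~ N(0, sd_linear); delta ~ half-normal
# (sd_delta) subject to delta1 >= delta2 >= 0 (violation -> -Inf).
log_prior <- function(params, priors = list()) {
  sd_linear <- priors$sd_linear %||% 10
  sd_delta <- priors$sd_delta %||% 10
  sd_latent <- priors$sd_latent %||% 1
  d <- params$delta
  if (d[1] < d[2] || d[2] < 0) return(-Inf)
  sum(stats::dnorm(c(params$alpha, params$beta_nitrogen,
                     params$beta_height), 0, sd_linear, log = TRUE)) +
    sum(stats::dnorm(d, 0, sd_delta, log = TRUE) + log(2)) +
    sum(stats::dnorm(params$plant_latents, 0, sd_latent, log = TRUE)) +
    sum(stats::dnorm(params$butterfly_latents, 0, sd_latent, log = TRUE))
}

#' Log posterior of the latent-trait link model
#'
#' `web_loglik()` plus the log prior used by [fit_trophic_model()]. States
#' violating the \eqn{\delta_1 \ge \delta_2 \ge 0} ordering have density
#' zero (`-Inf`).
#'
#' @inheritParams web_loglik
#' @param priors list with elements `sd_linear` (default 10), `sd_delta`
#'   (default 10), `sd_latent` (default 1).
#' @return scalar log posterior density (up to a constant).
#' @export
log_posterior <- function(web, params, traits, priors = list()) {
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + web_loglik(web, params, traits)
}

#' Predict the full link-probability matrix
#'
#' Dense matrix of link probabilities over all plant x butterfly pairs,
#' including pairs that were masked during fitting. Every listed species
#' must carry latent traits (fitted or imputed); plants must have measured
#' traits.
#'
#' @inheritParams link_probability
#' @param plant_ids,butterfly_ids species to include; default all species in
#'   `params`.
#' @return matrix of probabilities with a `provenance` attribute (per-species
#'   `"fitted"`/`"imputed"` flags when `params` carries them).
#' @export
predict_link_matrix <- function(params, traits, plant_ids = NULL,
                                butterfly_ids = NULL) {
  rn_p <- rownames(params$plant_latents) %||%
    as.character(seq_len(nrow(params$plant_latents)))
  rn_b <- rownames(params$butterfly_latents) %||%
    as.character(seq_len(nrow(params$butterfly_latents)))
  plant_ids <- plant_ids %||% rn_p
  butterfly_ids <- butterfly_ids %||% rn_b
  pi <- match(plant_ids, rn_p)
  bi <- match(butterfly_ids, rn_b)
  if (anyNA(pi))
    stopf("no latent traits for plant(s): %s",
          paste(plant_ids[is.na(pi)], collapse = ", "))
  if (anyNA(bi))
    stopf("no latent traits for butterfly(s): %s",
          paste(butterfly_ids[is.na(bi)], collapse = ", "))
  sub <- link_params(params$alpha, params$beta_nitrogen, params$beta_height,
                     params$delta,
                     params$plant_latents[pi, , drop = FALSE],
                     params$butterfly_latents[bi, , drop = FALSE])
  tr <- data.frame(nitrogen = traits[["nitrogen"]][pi],
                   avg_height = traits[["avg_height"]][pi])
  p <- stats::plogis(link_logit_matrix(sub, tr))
  dimnames(p) <- list(plant_ids, butterfly_ids)
  prov <- attr(params, "provenance")
  if (!is.null(prov))
    attr(p, "provenance") <- list(plants = prov$plants[plant_ids],
                                  butterflies = prov$butterflies[butterfly_ids])
  p
}
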