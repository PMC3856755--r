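#' MCMC control settings for the link model
#'
#' @param n_iter total Metropolis-Hastings iterations.
#' @param burn_in iterations discarded before retaining samples
#'   (default `n_iter / 2`).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param prop_linear,prop_delta,prop_latent Gaussian random-walk proposal
#'   standard deviations for the (alpha, beta) block, the delta block, and
#'   each species' latent pair.
#' @param adapt adapt proposal scales toward ~30% acceptance during burn-in
#'   only (the retained chain stays Markovian).
#' @param fix_delta optional length-2 vector; when given, delta is held fixed
#'   (e.g. `c(0, 0)` collapses the model to plain logistic regression on the
#'   measured traits).
#' @param sd_linear,sd_delta,sd_latent prior standard deviations (see
#'   [log_posterior()]).
#' @return a list of class `trophic_control`.
#' @export
trophic_control <- function(n_iter = 20000, burn_in = NULL, thin = 10,
                            prop_linear = 0.15, prop_delta = 0.15,
                            prop_latent = 0.4, adapt = TRUE,
                            fix_delta = NULL, sd_linear = 10,
                            sd_delta = 10, sd_latent = 1) {
  burn_in <- burn_in %||% floor(n_iter / 2)
  if (burn_in >= n_iter) stopf("burn_in must be smaller than n_iter")
  if (min(prop_linear, prop_delta, prop_latent) <= 0)
    stopf("proposal scales must be positive")
  if (!is.null(fix_delta)) {
    fix_delta <- as.numeric(fix_delta)
    if (length(fix_delta) != 2 || fix_delta[1] < fix_delta[2] ||
        fix_delta[2] < 0)
      stopf("fix_delta must satisfy fix_delta[1] >= fix_delta[2] >= 0")
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 prop_linear = prop_linear, prop_delta = prop_delta,
                 prop_latent = prop_latent, adapt = adapt,
                 fix_delta = fix_delta, sd_linear = sd_linear,
                 sd_delta = sd_delta, sd_latent = sd_latent),
            class = "trophic_control")
}

#' Fit the latent-trait trophic link model by Metropolis-Hastings MCMC
#'
#' Block-wise Gaussian random-walk Metropolis-Hastings over the intercept and
#' trait slopes, the two latent-scale factors delta (subject to
#' \eqn{\delta_1 \ge \delta_2 \ge 0}), and each species' latent-trait pair.
#' Only knowable cells (`web$mask == 1`) enter the likelihood. Measured
#' traits are z-scored internally; reported slopes are on the standardized
#' scale and the centering/scaling is stored for prediction.
#'
#' After sampling, the sign of each latent dimension is aligned across
#' retained samples (to the first retained sample, by the inner product of
#' plant latents) so that posterior-mean latent traits are meaningful for
#' downstream phylogenetic regression; link probabilities themselves are
#' invariant to these sign flips.
#'
#' @param web a [trophic_web] with at least one knowable cell.
#' @param traits data frame with columns `species`, `nitrogen`, `avg_height`
#'   covering every plant in the web (any order; matched by label), or
#'   without a `species` column when already aligned with the web rows.
#' @param control a [trophic_control].
#' @param seed integer seed; the chain is bit-reproducible given
#'   (control, seed).
#' @return an object of class `trophic_fit`; see [coef.trophic_fit()],
#'   [fitted.trophic_fit()], [predict.trophic_fit()], [summary.trophic_fit()].
#' @export
fit_trophic_model <- function(web, traits, control = trophic_control(),
                              seed = 1) {
  stopifnot(inherits(web, "trophic_web"))
  if (sum(web$mask) == 0)
    stopf("no information: the web has zero knowable cells")
  A <- web$links
  Z <- web$mask
  P <- nrow(A); B <- ncol(A)

  if (!is.null(traits$species)) {
    idx <- match(web$plant_ids, traits$species)
    if (anyNA(idx))
      stopf("traits missing for plant(s): %s",
            paste(web$plant_ids[is.na(idx)], collapse = ", "))
    traits <- traits[idx, , drop = FALSE]
  } else if (nrow(traits) != P) {
    stopf("trait table has %d rows for %d plants", nrow(traits), P)
  }
  raw <- cbind(nitrogen = as.numeric(traits$nitrogen),
               avg_height = as.numeric(traits$avg_height))
  if (!all(is.finite(raw))) stopf("non-finite trait value")
  Xs <- zscore(raw)
  Nz <- Xs[, 1]; Hz <- Xs[, 2]

  ctl <- control
  priors <- list(sd_linear = ctl$sd_linear, sd_delta = ctl$sd_delta,
                 sd_latent = ctl$sd_latent)
  set.seed(seed)

  # --- state ---------------------------------------------------------------
  ab <- c(stats::qlogis(max(min(mean(A[Z == 1]), 0.99), 0.01)), 0, 0)
  if (is.null(ctl$fix_delta)) d <- c(1, 0.5) else d <- ctl$fix_delta
  V <- matrix(stats::rnorm(P * 2, 0, 0.1), P, 2)
  Fm <- matrix(stats::rnorm(B * 2, 0, 0.1), B, 2)

  cell_ll <- function() {
    lin <- ab[1] + ab[2] * Nz + ab[3] * Hz
    X <- lin + d[1] * tcrossprod(V[, 1], Fm[, 1]) +
      d[2] * tcrossprod(V[, 2], Fm[, 2])
    Z * bernoulli_loglik_logit(A, X)
  }
  row_ll <- function(i, Vi) {
    x <- ab[1] + ab[2] * Nz[i] + ab[3] * Hz[i] +
      d[1] * Vi[1] * Fm[, 1] + d[2] * Vi[2] * Fm[, 2]
    Z[i, ] * bernoulli_loglik_logit(A[i, ], x)
  }
  col_ll <- function(j, Fj) {
    x <- ab[1] + ab[2] * Nz + ab[3] * Hz +
      d[1] * V[, 1] * Fj[1] + d[2] * V[, 2] * Fj[2]
    Z[, j] * bernoulli_loglik_logit(A[, j], x)
  }
  LL <- cell_ll()

  # proposal scales (latents share one adapted scale per guild)
  sc <- c(linear = ctl$prop_linear, delta = ctl$prop_delta,
          plant = ctl$prop_latent, butterfly = ctl$prop_latent)
  acc <- c(linear = 0, delta = 0, plant = 0, butterfly = 0)
  try_n <- c(linear = 0, delta = 0, plant = 0, butterfly = 0)
  acc_b <- acc; try_b <- try_n  # per-batch counters for adaptation

  update_delta <- is.null(ctl$fix_delta)
  n_keep <- floor((ctl$n_iter - ctl$burn_in) / ctl$thin)
  chain <- matrix(NA_real_, n_keep, 6,
                  dimnames = list(NULL, c("alpha", "beta_nitrogen",
                                          "beta_height", "delta1", "delta2",
                                          "log_post")))
  V_samp <- array(NA_real_, c(n_keep, P, 2))
  F_samp <- array(NA_real_, c(n_keep, B, 2))
  p_mean <- matrix(0, P, B)
  k <- 0L
  n_p <- 0L

  lp_linear <- function(v) sum(stats::dnorm(v, 0, ctl$sd_linear, log = TRUE))
  lp_delta <- function(v) {
    if (v[1] < v[2] || v[2] < 0) return(-Inf)
    sum(stats::dnorm(v, 0, ctl$sd_delta, log = TRUE))
  }
  lp_lat <- function(v) sum(stats::dnorm(v, 0, ctl$sd_latent, log = TRUE))

  for (it in seq_len(ctl$n_iter)) {
    # (alpha, beta) block
    ab_new <- ab + stats::rnorm(3, 0, sc["linear"])
    lp0 <- sum(LL) + lp_linear(ab)
    ab_old <- ab; ab <- ab_new
    LL_new <- cell_ll()
    lp1 <- sum(LL_new) + lp_linear(ab_new)
    try_n["linear"] <- try_n["linear"] + 1; try_b["linear"] <- try_b["linear"] + 1
    if (log(stats::runif(1)) < lp1 - lp0) {
      LL <- LL_new
      acc["linear"] <- acc["linear"] + 1; acc_b["linear"] <- acc_b["linear"] + 1
    } else ab <- ab_old

    # delta block
    if (update_delta) {
      d_new <- d + stats::rnorm(2, 0, sc["delta"])
      lpd1 <- lp_delta(d_new)
      try_n["delta"] <- try_n["delta"] + 1; try_b["delta"] <- try_b["delta"] + 1
      if (is.finite(lpd1)) {
        lp0 <- sum(LL) + lp_delta(d)
        d_old <- d; d <- d_new
        LL_new <- cell_ll()
        lp1 <- sum(LL_new) + lpd1
        if (log(stats::runif(1)) < lp1 - lp0) {
          LL <- LL_new
          acc["delta"] <- acc["delta"] + 1; acc_b["delta"] <- acc_b["delta"] + 1
        } else d <- d_old
      }
    }

    # plant latent pairs (row-local likelihood)
    for (i in seq_len(P)) {
      v_new <- V[i, ] + stats::rnorm(2, 0, sc["plant"])
      ll_new <- row_ll(i, v_new)
      lr <- sum(ll_new) - sum(LL[i, ]) + lp_lat(v_new) - lp_lat(V[i, ])
      try_n["plant"] <- try_n["plant"] + 1; try_b["plant"] <- try_b["plant"] + 1
      if (log(stats::runif(1)) < lr) {
        V[i, ] <- v_new
        LL[i, ] <- ll_new
        acc["plant"] <- acc["plant"] + 1; acc_b["plant"] <- acc_b["plant"] + 1
      }
    }

    # butterfly latent pairs (column-local likelihood)
    for (j in seq_len(B)) {
      f_new <- Fm[j, ] + stats::rnorm(2, 0, sc["butterfly"])
      ll_new <- col_ll(j, f_new)
      lr <- sum(ll_new) - sum(LL[, j]) + lp_lat(f_new) - lp_lat(Fm[j, ])
      try_n["butterfly"] <- try_n["butterfly"] + 1
      try_b["butterfly"] <- try_b["butterfly"] + 1
      if (log(stats::runif(1)) < lr) {
        Fm[j, ] <- f_new
        LL[, j] <- ll_new
        acc["butterfly"] <- acc["butterfly"] + 1
        acc_b["butterfly"] <- acc_b["butterfly"] + 1
      }
    }

    # burn-in-only scale adaptation toward ~0.3 acceptance
    if (ctl$adapt && it <= ctl$burn_in && it %% 50 == 0) {
      rate <- ifelse(try_b > 0, acc_b / try_b, 0.3)
      sc <- sc * exp(0.5 * (rate - 0.3))
      sc <- pmin(pmax(sc, 1e-3), 10)
      acc_b[] <- 0; try_b[] <- 0
    }

    if (it > ctl$burn_in) {
      # p_mean is Rao-Blackwellised over every post-burn-in iteration, not
      # just the thinned draws kept for the chain
      lin <- ab[1] + ab[2] * Nz + ab[3] * Hz
      X <- lin + d[1] * tcrossprod(V[, 1], Fm[, 1]) +
        d[2] * tcrossprod(V[, 2], Fm[, 2])
      p_mean <- p_mean + stats::plogis(X)
      n_p <- n_p + 1L
    }
    if (it > ctl$burn_in && (it - ctl$burn_in) %% ctl$thin == 0) {
      k <- k + 1L
      chain[k, ] <- c(ab, d,
                      sum(LL) + lp_linear(ab) +
                        (if (update_delta) lp_delta(d) + 2 * log(2) else 0) +
                        lp_lat(V) + lp_lat(Fm))
      V_samp[k, , ] <- V
      F_samp[k, , ] <- Fm
    }
  }
  p_mean <- p_mean / n_p
  dimnames(p_mean) <- dimnames(web$links)

  # sign alignment: per latent dimension, flip samples whose plant latents
  # point away from the first retained sample
  flips <- matrix(1, k, 2)
  for (dd in 1:2) {
    ref <- V_samp[1, , dd]
    s <- sign(V_samp[, , dd] %*% ref)
    s[s == 0] <- 1
    V_samp[, , dd] <- V_samp[, , dd] * as.vector(s)
    F_samp[, , dd] <- F_samp[, , dd] * as.vector(s)
    flips[, dd] <- s
  }

  V_mean <- apply(V_samp, c(2, 3), mean)
  F_mean <- apply(F_samp, c(2, 3), mean)
  rownames(V_mean) <- web$plant_ids
  rownames(F_mean) <- web$butterfly_ids
  post <- link_params(mean(chain[, "alpha"]), mean(chain[, "beta_nitrogen"]),
                      mean(chain[, "beta_height"]),
                      sort(colMeans(chain[, c("delta1", "delta2")]),
                           decreasing = TRUE),
                      V_mean, F_mean)
  attr(post, "provenance") <- list(
    plants = stats::setNames(rep("fitted", P), web$plant_ids),
    butterflies = stats::setNames(rep("fitted", B), web$butterfly_ids))

  structure(
    list(params = post, p_mean = p_mean, chain = as.data.frame(chain),
         plant_latent_samples = V_samp, butterfly_latent_samples = F_samp,
         acceptance = acc / pmax(try_n, 1), proposal_scales = sc,
         web = web, trait_center = attr(Xs, "center"),
         trait_scale = attr(Xs, "scale"), traits_std = Xs,
         control = ctl, priors = priors, seed = seed, n_kept = k),
    class = "trophic_fit")
}

#' @export
print.trophic_fit <- function(x, ...) {
  cat("Latent-trait trophic link model (Metropolis-Hastings MCMC)\n")
  print(x$web)
  cat(sprintf("  %d iterations (%d burn-in, thin %d) -> %d retained samples\n",
              x$control$n_iter, x$control$burn_in, x$control$thin, x$n_kept))
  cat("  acceptance rates: ",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n", sep = "")
  cat("  posterior means (standardized trait scale):\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.trophic_fit <- function(object, ...) {
  p <- object$params
  c(alpha = p$alpha, beta_nitrogen = p$beta_nitrogen,
    beta_height = p$beta_height, delta1 = p$delta[1], delta2 = p$delta[2])
}

#' Posterior-mean link probabilities on the fitted web
#'
#' The posterior mean of \eqn{p_{ij}} over retained samples (not the
#' probability at the posterior-mean parameters), for every cell of the
#' fitted web including masked ones.
#'
#' @param object a `trophic_fit`.
#' @param ... unused.
#' @export
fitted.trophic_fit <- function(object, ...) object$p_mean

#' @export
logLik.trophic_fit <- function(object, ...) {
  tr <- data.frame(nitrogen = object$traits_std[, 1],
                   avg_height = object$traits_std[, 2])
  ll <- web_loglik(object$web, object$params, tr)
  structure(ll, df = 5 + 2 * (nrow(object$traits_std) +
                                nrow(object$params$butterfly_latents)),
            class = "logLik")
}

#' Summarize the posterior chain
#'
#' Posterior means, standard deviations, batch-means Monte-Carlo standard
#' errors and central 95% intervals for the scalar parameters.
#'
#' @param object a `trophic_fit`.
#' @param n_batches batches for the batch-means MCSE (default 30).
#' @param ... unused.
#' @return data frame, one row per scalar parameter.
#' @export
summary.trophic_fit <- function(object, n_batches = 30, ...) {
  ch <- object$chain[, c("alpha", "beta_nitrogen", "beta_height",
                         "delta1", "delta2")]
  n <- nrow(ch)
  nb <- min(n_batches, n)
  batch <- sort(rep_len(seq_len(nb), n))
  mcse <- vapply(ch, function(v) {
    bm <- tapply(v, batch, mean)
    stats::sd(bm) / sqrt(nb)
  }, numeric(1))
  out <- data.frame(
    mean = colMeans(ch),
    sd = vapply(ch, stats::sd, numeric(1)),
    mcse = mcse,
    q2.5 = vapply(ch, stats::quantile, numeric(1), probs = 0.025),
    q97.5 = vapply(ch, stats::quantile, numeric(1), probs = 0.975))
  class(out) <- c("summary.trophic_fit", "data.frame")
  out
}

#' Predict link probabilities for arbitrary species sets
#'
#' Wraps [predict_link_matrix()] with the fit's posterior-mean parameters.
#' New plants must come with measured traits (raw scale; the fit's stored
#' z-scoring is applied) and both guilds may include species with imputed
#' latent traits (see [impute_all_latents()]).
#'
#' @param object a `trophic_fit`.
#' @param traits raw-scale trait data frame with a `species` column covering
#'   all requested plants; defaults to the training plants.
#' @param plant_ids,butterfly_ids species to predict for.
#' @param plant_latents,butterfly_latents optional latent-trait matrices
#'   (rownames = species) extending/overriding the fitted posterior means.
#' @param ... unused.
#' @return probability matrix (see [predict_link_matrix()]).
#' @export
predict.trophic_fit <- function(object, traits = NULL, plant_ids = NULL,
                                butterfly_ids = NULL, plant_latents = NULL,
                                butterfly_latents = NULL, ...) {
  params <- object$params
  prov <- attr(params, "provenance")
  if (!is.null(plant_latents)) {
    add <- setdiff(rownames(plant_latents), rownames(params$plant_latents))
    params$plant_latents <- rbind(
      params$plant_latents[setdiff(rownames(params$plant_latents),
                                   rownames(plant_latents)), , drop = FALSE],
      plant_latents)
    prov$plants[rownames(plant_latents)] <-
      ifelse(rownames(plant_latents) %in% add, "imputed", "fitted")
  }
  if (!is.null(butterfly_latents)) {
    add <- setdiff(rownames(butterfly_latents),
                   rownames(params$butterfly_latents))
    params$butterfly_latents <- rbind(
      params$butterfly_latents[setdiff(rownames(params$butterfly_latents),
                                       rownames(butterfly_latents)), ,
                               drop = FALSE],
      butterfly_latents)
    prov$butterflies[rownames(butterfly_latents)] <-
      ifelse(rownames(butterfly_latents) %in% add, "imputed", "fitted")
  }
  attr(params, "provenance") <- prov
  plant_ids <- plant_ids %||% rownames(params$plant_latents)
  butterfly_ids <- butterfly_ids %||% rownames(params$butterfly_latents)

  # z-scored traits aligned with the rows of params$plant_latents: training
  # plants from the stored standardized table, new plants from `traits`
  # (raw scale) via the stored centering/scaling
  all_plants <- rownames(params$plant_latents)
  std <- matrix(NA_real_, length(all_plants), 2,
                dimnames = list(all_plants, c("nitrogen", "avg_height")))
  train <- intersect(all_plants, object$web$plant_ids)
  std[train, ] <- object$traits_std[match(train, object$web$plant_ids), ]
  if (!is.null(traits)) {
    hit <- intersect(all_plants, traits$species)
    idx <- match(hit, traits$species)
    raw <- cbind(as.numeric(traits$nitrogen[idx]),
                 as.numeric(traits$avg_height[idx]))
    std[hit, ] <- zscore(raw, object$trait_center, object$trait_scale)
  }
  if (anyNA(match(plant_ids, all_plants)))
    stopf("no latent traits for plant(s): %s",
          paste(setdiff(plant_ids, all_plants), collapse = ", "))
  need <- all_plants[match(plant_ids, all_plants)]
  if (anyNA(std[need, ]))
    stopf("no measured traits for plant(s): %s",
          paste(unique(need[rowSums(is.na(std[need, , drop = FALSE])) > 0]),
                collapse = ", "))
  tr <- data.frame(nitrogen = std[, 1], avg_height = std[, 2])
  predict_link_matrix(params, tr, plant_ids, butterfly_ids)
}

#' Trace plots of the scalar chain
#'
#' @param x a `trophic_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trophic_fit <- function(x, ...) {
  pars <- c("alpha", "beta_nitrogen", "beta_height", "delta1", "delta2")
  old <- graphics::par(mfrow = c(2, 3), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars)
    graphics::plot(x$chain[[p]], type = "l", main = p, xlab = "sample",
                   ylab = "", ...)
  graphics::plot(x$chain$log_post, type = "l", main = "log posterior",
                 xlab = "sample", ylab = "")
  invisible(x)
}
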