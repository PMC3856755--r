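#' Stack per-species probabilities into a site community
#'
#' Threshold-independent stacking: the predicted richness is the rounded sum
#' of the per-species presence probabilities, and the predicted community is
#' the `richness` highest-probability species (ties broken deterministically
#' by species-id order). A probabilistic variant draws independent Bernoulli
#' presences instead.
#'
#' @param probabilities named vector of per-species probabilities at one
#'   site.
#' @param method `"deterministic"` (default, rank selection) or
#'   `"resample"` (seeded Bernoulli draws).
#' @param seed used by the resampling variant only.
#' @return list with `richness` (integer) and `species` (character vector).
#' @export
stack_site <- function(probabilities, method = c("deterministic", "resample"),
                       seed = 1) {
  method <- match.arg(method)
  p <- probabilities
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  ids <- names(p) %||% as.character(seq_along(p))
  if (method == "resample") {
    set.seed(seed)
    draw <- stats::rbinom(length(p), 1, p)
    return(list(richness = sum(draw), species = ids[draw == 1]))
  }
  rich <- as.integer(round(sum(p)))
  if (rich == 0) return(list(richness = 0L, species = character(0)))
  ord <- order(-p, ids)
  list(richness = rich, species = sort(ids[ord[seq_len(rich)]]))
}

#' Sorensen similarity between predicted and observed species sets
#'
#' `2a / (2a + b + c)` with `a` the number of species both observed and
#' predicted, `b` observed only, `c` predicted only. Two empty sets count as
#' perfect agreement (1).
#'
#' @param predicted,observed character vectors of species ids.
#' @return value in [0, 1].
#' @export
sorensen <- function(predicted, observed) {
  predicted <- unique(predicted)
  observed <- unique(observed)
  a <- length(intersect(predicted, observed))
  b <- length(setdiff(observed, predicted))
  c_ <- length(setdiff(predicted, observed))
  if (a + b + c_ == 0) return(1)
  2 * a / (2 * a + b + c_)
}

#' Signed richness residual
#'
#' Predicted minus observed species richness (sign convention recorded in
#' evaluation output; medians of absolute residuals are unaffected by it).
#'
#' @param predicted,observed non-negative integer richness values.
#' @return signed integer.
#' @export
richness_residual <- function(predicted, observed) {
  as.integer(predicted) - as.integer(observed)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a randomly chosen presence is scored above a randomly
#' chosen absence, with ties counted 1/2.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return value in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stopf("AUC undefined: labels contain a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired Wilcoxon signed-rank test
#'
#' Thin wrapper around [stats::wilcox.test()] with the conventions used
#' throughout the evaluation: zero differences dropped, exact null for
#' n <= 25 without ties, normal approximation with continuity correction
#' otherwise, two-sided by default.
#'
#' @param x,y paired samples of equal length.
#' @param alternative passed to [stats::wilcox.test()].
#' @return named vector `(V, p.value)`.
#' @export
paired_signed_rank <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- x - y
  if (all(d == 0)) {
    warnf("all paired differences are zero")
    return(c(V = 0, p.value = 1))
  }
  nz <- d != 0
  n <- sum(nz)
  exact <- n <= 25 && !any(duplicated(abs(d[nz])))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                       exact = exact, correct = TRUE))
  c(V = unname(wt$statistic), p.value = wt$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with g - 1 degrees of freedom). All
#' values identical yields H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return named vector `(H, p.value)`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(lengths(groups) < 1)) stopf("every group needs >= 1 value")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) return(c(H = 0, p.value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(vals, g)
  c(H = unname(kt$statistic), p.value = kt$p.value)
}

#' Stack and evaluate community predictions for one technique x tag
#'
#' Builds the site x species out-of-fold probability matrix from a list of
#' [cross_validate()] results, stacks each site, and scores it against the
#' observed butterfly community.
#'
#' @param cv_list list of `cv_result` objects (one per species) sharing the
#'   same sites.
#' @param observed site x species 0/1 matrix of observed communities.
#' @return data frame with per-site `sorensen`, `residual` (predicted -
#'   observed richness), `richness_pred`, `richness_obs`.
#' @export
evaluate_communities <- function(cv_list, observed) {
  sp <- vapply(cv_list, function(x) x$species, character(1))
  P <- do.call(cbind, lapply(cv_list, function(x) x$site_prob))
  colnames(P) <- sp
  obs <- as.matrix(observed)[, sp, drop = FALSE]
  out <- data.frame(site = rownames(obs) %||% seq_len(nrow(obs)),
                    sorensen = NA_real_, residual = NA_integer_,
                    richness_pred = NA_integer_, richness_obs = NA_integer_)
  for (s in seq_len(nrow(obs))) {
    st <- stack_site(stats::setNames(P[s, ], sp))
    obs_set <- sp[obs[s, ] == 1]
    out$sorensen[s] <- sorensen(st$species, obs_set)
    out$richness_pred[s] <- st$richness
    out$richness_obs[s] <- length(obs_set)
    out$residual[s] <- richness_residual(st$richness, length(obs_set))
  }
  out
}

#' Compare predictive accuracy across predictor sets
#'
#' For every technique present: paired Wilcoxon signed-rank tests of
#' per-species AUCs (each biotic predictor set against the abiotic
#' baseline), of per-site Sorensen similarities and of absolute richness
#' residuals; optionally a Kruskal-Wallis comparison of food-web predictive
#' performance across butterfly families.
#'
#' @param cv_by_tag named list (tag -> list of `cv_result`, one per species,
#'   same species order and fold seeds across tags).
#' @param observed site x species 0/1 matrix of observed communities.
#' @param family_map optional named character vector species -> family.
#' @param baseline the reference tag (default `"abiotic"`).
#' @return object of class `evaluation_report`: `species_auc` (long table),
#'   `site_metrics`, `tests`, and `kruskal_wallis` (or NULL).
#' @export
compare_models <- function(cv_by_tag, observed, family_map = NULL,
                           baseline = "abiotic") {
  tags <- names(cv_by_tag)
  if (!(baseline %in% tags)) stopf("baseline tag '%s' not supplied", baseline)
  sp_of <- function(l) vapply(l, function(x) x$species, character(1))
  tech_of <- function(l) vapply(l, function(x) x$technique, character(1))
  ref_sp <- sp_of(cv_by_tag[[baseline]])
  for (tg in tags) {
    if (!identical(sp_of(cv_by_tag[[tg]]), ref_sp))
      stopf("species coverage differs between tags '%s' and '%s'",
            baseline, tg)
  }

  species_auc <- do.call(rbind, lapply(tags, function(tg) {
    l <- cv_by_tag[[tg]]
    data.frame(species = sp_of(l), technique = tech_of(l), tag = tg,
               auc = vapply(l, function(x) x$auc, numeric(1)))
  }))

  site_metrics <- do.call(rbind, lapply(tags, function(tg) {
    cm <- evaluate_communities(cv_by_tag[[tg]], observed)
    cbind(tag = tg, technique = cv_by_tag[[tg]][[1]]$technique, cm)
  }))

  tests <- NULL
  base_auc <- species_auc[species_auc$tag == baseline, ]
  base_cm <- site_metrics[site_metrics$tag == baseline, ]
  for (tg in setdiff(tags, baseline)) {
    t_auc <- species_auc[species_auc$tag == tg, ]
    t_cm <- site_metrics[site_metrics$tag == tg, ]
    w_auc <- paired_signed_rank(t_auc$auc, base_auc$auc)
    w_sor <- paired_signed_rank(t_cm$sorensen, base_cm$sorensen)
    w_res <- paired_signed_rank(abs(t_cm$residual), abs(base_cm$residual))
    tests <- rbind(tests, data.frame(
      comparison = paste(tg, "vs", baseline),
      metric = c("species AUC", "site Sorensen", "|richness residual|"),
      V = c(w_auc["V"], w_sor["V"], w_res["V"]),
      p.value = c(w_auc["p.value"], w_sor["p.value"], w_res["p.value"]),
      median_tag = c(stats::median(t_auc$auc),
                     stats::median(t_cm$sorensen),
                     stats::median(abs(t_cm$residual))),
      median_baseline = c(stats::median(base_auc$auc),
                          stats::median(base_cm$sorensen),
                          stats::median(abs(base_cm$residual)))))
  }

  kw <- NULL
  fw_tag <- grep("foodweb", tags, value = TRUE)
  if (!is.null(family_map) && length(fw_tag) == 1) {
    t_auc <- species_auc[species_auc$tag == fw_tag, ]
    fam <- family_map[t_auc$species]
    groups <- split(t_auc$auc, fam)
    groups <- groups[lengths(groups) >= 1]
    if (length(groups) >= 2) kw <- kruskal_wallis(groups)
  }

  structure(list(species_auc = species_auc, site_metrics = site_metrics,
                 tests = tests, kruskal_wallis = kw,
                 baseline = baseline,
                 residual_convention = "predicted - observed"),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Model comparison report (baseline:", x$baseline, ")\n")
  agg <- stats::aggregate(auc ~ tag + technique, x$species_auc,
                          stats::median)
  cat("  median species AUC by tag:\n")
  print(agg, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("  paired Wilcoxon tests vs baseline:\n")
    print(x$tests, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$kruskal_wallis))
    cat(sprintf("  Kruskal-Wallis across families: H = %.3f, P = %.4g\n",
                x$kruskal_wallis["H"], x$kruskal_wallis["p.value"]))
  invisible(x)
}
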