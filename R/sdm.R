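#' "Best-case scenario" trophic term for one site
#'
#' The maximum modelled link probability between the focal butterfly and any
#' plant present at the site; 0 when no plant is present (no host available
#' is the worst case for an herbivore).
#'
#' @param plant_presence_row 0/1 vector of plant presences at one site.
#' @param link_probabilities_for_butterfly link probabilities of the focal
#'   butterfly with the same plants, same order.
#' @return scalar in [0, 1].
#' @export
trophic_term <- function(plant_presence_row, link_probabilities_for_butterfly) {
  if (length(plant_presence_row) != length(link_probabilities_for_butterfly))
    stopf("presence row (%d) and link probabilities (%d) differ in length",
          length(plant_presence_row),
          length(link_probabilities_for_butterfly))
  present <- plant_presence_row > 0
  if (!any(present)) return(0)
  max(link_probabilities_for_butterfly[present])
}

# Site-vectorized trophic term: site x plant matrix against one butterfly's
# link-probability vector.
trophic_term_sites <- function(plant_occ, link_probs) {
  if (ncol(plant_occ) != length(link_probs))
    stopf("plant occurrence table and link probabilities disagree")
  apply(plant_occ, 1, trophic_term, link_probabilities_for_butterfly = link_probs)
}

#' Literature-based host presence term
#'
#' 1 when at least one known host plant (from the literature) is present at
#' the site, 0 otherwise. Host ids not present among the plant columns are
#' ignored with a warning.
#'
#' @param plant_presence_row named 0/1 vector of plant presences at one site.
#' @param known_host_set character vector of host plant ids.
#' @return 0 or 1.
#' @export
literature_term <- function(plant_presence_row, known_host_set) {
  ids <- names(plant_presence_row)
  unknown <- setdiff(known_host_set, ids)
  if (length(unknown) > 0)
    warnf("unknown plant id(s) in host set ignored: %s",
          paste(unknown, collapse = ", "))
  hosts <- intersect(known_host_set, ids)
  if (length(hosts) == 0) return(0L)
  as.integer(any(plant_presence_row[hosts] > 0))
}

#' Build the per-site predictor matrix for one butterfly species
#'
#' Abiotic block: linear and quadratic terms of z-scored degree-days
#' (`ddeg`), moisture index (`mind`) and solar radiation (`srad`) — six
#' columns, identical across predictor sets. Depending on `tag`, a seventh
#' biotic column is appended: the literature host-presence indicator or the
#' food-web trophic term.
#'
#' @param study an occurrence study: list with `env` (data frame with
#'   columns ddeg, mind, srad), `plant_occ` (site x plant 0/1 matrix).
#' @param species focal butterfly id (used to pick the link-matrix column).
#' @param tag one of `"abiotic"`, `"abiotic+literature"`,
#'   `"abiotic+foodweb"`.
#' @param link_matrix plants x butterflies probability matrix (required for
#'   the foodweb tag).
#' @param literature named list of host-id vectors per butterfly (required
#'   for the literature tag).
#' @param center,scale optional centering/scaling of the three abiotic
#'   variables (e.g. from a training fold); defaults computed from `study`.
#' @return numeric matrix, sites x predictors, with `center`/`scale`
#'   attributes.
#' @export
build_predictors <- function(study, species, tag = "abiotic",
                             link_matrix = NULL, literature = NULL,
                             center = NULL, scale = NULL) {
  tag <- match.arg(tag, c("abiotic", "abiotic+literature",
                          "abiotic+foodweb"))
  env <- as.matrix(study$env[, c("ddeg", "mind", "srad")])
  z <- zscore(env, center, scale)
  X <- cbind(ddeg = z[, 1], mind = z[, 2], srad = z[, 3],
             ddeg2 = z[, 1]^2, mind2 = z[, 2]^2, srad2 = z[, 3]^2)
  if (tag == "abiotic+foodweb") {
    if (is.null(link_matrix))
      stopf("abiotic+foodweb predictors require a link matrix")
    lp <- link_matrix[colnames(study$plant_occ), species]
    X <- cbind(X, trophic = trophic_term_sites(study$plant_occ, lp))
  } else if (tag == "abiotic+literature") {
    if (is.null(literature))
      stopf("abiotic+literature predictors require a host list")
    hosts <- literature[[species]] %||% character(0)
    X <- cbind(X, host = apply(study$plant_occ, 1, literature_term,
                               known_host_set = hosts))
  }
  rownames(X) <- rownames(study$plant_occ)
  attr(X, "center") <- attr(z, "center")
  attr(X, "scale") <- attr(z, "scale")
  attr(X, "tag") <- tag
  X
}

#' Fit one species distribution model
#'
#' Four techniques, matching common practice in distribution modelling:
#' `glm` — binomial GLM on the linear + quadratic abiotic columns (plus the
#' biotic column when present); `gam` — [mgcv::gam()] with thin-plate
#' smooths of the three abiotic gradients and a linear biotic term; `gbm` —
#' gradient boosted trees (xgboost backend; depth 2, eta 0.1, 100 rounds);
#' `rf` — [randomForest::randomForest()] (500 trees). All are deterministic
#' given `seed`.
#'
#' @param presence 0/1 response vector (>= `min_presences` presences
#'   required; the default mirrors the usual modelling filter for rare
#'   species).
#' @param predictors matrix from [build_predictors()].
#' @param technique one of `"glm"`, `"gam"`, `"gbm"`, `"rf"`.
#' @param seed integer seed.
#' @param min_presences refusal threshold; [cross_validate()] applies the
#'   10-occurrence filter to the full dataset and lowers this bound for the
#'   90% training folds.
#' @return object of class `sdm_fit`.
#' @export
fit_sdm <- function(presence, predictors, technique = "glm", seed = 1,
                    min_presences = 10) {
  technique <- match.arg(technique, c("glm", "gam", "gbm", "rf"))
  y <- as.integer(presence)
  X <- as.matrix(predictors)
  if (sum(y) < min_presences)
    stopf("refusing to fit: only %d presences (< %d)", sum(y),
          min_presences)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warnf("dropping constant predictor column(s): %s",
          paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  set.seed(seed)
  df <- data.frame(y = y, X)
  model <- switch(
    technique,
    glm = stats::glm(y ~ ., data = df, family = stats::binomial()),
    gam = {
      smooth <- intersect(c("ddeg", "mind", "srad"), colnames(X))
      lin <- setdiff(colnames(X), c(smooth, "ddeg2", "mind2", "srad2"))
      form <- stats::as.formula(paste(
        "y ~", paste(c(sprintf("s(%s, k = 5)", smooth), lin),
                     collapse = " + ")))
      mgcv::gam(form, data = df, family = stats::binomial(),
                method = "REML")
    },
    gbm = xgboost::xgboost(
      X, factor(y, levels = c(0, 1)), objective = "binary:logistic",
      nrounds = 100, max_depth = 2, learning_rate = 0.1,
      nthreads = 1, seed = seed %% .Machine$integer.max),
    rf = randomForest::randomForest(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)), ntree = 500))
  structure(list(technique = technique, model = model,
                 columns = colnames(X), seed = seed,
                 tag = attr(predictors, "tag")),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("SDM fit: technique = %s, predictors = %s (%d columns)\n",
              x$technique, x$tag %||% "custom", length(x$columns)))
  invisible(x)
}

#' Predict presence probabilities from a fitted SDM
#'
#' @param fit an `sdm_fit`.
#' @param predictors matrix whose columns must include the training schema.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_sdm <- function(fit, predictors) {
  X <- as.matrix(predictors)
  miss <- setdiff(fit$columns, colnames(X))
  if (length(miss) > 0)
    stopf("predictor schema mismatch; missing column(s): %s",
          paste(miss, collapse = ", "))
  X <- X[, fit$columns, drop = FALSE]
  p <- switch(
    fit$technique,
    glm = stats::predict(fit$model, newdata = as.data.frame(X),
                         type = "response"),
    gam = as.numeric(stats::predict(fit$model, newdata = as.data.frame(X),
                                    type = "response")),
    gbm = stats::predict(fit$model, X, type = "response"),
    rf = stats::predict(fit$model, newdata = as.data.frame(X),
                        type = "prob")[, "1"])
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# Presence-stratified fold assignment; depends only on (y, k, seed) so the
# same folds are reused across predictor sets and techniques.
make_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Tenfold cross-validation of one species x technique x predictor set
#'
#' Sites are split into `k` folds stratified by presence/absence (so no
#' training fold is single-class); the assignment depends only on the
#' response and the seed, hence is identical across predictor sets and
#' techniques — the paired design needed for Wilcoxon comparisons. Abiotic
#' standardization is computed on each training fold and applied to its test
#' fold.
#'
#' @param study occurrence study (list with `env`, `plant_occ`,
#'   `butterfly_occ`).
#' @param species focal butterfly id (column of `study$butterfly_occ`).
#' @param technique,tag see [fit_sdm()] / [build_predictors()].
#' @param k number of folds.
#' @param seed integer seed (drives only the fold assignment and technique
#'   randomness).
#' @param link_matrix,literature forwarded to [build_predictors()].
#' @return object of class `cv_result`: `site_prob` (out-of-fold probability
#'   per site), `fold`, `auc`, plus identifiers.
#' @export
cross_validate <- function(study, species, technique = "glm",
                           tag = "abiotic", k = 10, seed = 1,
                           link_matrix = NULL, literature = NULL) {
  y <- as.integer(study$butterfly_occ[, species])
  folds <- make_folds(y, k, seed)
  prob <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2)
      stopf("training fold %d is single-class; too few presences for k = %d",
            f, k)
    study_tr <- list(env = study$env[tr, , drop = FALSE],
                     plant_occ = study$plant_occ[tr, , drop = FALSE])
    Xtr <- build_predictors(study_tr, species, tag, link_matrix, literature)
    Xall <- build_predictors(study, species, tag, link_matrix, literature,
                             center = attr(Xtr, "center"),
                             scale = attr(Xtr, "scale"))
    fit <- suppressWarnings(
      fit_sdm(y[tr], Xtr, technique, seed = seed + f, min_presences = 1))
    prob[!tr] <- predict_sdm(fit, Xall[!tr, , drop = FALSE])
  }
  structure(list(species = species, technique = technique, tag = tag,
                 k = k, seed = seed, site_prob = prob, fold = folds,
                 observed = y, auc = auc(prob, y)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: %s / %s / %s -> AUC %.3f\n",
              x$k, x$species, x$technique, x$tag, x$auc))
  invisible(x)
}
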