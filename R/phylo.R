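#' Shared-time matrix of an ultrametric phylogeny
#'
#' For each pair of tips, the fraction of evolutionary time shared since the
#' root: depth of their most recent common ancestor divided by total tree
#' depth. Diagonal exactly 1; symmetric; entries in [0, 1]. The tree must be
#' ultrametric within a relative tolerance of `tol` (the matrix is otherwise
#' ill-defined); trees are never rescaled.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param tol maximum allowed relative spread of root-to-tip depths.
#' @return symmetric matrix with tip labels as dimnames.
#' @export
shared_time_matrix <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stopf("duplicate tip labels")
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  tip_depth <- depths[seq_len(n)]
  depth <- max(tip_depth)
  if (depth <= 0) stopf("tree depth is zero")
  dev <- (max(tip_depth) - min(tip_depth)) / depth
  if (dev > tol)
    stopf("tree is not ultrametric: relative depth deviation %.3g > %.3g",
          dev, tol)
  mr <- ape::mrca(tree)
  t_ij <- matrix(depths[mr], n, n, dimnames = dimnames(mr)) / depth
  diag(t_ij) <- 1
  t_ij
}

#' Phylogenetic variance-covariance matrix under Pagel's lambda
#'
#' `C(lambda)` has diagonal `sigma2` and off-diagonal
#' `sigma2 * lambda * t_ij`: `lambda = 0` gives iid variation (star
#' phylogeny), `lambda = 1` full Brownian covariance proportional to shared
#' time.
#'
#' @param t shared-time matrix from [shared_time_matrix()].
#' @param sigma2 variance (> 0).
#' @param lambda Pagel's lambda in [0, 1].
#' @return covariance matrix.
#' @export
lambda_vcv <- function(t, sigma2, lambda) {
  if (sigma2 <= 0) stopf("sigma2 must be positive")
  if (lambda < 0 || lambda > 1) stopf("lambda must lie in [0, 1]")
  C <- sigma2 * lambda * t
  diag(C) <- sigma2
  C
}

#' Intercept-only phylogenetic regression with Pagel's-lambda correlation
#'
#' Maximizes the multivariate-normal log-likelihood of `values ~ mu * 1`
#' with covariance `C(lambda)` over (mu, sigma2, lambda). At each lambda the
#' GLS estimates of mu and the ML variance are closed-form, so lambda is
#' found by a profile search on [0, 1]: an 11-point grid pre-scan followed by
#' [stats::optimize()] in the bracketing interval (tolerance 1e-4). A single
#' eigendecomposition of the shared-time matrix makes each profile
#' evaluation O(n).
#'
#' @param values named numeric vector of one trait value per tip (names must
#'   match tip labels; tips without values are dropped from the tree).
#' @param tree an ultrametric [ape::phylo].
#' @return an object of class `lambda_fit` with elements `mu`, `sigma2`,
#'   `lambda`, `loglik`, `loglik0` (profile log-likelihood at lambda = 0),
#'   `n`, `tips`.
#' @export
fit_lambda_regression <- function(values, tree) {
  if (is.null(names(values))) stopf("values must be named by tip label")
  keep <- names(values)[is.finite(values)]
  miss <- setdiff(keep, tree$tip.label)
  if (length(miss) > 0)
    stopf("tips absent from tree: %s", paste(miss, collapse = ", "))
  if (length(keep) < 3) stopf("need at least 3 tips with values")
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  fit_lambda_core(values, shared_time_matrix(tree))
}

# Profile-likelihood engine shared by fit_lambda_regression() (tree input)
# and impute_all_latents() (pre-built shared-time matrix, so that fitting
# and imputation use identical time fractions).
fit_lambda_core <- function(values, t_ij) {
  y <- values[rownames(t_ij)]
  n <- length(y)

  # R(lambda) = (1-lambda) I + lambda T ; one eigendecomposition serves all
  # profile evaluations
  eig <- eigen(t_ij, symmetric = TRUE)
  yt <- drop(crossprod(eig$vectors, y))
  ot <- drop(crossprod(eig$vectors, rep(1, n)))

  profile <- function(lambda) {
    w <- (1 - lambda) + lambda * eig$values
    if (any(w < 1e-12)) return(list(ll = -Inf))
    mu <- sum(ot * yt / w) / sum(ot^2 / w)
    r2 <- (yt - mu * ot)^2
    s2 <- sum(r2 / w) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
    list(ll = ll, mu = mu, sigma2 = s2)
  }

  grid <- seq(0, 1, length.out = 11)
  gll <- vapply(grid, function(l) profile(l)$ll, numeric(1))
  best <- which.max(gll)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(function(l) profile(l)$ll, c(lo, hi),
                         maximum = TRUE, tol = 1e-4)
  cand <- rbind(c(opt$maximum, opt$objective),
                cbind(unname(grid), unname(gll)))
  lambda <- unname(cand[which.max(cand[, 2]), 1])
  at <- profile(lambda)
  if (!is.finite(at$ll)) stopf("singular phylogenetic covariance")
  structure(
    list(mu = at$mu, sigma2 = at$sigma2, lambda = lambda, loglik = at$ll,
         loglik0 = profile(0)$ll, n = n, tips = rownames(t_ij)),
    class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  ts <- lambda_signal_test(x)
  cat(sprintf(
    "Pagel's-lambda phylogenetic regression (%d tips)\n", x$n))
  cat(sprintf("  lambda = %.4f, mu = %.4f, sigma2 = %.4f\n",
              x$lambda, x$mu, x$sigma2))
  cat(sprintf("  logLik = %.3f (lambda = 0: %.3f); LRT = %.3f, P = %.3g\n",
              x$loglik, x$loglik0, ts["statistic"], ts["p.value"]))
  invisible(x)
}

#' Likelihood-ratio test of phylogenetic signal (lambda = 0)
#'
#' The null hypothesis lambda = 0 lies on the boundary of [0, 1], so the LRT
#' statistic `2 * (loglik(lambda_hat) - loglik(0))` is referred to the 50:50
#' mixture of a point mass at zero and a chi-square with one degree of
#' freedom.
#'
#' @param fit a `lambda_fit`.
#' @return named vector `(statistic, p.value)`.
#' @export
lambda_signal_test <- function(fit) {
  stat <- max(0, 2 * (fit$loglik - fit$loglik0))
  p <- if (stat <= 0) 1 else
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  c(statistic = stat, p.value = p)
}

#' Impute a trait for unobserved tips by conditional expectation
#'
#' Kriging on the phylogeny: with the trait jointly normal under the fitted
#' `C(lambda)`, the best predictor for a target tip x given the observed
#' tips o is `mu + C_xo C_oo^{-1} (y_o - mu)`. At lambda = 0 the
#' cross-covariance vanishes and every prediction collapses to mu; a target
#' perfectly correlated with an observed tip reproduces its value.
#'
#' @param fit a `lambda_fit` (provides mu, sigma2, lambda).
#' @param t shared-time matrix covering observed and target tips.
#' @param observed named vector of known trait values.
#' @param targets tip labels to predict (disjoint from `names(observed)`).
#' @return named vector of predictions.
#' @export
impute_latent <- function(fit, t, observed, targets) {
  obs <- names(observed)
  if (length(intersect(obs, targets)) > 0)
    stopf("targets must be disjoint from observed tips")
  miss <- setdiff(c(obs, targets), rownames(t))
  if (length(miss) > 0)
    stopf("tips absent from shared-time matrix: %s",
          paste(miss, collapse = ", "))
  C <- lambda_vcv(t, fit$sigma2, fit$lambda)
  Coo <- C[obs, obs, drop = FALSE]
  Cxo <- C[targets, obs, drop = FALSE]
  sol <- tryCatch(solve(Coo, observed - fit$mu),
                  error = function(e) stopf("singular covariance among observed tips: %s",
                                            conditionMessage(e)))
  stats::setNames(drop(fit$mu + Cxo %*% sol), targets)
}

#' Fit and impute all four latent-trait dimensions
#'
#' Each guild carries two latent dimensions (plant susceptibility v1, v2;
#' butterfly foraging f1, f2). Each dimension is regressed on its phylogeny
#' independently with [fit_lambda_regression()] and extrapolated to species
#' without fitted values via [impute_latent()], using only species with at
#' least one recorded interaction as the conditioning set.
#'
#' @param plant_latents,butterfly_latents 2-column matrices of fitted latent
#'   means, rownames = species (e.g. from a [fit_trophic_model()] fit).
#' @param plant_tree,butterfly_tree ultrametric [ape::phylo] trees covering
#'   all species.
#' @param plant_ids,butterfly_ids full species lists to cover (default: all
#'   tree tips).
#' @return list with completed `plant_latents` and `butterfly_latents`
#'   matrices (all requested species), `provenance` flags
#'   (`"fitted"`/`"imputed"`), and the four `lambda_fit` records in `fits`.
#' @export
impute_all_latents <- function(plant_latents, plant_tree,
                               butterfly_latents, butterfly_tree,
                               plant_ids = NULL, butterfly_ids = NULL) {
  do_guild <- function(lat, tree, ids, label) {
    ids <- ids %||% tree$tip.label
    miss <- setdiff(ids, tree$tip.label)
    if (length(miss) > 0)
      stopf("%s species absent from tree: %s", label,
            paste(miss, collapse = ", "))
    fitted_sp <- intersect(rownames(lat), ids)
    if (length(fitted_sp) < 3)
      stopf("need >= 3 fitted %s species on the tree", label)
    unknown <- setdiff(ids, fitted_sp)
    t_ij <- shared_time_matrix(ape::keep.tip(tree, ids))
    out <- matrix(NA_real_, length(ids), 2,
                  dimnames = list(ids, colnames(lat) %||% c("dim1", "dim2")))
    out[fitted_sp, ] <- lat[fitted_sp, ]
    fits <- vector("list", 2)
    for (d in 1:2) {
      vals <- stats::setNames(lat[fitted_sp, d], fitted_sp)
      fits[[d]] <- fit_lambda_core(vals, t_ij[fitted_sp, fitted_sp])
      if (length(unknown) > 0)
        out[unknown, d] <- impute_latent(fits[[d]], t_ij, vals, unknown)
    }
    prov <- stats::setNames(
      ifelse(ids %in% fitted_sp, "fitted", "imputed"), ids)
    list(latents = out, fits = fits, provenance = prov)
  }
  pl <- do_guild(plant_latents, plant_tree, plant_ids, "plant")
  bf <- do_guild(butterfly_latents, butterfly_tree, butterfly_ids,
                 "butterfly")
  list(plant_latents = pl$latents, butterfly_latents = bf$latents,
       provenance = list(plants = pl$provenance,
                         butterflies = bf$provenance),
       fits = list(plant_v1 = pl$fits[[1]], plant_v2 = pl$fits[[2]],
                   butterfly_f1 = bf$fits[[1]],
                   butterfly_f2 = bf$fits[[2]]))
}
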