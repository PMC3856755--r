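#' Configuration of a synthetic plant-butterfly study
#'
#' Defaults describe a mid-sized alpine-grassland style study: 30 plants, 40
#' butterflies, 150 sites along an elevation-like gradient; latent traits
#' with strong phylogenetic signal (lambda 0.8, within the range estimated
#' for real plant-herbivore webs); link-model parameters alpha = -1,
#' beta = (1, 0.5), delta = (2, 1) on the standardized trait scale; leaf
#' nitrogen in % dry mass and canopy height in cm; and trophic coupling
#' gamma = 3 on the logit of butterfly occupancy (a trophically constrained
#' community; gamma = 0 gives the null, trophically unconstrained case).
#'
#' @param n_plants,n_butterflies,n_sites problem dimensions (counts >= 3).
#' @param lambda named/unnamed length-4 vector of Pagel's lambda for the
#'   latent dimensions (plant v1, v2; butterfly f1, f2).
#' @param sigma2 length-4 vector of latent-trait variances.
#' @param alpha,beta,delta link-model parameters (standardized trait scale);
#'   `beta = c(nitrogen, height)`, `delta` decreasing non-negative.
#' @param nitrogen_mean,nitrogen_sd leaf nitrogen distribution (% dry mass).
#' @param height_meanlog,height_sdlog log-normal canopy height (cm).
#' @param gamma trophic coupling strength (>= 0) on the butterfly occupancy
#'   logit.
#' @param plant_prevalence,butterfly_prevalence ranges of target occupancy
#'   rates used to centre the quadratic niches.
#' @param niche_width width (in gradient SD units) of the quadratic niches.
#' @param seed mandatory integer seed; every artifact is reproducible from
#'   (config, seed).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plants = 30, n_butterflies = 40,
                             n_sites = 150,
                             lambda = c(0.8, 0.8, 0.8, 0.8),
                             sigma2 = c(1, 1, 1, 1),
                             alpha = -1, beta = c(1, 0.5), delta = c(2, 1),
                             nitrogen_mean = 2.5, nitrogen_sd = 0.6,
                             height_meanlog = log(30), height_sdlog = 0.5,
                             gamma = 3,
                             plant_prevalence = c(0.05, 0.5),
                             butterfly_prevalence = c(0.15, 0.5),
                             niche_width = 1.5,
                             seed = 1) {
  if (min(n_plants, n_butterflies) < 3 || n_sites < 3)
    stopf("species and site counts must be >= 3")
  if (gamma < 0) stopf("gamma must be >= 0")
  if (is.null(seed)) stopf("seed is mandatory")
  lambda <- rep_len(lambda, 4)
  sigma2 <- rep_len(sigma2, 4)
  if (any(lambda < 0 | lambda > 1)) stopf("lambda must lie in [0, 1]")
  if (delta[1] < delta[2] || delta[2] < 0)
    stopf("delta must satisfy delta[1] >= delta[2] >= 0")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' Yule (pure-birth) tree with depth normalized to 1, so shared-time
#' fractions read directly off node depths.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed (byte-identical Newick for equal seeds).
#' @param prefix tip-label prefix.
#' @return an [ape::phylo].
#' @export
simulate_tree <- function(n_tips, seed = 1, prefix = "t") {
  if (n_tips < 3) stopf("need at least 3 tips")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("%s%0*d", prefix,
                            nchar(as.character(n_tips)), seq_len(n_tips))
  tree
}

#' Draw phylogenetically structured trait values
#'
#' One draw from the multivariate normal with mean `mu` and covariance
#' `lambda_vcv(shared_time_matrix(tree), sigma2, lambda)` — the generative
#' counterpart of [fit_lambda_regression()].
#'
#' @param tree ultrametric [ape::phylo].
#' @param lambda,sigma2,mu covariance parameters.
#' @param seed integer seed.
#' @return named vector, one value per tip.
#' @export
simulate_latents <- function(tree, lambda, sigma2 = 1, mu = 0, seed = 1) {
  t_ij <- shared_time_matrix(tree)
  C <- lambda_vcv(t_ij, sigma2, lambda)
  # tiny ridge keeps the Cholesky stable at lambda = 1 on deep trees
  L <- chol(C + diag(1e-10, nrow(C)))
  set.seed(seed)
  z <- stats::rnorm(nrow(C))
  stats::setNames(mu + drop(crossprod(L, z)), rownames(t_ij))
}

#' Simulate a trophic web from the latent-trait link model
#'
#' Independent Bernoulli draws with `a_ij ~ Bernoulli(p_ij)` where `p_ij`
#' comes from [link_probability()]; the mask is all ones (co-occurrence
#' masking is applied later from the simulated landscape).
#'
#' @param params a [link_params].
#' @param traits trait data frame aligned with `params$plant_latents`.
#' @param seed integer seed.
#' @return a [trophic_web] (full mask) with the true probability matrix in
#'   attribute `"p_true"`.
#' @export
simulate_web <- function(params, traits, seed = 1) {
  p <- stats::plogis(link_logit_matrix(params, traits))
  dimnames(p) <- list(rownames(params$plant_latents),
                      rownames(params$butterfly_latents))
  set.seed(seed)
  A <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p),
              dimnames = dimnames(p))
  web <- trophic_web(A)
  attr(web, "p_true") <- p
  web
}

# Quadratic niche logit on standardized environment, centred per species so
# that the mean presence probability matches a target prevalence (keeps the
# landscape usable for distribution modelling at any gamma).
niche_logit <- function(env_z, optima, width, extra = 0, prevalence) {
  quad <- -rowSums(sweep(env_z, 2, optima, "-")^2) / (2 * width^2)
  base <- quad + extra
  f <- function(b0) mean(stats::plogis(base + b0)) - prevalence
  b0 <- stats::uniroot(f, c(-30, 30))$root
  base + b0
}

#' Simulate site environments and plant/butterfly occurrences
#'
#' Sites sit along an elevation-like gradient: degree-days decline with it,
#' the moisture index rises, solar radiation varies independently. Plants
#' follow quadratic logistic niches in the standardized environment;
#' butterflies follow their own niches plus `gamma` times the "best-case"
#' trophic term computed from the true link probabilities and the realized
#' plant presences.
#'
#' @param config a [synthetic_config].
#' @param link_matrix_truth true plants x butterflies probability matrix.
#' @param seed integer seed.
#' @return list with `env` (data frame: site, ddeg, mind, srad),
#'   `plant_occ`, `butterfly_occ` (site x species 0/1 matrices) and
#'   per-species truth (`plant_niche`, `butterfly_niche`, `trophic`).
#' @export
simulate_occurrences <- function(config, link_matrix_truth, seed = 1) {
  ns <- config$n_sites
  set.seed(seed)
  elev <- stats::runif(ns)
  ddeg <- 3000 - 2200 * elev + stats::rnorm(ns, 0, 120)
  mind <- -400 + 800 * elev + stats::rnorm(ns, 0, 60)
  srad <- 18000 + 3000 * stats::rnorm(ns)
  env <- data.frame(ddeg = ddeg, mind = mind, srad = srad)
  rownames(env) <- sprintf("site_%03d", seq_len(ns))
  env_z <- zscore(env)

  plants <- rownames(link_matrix_truth)
  butterflies <- colnames(link_matrix_truth)

  plant_opt <- matrix(stats::runif(length(plants) * 3, -1.5, 1.5),
                      ncol = 3)
  plant_prev <- stats::runif(length(plants), config$plant_prevalence[1],
                             config$plant_prevalence[2])
  plant_occ <- matrix(0L, ns, length(plants),
                      dimnames = list(rownames(env), plants))
  for (i in seq_along(plants)) {
    lg <- niche_logit(env_z, plant_opt[i, ], config$niche_width,
                      prevalence = plant_prev[i])
    plant_occ[, i] <- stats::rbinom(ns, 1, stats::plogis(lg))
  }

  bf_opt <- matrix(stats::runif(length(butterflies) * 3, -1.5, 1.5),
                   ncol = 3)
  bf_prev <- stats::runif(length(butterflies),
                          config$butterfly_prevalence[1],
                          config$butterfly_prevalence[2])
  bf_occ <- matrix(0L, ns, length(butterflies),
                   dimnames = list(rownames(env), butterflies))
  trophic <- matrix(0, ns, length(butterflies),
                    dimnames = list(rownames(env), butterflies))
  for (j in seq_along(butterflies)) {
    tt <- trophic_term_sites(plant_occ, link_matrix_truth[, j])
    trophic[, j] <- tt
    lg <- niche_logit(env_z, bf_opt[j, ], config$niche_width,
                      extra = config$gamma * tt, prevalence = bf_prev[j])
    bf_occ[, j] <- stats::rbinom(ns, 1, stats::plogis(lg))
  }

  list(env = env, plant_occ = plant_occ, butterfly_occ = bf_occ,
       plant_niche = list(optima = plant_opt, prevalence = plant_prev),
       butterfly_niche = list(optima = bf_opt, prevalence = bf_prev),
       trophic = trophic)
}

#' Generate a complete synthetic study with ground truth
#'
#' Composes the simulators into the five standard inputs — partially
#' observed trophic web with its co-occurrence mask, plant trait table, two
#' ultrametric phylogenies, site occupancy tables and site environments —
#' and attaches the generating truth (parameters, latent traits, true link
#' probabilities, niche models). The global seed is expanded into fixed
#' per-component substreams, so the study is bit-reproducible and adding a
#' component never perturbs earlier draws.
#'
#' @param config a [synthetic_config].
#' @return object of class `synthetic_study` with elements `web` (masked),
#'   `web_full` (pre-masking), `traits`, `plant_tree`, `butterfly_tree`,
#'   `occurrences`, `truth`, `config`, `masked_fraction`.
#' @export
make_study <- function(config = synthetic_config()) {
  s <- config$seed
  plant_tree <- simulate_tree(config$n_plants, seed = s + 101L,
                              prefix = "plant_")
  butterfly_tree <- simulate_tree(config$n_butterflies, seed = s + 102L,
                                  prefix = "butterfly_")

  V <- cbind(
    simulate_latents(plant_tree, config$lambda[1], config$sigma2[1],
                     seed = s + 111L),
    simulate_latents(plant_tree, config$lambda[2], config$sigma2[2],
                     seed = s + 112L))
  Fm <- cbind(
    simulate_latents(butterfly_tree, config$lambda[3], config$sigma2[3],
                     seed = s + 113L),
    simulate_latents(butterfly_tree, config$lambda[4], config$sigma2[4],
                     seed = s + 114L))
  colnames(V) <- c("v1", "v2"); colnames(Fm) <- c("f1", "f2")

  set.seed(s + 121L)
  traits <- data.frame(
    species = plant_tree$tip.label,
    nitrogen = stats::rnorm(config$n_plants, config$nitrogen_mean,
                            config$nitrogen_sd),
    avg_height = stats::rlnorm(config$n_plants, config$height_meanlog,
                               config$height_sdlog))
  # the generating model applies its betas on the standardized trait scale,
  # matching the fitting convention
  tz <- zscore(traits[, c("nitrogen", "avg_height")])
  traits_std <- data.frame(nitrogen = tz[, 1], avg_height = tz[, 2])

  params <- link_params(config$alpha, config$beta[1], config$beta[2],
                        config$delta, V, Fm)
  web_full <- simulate_web(params, traits_std, seed = s + 131L)
  p_true <- attr(web_full, "p_true")

  occ <- simulate_occurrences(config, p_true, seed = s + 141L)
  mask <- compute_cooccurrence_mask(occ$plant_occ, occ$butterfly_occ)
  web <- trophic_web(web_full$links, mask)

  structure(
    list(web = web, web_full = web_full, traits = traits,
         plant_tree = plant_tree, butterfly_tree = butterfly_tree,
         occurrences = occ[c("env", "plant_occ", "butterfly_occ")],
         truth = list(params = params, p_matrix = p_true,
                      traits_std = traits_std,
                      plant_niche = occ$plant_niche,
                      butterfly_niche = occ$butterfly_niche,
                      trophic_term = occ$trophic, gamma = config$gamma),
         config = config,
         masked_fraction = 1 - mean(mask)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic plant-butterfly study (seed %d)\n", x$config$seed))
  cat(sprintf("  %d plants, %d butterflies, %d sites; gamma = %g\n",
              x$config$n_plants, x$config$n_butterflies, x$config$n_sites,
              x$config$gamma))
  cat(sprintf("  never-co-occurring pairs: %.1f%%\n",
              100 * x$masked_fraction))
  invisible(x)
}

#' Write a synthetic study to the standard on-disk formats
#'
#' CSV tables (web, mask, traits, occurrences, environments), Newick trees,
#' and a truth JSON, i.e. exactly the formats the fitting side reads.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    web = file.path(dir, "web.csv"),
    mask = file.path(dir, "mask.csv"),
    traits = file.path(dir, "traits.csv"),
    plant_tree = file.path(dir, "plant_tree.nwk"),
    butterfly_tree = file.path(dir, "butterfly_tree.nwk"),
    env = file.path(dir, "environment.csv"),
    plant_occ = file.path(dir, "plant_occurrences.csv"),
    butterfly_occ = file.path(dir, "butterfly_occurrences.csv"),
    truth = file.path(dir, "truth.json"))
  write_trophic_web(study$web, paths["web"], paths["mask"])
  utils::write.csv(study$traits, paths["traits"], row.names = FALSE)
  ape::write.tree(study$plant_tree, paths["plant_tree"])
  ape::write.tree(study$butterfly_tree, paths["butterfly_tree"])
  utils::write.csv(cbind(site = rownames(study$occurrences$env),
                         study$occurrences$env),
                   paths["env"], row.names = FALSE)
  utils::write.csv(study$occurrences$plant_occ, paths["plant_occ"])
  utils::write.csv(study$occurrences$butterfly_occ, paths["butterfly_occ"])
  tr <- study$truth
  jsonlite::write_json(
    list(seed = study$config$seed, gamma = tr$gamma,
         alpha = tr$params$alpha,
         beta = c(tr$params$beta_nitrogen, tr$params$beta_height),
         delta = tr$params$delta,
         plant_latents = as.data.frame(tr$params$plant_latents),
         butterfly_latents = as.data.frame(tr$params$butterfly_latents),
         masked_fraction = study$masked_fraction),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
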