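#' Validate a set of study input files
#'
#' Cross-checks species-label agreement between the web, trait table, trees
#' and occurrence tables, and scans the 0/1 tables for illegal values,
#' without fitting anything.
#'
#' @param paths named list/vector with elements `web`, `mask` (optional),
#'   `traits`, `plant_tree`, `butterfly_tree`, `env`, `plant_occ`,
#'   `butterfly_occ` (paths as written by [write_study()]).
#' @return data frame of problems (zero rows when everything is
#'   consistent), columns `file`, `problem`.
#' @export
validate_inputs <- function(paths) {
  problems <- data.frame(file = character(0), problem = character(0))
  note <- function(file, problem)
    problems <<- rbind(problems, data.frame(file = file, problem = problem))
  get <- function(key) if (key %in% names(paths)) paths[[key]] else NULL

  read_01 <- function(path, what) {
    m <- tryCatch(
      as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE)),
      error = function(e) stopf("unreadable file %s: %s", path,
                                conditionMessage(e)))
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad) > 0) {
      rc <- arrayInd(bad[1], dim(m))
      note(path, sprintf("%s contains non-0/1 value %s at row %d, column %d",
                         what, m[bad[1]], rc[1], rc[2]))
    }
    m
  }

  web <- if (!is.null(get("web"))) read_01(get("web"), "web")
  if (!is.null(get("mask"))) {
    mask <- read_01(get("mask"), "mask")
    if (!is.null(web) && !all(dim(mask) == dim(web)))
      note(get("mask"), "mask shape differs from web")
  }
  traits <- if (!is.null(get("traits")))
    tryCatch(utils::read.csv(get("traits")),
             error = function(e) stopf("unreadable file %s: %s",
                                       get("traits"), conditionMessage(e)))
  plant_occ <- if (!is.null(get("plant_occ")))
    read_01(get("plant_occ"), "plant occurrences")
  bf_occ <- if (!is.null(get("butterfly_occ")))
    read_01(get("butterfly_occ"), "butterfly occurrences")

  plants <- if (!is.null(web)) rownames(web) else colnames(plant_occ)
  butterflies <- if (!is.null(web)) colnames(web) else colnames(bf_occ)

  if (!is.null(traits) && !is.null(plants)) {
    orphan <- setdiff(plants, traits$species)
    for (sp in orphan)
      note(get("traits"), sprintf("plant %s has no trait row", sp))
  }
  check_tree <- function(key, ids, guild) {
    if (is.null(get(key)) || is.null(ids)) return()
    tree <- tryCatch(ape::read.tree(get(key)),
                     error = function(e) stopf("unreadable file %s: %s",
                                               get(key), conditionMessage(e)))
    for (sp in setdiff(ids, tree$tip.label))
      note(get(key), sprintf("%s %s missing from tree", guild, sp))
  }
  check_tree("plant_tree", plants, "plant")
  check_tree("butterfly_tree", butterflies, "butterfly")

  if (!is.null(plant_occ) && !is.null(bf_occ) &&
      !identical(rownames(plant_occ), rownames(bf_occ)))
    note(get("butterfly_occ"), "site index differs from plant occurrences")
  if (!is.null(get("env"))) {
    env <- tryCatch(utils::read.csv(get("env")),
                    error = function(e) stopf("unreadable file %s: %s",
                                              get("env"), conditionMessage(e)))
    need <- setdiff(c("ddeg", "mind", "srad"), names(env))
    if (length(need) > 0)
      note(get("env"), paste("missing column(s):",
                             paste(need, collapse = ", ")))
  }
  problems
}

#' Export a fitted link model as JSON
#'
#' All [link_params()] fields plus the control echo and seed, so the fit is
#' regenerable and auditable.
#'
#' @param fit a `trophic_fit`.
#' @param path output path.
#' @export
write_trophic_fit <- function(fit, path) {
  p <- fit$params
  jsonlite::write_json(
    list(alpha = p$alpha, beta_nitrogen = p$beta_nitrogen,
         beta_height = p$beta_height, delta = p$delta,
         plant_latents = cbind(species = rownames(p$plant_latents),
                               as.data.frame(p$plant_latents)),
         butterfly_latents = cbind(species = rownames(p$butterfly_latents),
                                   as.data.frame(p$butterfly_latents)),
         trait_center = as.list(fit$trait_center),
         trait_scale = as.list(fit$trait_scale),
         acceptance = as.list(fit$acceptance),
         control = fit$control[c("n_iter", "burn_in", "thin")],
         seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full synthetic workflow: simulate, fit, impute, model, evaluate
#'
#' Stages: (1) generate a synthetic study and write its files; (2) fit the
#' latent-trait link model by MCMC on the masked web; (3) impute latent
#' traits for species without knowable interactions via the phylogenies and
#' predict the dense link matrix; (4) cross-validate SDMs per butterfly for
#' the requested predictor sets; (5) stack and compare. Stages are
#' idempotent: a stage whose outputs already exist under `out_dir` is
#' skipped (status `"cached"` in the manifest); delete an intermediate to
#' recompute it and everything downstream of it.
#'
#' @param config list (or YAML file path) with optional entries `out_dir`,
#'   `seed`, `synthetic` (arguments to [synthetic_config()]), `mcmc`
#'   (arguments to [trophic_control()]), `techniques`, `tags`, `folds`.
#' @return list of class `run_manifest` (also written as
#'   `manifest.json`): per-stage status and output checksums.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempfile("foodwebsdm_run_")
  seed <- config$seed %||% 1L
  techniques <- config$techniques %||% "glm"
  tags <- config$tags %||% c("abiotic", "abiotic+foodweb")
  folds <- config$folds %||% 10L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(tool = "foodwebSDM",
                   version = as.character(utils::packageVersion("foodwebSDM")),
                   seed = seed, config = config, stages = list())
  record <- function(stage, status, outputs) {
    sums <- tryCatch(tools::md5sum(outputs), error = function(e) NULL)
    manifest$stages[[stage]] <<- list(status = status,
                                      outputs = as.list(sums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  fail <- function(stage, err) {
    record(stage, paste("failed:", conditionMessage(err)), character(0))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(err))
  }

  # stage 1: synthesize --------------------------------------------------
  study_dir <- file.path(out_dir, "study")
  study_rds <- file.path(out_dir, "study_files.txt")
  stage_done <- function(files) length(files) > 0 && all(file.exists(files))
  syn_args <- config$synthetic %||% list()
  syn_args$seed <- syn_args$seed %||% seed
  cfg <- do.call(synthetic_config, syn_args)
  study <- make_study(cfg)
  study_files <- file.path(study_dir,
                           c("web.csv", "mask.csv", "traits.csv",
                             "plant_tree.nwk", "butterfly_tree.nwk",
                             "environment.csv", "plant_occurrences.csv",
                             "butterfly_occurrences.csv", "truth.json"))
  if (stage_done(study_files)) {
    record("synthesize", "cached", study_files)
  } else {
    tryCatch(write_study(study, study_dir), error = function(e)
      fail("synthesize", e))
    record("synthesize", "done", study_files)
  }

  # stage 2: fit the food-web model --------------------------------------
  fit_path <- file.path(out_dir, "foodweb_fit.json")
  fit_rda <- file.path(out_dir, "foodweb_fit_cache.rds")
  if (stage_done(c(fit_path, fit_rda))) {
    fit <- readRDS(fit_rda)
    record("fit-foodweb", "cached", fit_path)
  } else {
    mcmc_args <- config$mcmc %||% list()
    ctl <- do.call(trophic_control, mcmc_args)
    fit <- tryCatch(fit_trophic_model(study$web, study$traits, ctl,
                                      seed = seed),
                    error = function(e) fail("fit-foodweb", e))
    write_trophic_fit(fit, fit_path)
    saveRDS(fit, fit_rda)
    record("fit-foodweb", "done", fit_path)
  }

  # stage 3: impute latents + dense link matrix ---------------------------
  link_path <- file.path(out_dir, "link_matrix.csv")
  lat_path <- file.path(out_dir, "latents.csv")
  if (stage_done(c(link_path, lat_path))) {
    link_matrix <- as.matrix(utils::read.csv(link_path, row.names = 1,
                                             check.names = FALSE))
    record("impute", "cached", c(link_path, lat_path))
  } else {
    imp <- tryCatch(
      impute_all_latents(fit$params$plant_latents, study$plant_tree,
                         fit$params$butterfly_latents, study$butterfly_tree),
      error = function(e) fail("impute", e))
    link_matrix <- tryCatch(
      predict(fit, traits = study$traits,
              plant_latents = imp$plant_latents,
              butterfly_latents = imp$butterfly_latents),
      error = function(e) fail("impute", e))
    utils::write.csv(link_matrix, link_path)
    lat <- rbind(
      data.frame(species = rownames(imp$plant_latents),
                 dim1 = imp$plant_latents[, 1],
                 dim2 = imp$plant_latents[, 2],
                 provenance = imp$provenance$plants, guild = "plant"),
      data.frame(species = rownames(imp$butterfly_latents),
                 dim1 = imp$butterfly_latents[, 1],
                 dim2 = imp$butterfly_latents[, 2],
                 provenance = imp$provenance$butterflies,
                 guild = "butterfly"))
    utils::write.csv(lat, lat_path, row.names = FALSE)
    record("impute", "done", c(link_path, lat_path))
  }

  # stage 4: SDM cross-validation -----------------------------------------
  pred_path <- file.path(out_dir, "cv_predictions.csv")
  cv_rda <- file.path(out_dir, "cv_cache.rds")
  occ <- study$occurrences
  modelable <- colnames(occ$butterfly_occ)[
    colSums(occ$butterfly_occ) >= max(10, folds)]
  if (stage_done(c(pred_path, cv_rda))) {
    cv_by <- readRDS(cv_rda)
    record("fit-sdm", "cached", pred_path)
  } else {
    cv_by <- list()
    for (tech in techniques) {
      for (tg in tags) {
        key <- paste(tech, tg, sep = "|")
        cv_by[[key]] <- tryCatch(
          lapply(modelable, function(sp)
            cross_validate(occ, sp, tech, tg, k = folds, seed = seed,
                           link_matrix = link_matrix)),
          error = function(e) fail("fit-sdm", e))
      }
    }
    preds <- do.call(rbind, lapply(cv_by, function(l)
      do.call(rbind, lapply(l, function(x)
        data.frame(site = rownames(occ$env), species = x$species,
                   technique = x$technique, tag = x$tag,
                   probability = x$site_prob, fold = x$fold)))))
    utils::write.csv(preds, pred_path, row.names = FALSE)
    saveRDS(cv_by, cv_rda)
    record("fit-sdm", "done", pred_path)
  }

  # stage 5: stack + evaluate ---------------------------------------------
  eval_path <- file.path(out_dir, "evaluation.json")
  reports <- list()
  for (tech in techniques) {
    by_tag <- stats::setNames(
      lapply(tags, function(tg) cv_by[[paste(tech, tg, sep = "|")]]), tags)
    reports[[tech]] <- tryCatch(
      compare_models(by_tag, occ$butterfly_occ[, modelable, drop = FALSE]),
      error = function(e) fail("evaluate", e))
  }
  jsonlite::write_json(
    lapply(reports, function(r)
      list(tests = r$tests,
           median_auc = stats::aggregate(auc ~ tag, r$species_auc,
                                         stats::median))),
    eval_path, auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  record("evaluate", "done", eval_path)

  manifest$reports <- reports
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline manifest (seed", x$seed, ")\n")
  for (s in names(x$stages))
    cat(sprintf("  %-12s %s\n", s, x$stages[[s]]$status))
  invisible(x)
}
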