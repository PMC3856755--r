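test_that("simulated trees are ultrametric, depth-1, and seed-stable", {
  tr <- simulate_tree(3, seed = 1)
  expect_identical(length(tr$tip.label), 3L)
  expect_identical(tr$Nnode, 2L)
  d <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(max(d) - min(d), 0, tolerance = 1e-9)
  expect_equal(max(d), 1, tolerance = 1e-12)

  a <- ape::write.tree(simulate_tree(25, seed = 9))
  b <- ape::write.tree(simulate_tree(25, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(25, seed = 10))))
})

test_that("latent draws reproduce the generating covariance", {
  # lambda = 0 on a 2-tip tree: sample variance near sigma2
  two <- ape::read.tree(text = "(A:1,B:1);")
  draws <- vapply(1:2000, function(s)
    simulate_latents(two, lambda = 0, sigma2 = 2, seed = s),
    numeric(2))
  expect_equal(var(as.vector(draws)), 2, tolerance = 0.1 * 2)

  # lambda = 1 on the toy tree: corr(A, B) approx t_AB = 0.5
  tt <- toy_tree()
  ab <- vapply(1:2000, function(s)
    simulate_latents(tt, lambda = 1, sigma2 = 1, seed = 3000 + s)[c("A", "B")],
    numeric(2))
  expect_equal(cor(ab[1, ], ab[2, ]), 0.5, tolerance = 0.05)

  expect_identical(simulate_latents(tt, 0.5, 1, seed = 7),
                   simulate_latents(tt, 0.5, 1, seed = 7))
})

test_that("refitting generated latents recovers the target lambda", {
  errs <- vapply(1:8, function(r) {
    tree <- simulate_tree(120, seed = 400 + r)
    y <- simulate_latents(tree, lambda = 0.8, sigma2 = 1, seed = 500 + r)
    fit_lambda_regression(y, tree)$lambda - 0.8
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.2)
})

test_that("simulated webs are Bernoulli draws of the model probabilities", {
  set.seed(20)
  params <- random_params(4, 4)
  traits <- random_traits(4)
  p <- attr(simulate_web(params, traits, seed = 1), "p_true")
  expect_equal(unname(p),
               unname(predict_link_matrix(params, traits)),
               tolerance = 1e-14)

  # saturated probabilities give a full web
  sat <- link_params(50, 0, 0, c(0, 0), matrix(0, 3, 2), matrix(0, 3, 2))
  wsat <- simulate_web(sat, random_traits(3), seed = 2)
  expect_true(all(wsat$links == 1))

  # empirical frequency of one cell across 1000 seeded draws matches p
  freq <- mean(vapply(1:1000, function(s)
    simulate_web(params, traits, seed = s)$links[2, 3], integer(1)))
  expect_lt(abs(freq - p[2, 3]), 0.04)

  expect_identical(simulate_web(params, traits, seed = 5)$links,
                   simulate_web(params, traits, seed = 5)$links)
})

test_that("a full synthetic study is internally consistent and
           bit-reproducible", {
  cfg <- synthetic_config(n_plants = 12, n_butterflies = 10, n_sites = 80,
                          seed = 33)
  st <- make_study(cfg)
  st2 <- make_study(cfg)
  expect_identical(st[names(st) != "config"], st2[names(st2) != "config"])

  # truth round-trip: stored p equals the model evaluated on stored truth
  expect_equal(st$truth$p_matrix,
               predict_link_matrix(st$truth$params, st$truth$traits_std),
               tolerance = 1e-12)

  # generated pieces satisfy the consumers' invariants
  expect_s3_class(st$web, "trophic_web")
  expect_true(all(st$web$mask %in% 0:1))
  expect_identical(dim(st$web$links), dim(st$web$mask))
  expect_gte(st$masked_fraction, 0)
  expect_true(all(st$truth$p_matrix > 0 & st$truth$p_matrix < 1))
  expect_identical(rownames(st$web$links), st$plant_tree$tip.label)
  expect_identical(colnames(st$web$links), st$butterfly_tree$tip.label)
  expect_identical(rownames(st$occurrences$plant_occ),
                   rownames(st$occurrences$butterfly_occ))
  expect_equal(shared_time_matrix(st$plant_tree)["plant_01", "plant_01"], 1)
  # mask matches the co-occurrence definition
  expect_identical(st$web$mask,
                   compute_cooccurrence_mask(st$occurrences$plant_occ,
                                             st$occurrences$butterfly_occ))
})

test_that("without trophic coupling, butterfly presence is independent of
           the trophic term", {
  st <- make_study(synthetic_config(n_plants = 15, n_butterflies = 30,
                                    n_sites = 120, gamma = 0, seed = 71))
  pvals <- vapply(seq_len(30), function(j) {
    y <- st$occurrences$butterfly_occ[, j]
    tt <- st$truth$trophic_term[, j]
    if (length(unique(y)) < 2 || sd(tt) == 0) return(NA_real_)
    suppressWarnings(cor.test(tt, y, method = "spearman")$p.value)
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_gte(mean(pvals > 0.05), 0.8) # expected ~95% under the null
})

test_that("strong coupling with scarce hosts empties no-host sites", {
  # rare plants and low-prevalence specialist butterflies under strong
  # coupling: sites without a likely host should be nearly always empty
  st <- make_study(synthetic_config(n_plants = 10, n_butterflies = 20,
                                    n_sites = 120, gamma = 6,
                                    plant_prevalence = c(0.1, 0.3),
                                    butterfly_prevalence = c(0.1, 0.25),
                                    seed = 72))
  absent <- total <- 0
  for (j in seq_len(20)) {
    has_host <- vapply(seq_len(120), function(s) {
      present <- st$occurrences$plant_occ[s, ] == 1
      any(st$truth$p_matrix[present, j] > 0.5)
    }, logical(1))
    y <- st$occurrences$butterfly_occ[, j]
    absent <- absent + sum(y[!has_host] == 0)
    total <- total + sum(!has_host)
  }
  expect_gt(total, 0)
  expect_gte(absent / total, 0.9)
})

test_that("study files round-trip through the standard formats", {
  st <- make_study(synthetic_config(n_plants = 6, n_butterflies = 5,
                                    n_sites = 30, seed = 3))
  d <- withr::local_tempdir()
  paths <- write_study(st, d)
  expect_true(all(file.exists(paths)))
  web <- read_trophic_web(paths["web"], paths["mask"])
  expect_identical(web$links, st$web$links)
  expect_identical(web$mask, st$web$mask)
  tree <- ape::read.tree(paths["plant_tree"])
  expect_setequal(tree$tip.label, st$plant_tree$tip.label)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$alpha, st$truth$params$alpha)
})

test_that("config validation rejects degenerate settings", {
  expect_error(synthetic_config(n_plants = 2), ">= 3")
  expect_error(synthetic_config(gamma = -1), "gamma")
  expect_error(synthetic_config(lambda = 1.5), "lambda")
  expect_error(synthetic_config(delta = c(1, 2)), "delta")
})
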