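test_that("link probability reproduces closed-form logistic values", {
  zero <- link_params(0, 0, 0, c(0, 0), matrix(0, 1, 2), matrix(0, 1, 2))
  tr0 <- data.frame(nitrogen = 0, avg_height = 0)
  expect_equal(link_probability(zero, tr0, 1, 1), 0.5)

  a1 <- link_params(1, 0, 0, c(0, 0), matrix(0, 1, 2), matrix(0, 1, 2))
  expect_equal(link_probability(a1, tr0, 1, 1), 1 / (1 + exp(-1)),
               tolerance = 1e-12)

  # nitrogen slope at the scale reported for real webs, N = 2
  bn <- link_params(0, 0.145, 0, c(0, 0), matrix(0, 1, 2), matrix(0, 1, 2))
  tr2 <- data.frame(nitrogen = 2, avg_height = 0)
  expect_equal(link_probability(bn, tr2, 1, 1), plogis(0.29),
               tolerance = 1e-12)
  expect_equal(plogis(0.29), 0.57199, tolerance = 1e-4)
})

test_that("link probability faults on bad indices and non-finite traits", {
  p <- random_params(3, 4)
  tr <- random_traits(3)
  expect_error(link_probability(p, tr, 0, 1), "out of range")
  expect_error(link_probability(p, tr, 1, 5), "out of range")
  tr$nitrogen[2] <- NA
  expect_error(link_probability(p, tr, 2, 1), "non-finite")
})

test_that("log-likelihood matches brute-force cell summation on random webs", {
  set.seed(42)
  for (rep in 1:20) {
    P <- sample(2:6, 1); B <- sample(2:6, 1)
    web <- random_web(P, B)
    params <- random_params(P, B)
    traits <- random_traits(P)
    expect_equal(web_loglik(web, params, traits),
                 oracle_loglik(web, params, traits), tolerance = 1e-12)
  }
})

test_that("masked cells contribute exactly zero to the likelihood", {
  set.seed(7)
  web <- random_web(5, 5, p_mask = 0.5)
  params <- random_params(5, 5)
  traits <- random_traits(5)
  ll <- web_loglik(web, params, traits)
  masked <- which(web$mask == 0)
  expect_gt(length(masked), 0)
  flipped <- web$links
  flipped[masked] <- 1L - flipped[masked]
  web2 <- trophic_web(flipped, web$mask)
  expect_identical(web_loglik(web2, params, traits), ll)

  # all-masked web: empty product, log-likelihood 0
  web0 <- trophic_web(web$links, matrix(0L, 5, 5))
  expect_identical(web_loglik(web0, params, traits), 0)

  # single observed cell at p = 0.5
  w1 <- trophic_web(matrix(1L, 1, 1))
  z <- link_params(0, 0, 0, c(0, 0), matrix(0, 1, 2), matrix(0, 1, 2))
  expect_equal(web_loglik(w1, z, data.frame(nitrogen = 0, avg_height = 0)),
               log(0.5), tolerance = 1e-12)
})

test_that("likelihood stays finite at extreme finite parameters", {
  w <- trophic_web(matrix(c(1L, 0L), 1, 2))
  p <- link_params(500, 0, 0, c(0, 0), matrix(0, 1, 2), matrix(0, 2, 2))
  ll <- web_loglik(w, p, data.frame(nitrogen = 0, avg_height = 0))
  expect_true(is.finite(ll))
  expect_equal(ll, -500, tolerance = 1e-6) # miss on the a=0 cell
})

test_that("log posterior decomposes into likelihood plus priors and
           rejects delta-order violations", {
  set.seed(11)
  web <- random_web(4, 4)
  params <- random_params(4, 4)
  traits <- random_traits(4)
  priors <- list(sd_linear = 10, sd_delta = 10, sd_latent = 1)
  manual_prior <-
    sum(dnorm(c(params$alpha, params$beta_nitrogen, params$beta_height),
              0, 10, log = TRUE)) +
    sum(dnorm(params$delta, 0, 10, log = TRUE) + log(2)) +
    sum(dnorm(params$plant_latents, 0, 1, log = TRUE)) +
    sum(dnorm(params$butterfly_latents, 0, 1, log = TRUE))
  expect_equal(log_posterior(web, params, traits, priors),
               web_loglik(web, params, traits) + manual_prior,
               tolerance = 1e-12)

  # flat likelihood (all masked): posterior is the prior alone
  web0 <- trophic_web(web$links, matrix(0L, 4, 4))
  expect_equal(log_posterior(web0, params, traits, priors), manual_prior,
               tolerance = 1e-12)

  bad <- params
  bad$delta <- c(0.5, 2) # violates ordering; bypass constructor on purpose
  expect_identical(log_posterior(web, bad, traits, priors), -Inf)
})

test_that("sign flips of one latent dimension leave probabilities unchanged", {
  set.seed(3)
  params <- random_params(4, 5)
  traits <- random_traits(4)
  p0 <- predict_link_matrix(params, traits)
  for (d in 1:2) {
    flipped <- params
    flipped$plant_latents[, d] <- -flipped$plant_latents[, d]
    flipped$butterfly_latents[, d] <- -flipped$butterfly_latents[, d]
    expect_equal(predict_link_matrix(flipped, traits), p0,
                 tolerance = 1e-14)
  }
})

test_that("predict_link_matrix agrees with link_probability elementwise", {
  set.seed(9)
  params <- random_params(4, 6)
  traits <- random_traits(4)
  pm <- predict_link_matrix(params, traits)
  for (i in 1:4) for (j in 1:6)
    expect_equal(pm[i, j], link_probability(params, traits, i, j),
                 tolerance = 1e-14)
  # 1x1 zero problem
  z <- link_params(0, 0, 0, c(0, 0), matrix(0, 1, 2), matrix(0, 1, 2))
  expect_equal(unname(predict_link_matrix(
    z, data.frame(nitrogen = 0, avg_height = 0))), matrix(0.5, 1, 1))
  # monotonicity in nitrogen when beta1 > 0
  params$beta_nitrogen <- abs(params$beta_nitrogen)
  tr_hi <- traits; tr_hi$nitrogen[2] <- tr_hi$nitrogen[2] + 1
  expect_true(all(predict_link_matrix(params, tr_hi)[2, ] >= pm[2, ]))
})

test_that("predict_link_matrix names missing species", {
  params <- random_params(3, 3, plant_ids = c("pa", "pb", "pc"))
  expect_error(predict_link_matrix(params, random_traits(3),
                                   plant_ids = c("pa", "nope")),
               "nope")
})

test_that("co-occurrence mask enumerates shared sites", {
  sites <- c("s1", "s2", "s3")
  p <- matrix(c(1, 1, 0), 3, 1, dimnames = list(sites, "A"))
  b <- matrix(c(0, 1, 1,  0, 0, 1), 3, 2,
              dimnames = list(sites, c("X", "Y")))
  z <- compute_cooccurrence_mask(p, b)
  expect_identical(z["A", "X"], 1L)
  expect_identical(z["A", "Y"], 0L)

  # disjoint site usage -> all-zero; one shared full site -> all-one
  p2 <- matrix(c(1, 0), 2, 1); b2 <- matrix(c(0, 1), 2, 1)
  expect_true(all(compute_cooccurrence_mask(p2, b2) == 0))
  expect_true(all(compute_cooccurrence_mask(matrix(1, 1, 3),
                                            matrix(1, 1, 2)) == 1))
  expect_error(compute_cooccurrence_mask(matrix(1, 2, 1), matrix(1, 3, 1)),
               "site")
})

test_that("trophic_web validates shape and 0/1 entries", {
  expect_error(trophic_web(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
  expect_error(trophic_web(matrix(2, 2, 2)), "0/1")
  expect_error(trophic_web(matrix(0, 2, 2),
                           plant_ids = c("a", "a"),
                           butterfly_ids = c("x", "y")), "unique")
})

test_that("web CSV round-trips", {
  set.seed(5)
  web <- random_web(4, 3)
  d <- withr::local_tempdir()
  write_trophic_web(web, file.path(d, "w.csv"), file.path(d, "m.csv"))
  back <- read_trophic_web(file.path(d, "w.csv"), file.path(d, "m.csv"))
  expect_identical(back$links, web$links)
  expect_identical(back$mask, web$mask)
})
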