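test_that("shared-time matrix matches hand-computed fractions", {
  t_ij <- shared_time_matrix(toy_tree())
  expect_equal(t_ij["A", "B"], 0.5)
  expect_equal(t_ij["A", "C"], 0)
  expect_equal(t_ij["B", "C"], 0)
  expect_equal(diag(t_ij), c(A = 1, B = 1, C = 1))

  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1, 5)
  t_star <- shared_time_matrix(star)
  expect_true(all(t_star[upper.tri(t_star)] == 0))
  expect_equal(unname(diag(t_star)), rep(1, 5))
})

test_that("shared-time matrix equals normalized phylogenetic VCV on random
           trees and is symmetric with unit diagonal", {
  for (s in 1:10) {
    set.seed(s)
    tree <- ape::rcoal(sample(4:20, 1))
    t_ij <- shared_time_matrix(tree)
    expect_equal(t_ij, t(t_ij))
    expect_true(all(t_ij >= 0 & t_ij <= 1))
    v <- ape::vcv(tree)[rownames(t_ij), colnames(t_ij)]
    ref <- v / max(v)
    diag(ref) <- 1
    expect_equal(t_ij, ref, tolerance = 1e-10)
  }
})

test_that("shared-time matrix refuses bad trees", {
  set.seed(1)
  nonultra <- ape::rtree(8) # uniform branch lengths, not ultrametric
  expect_error(shared_time_matrix(nonultra), "not ultrametric")
  bad <- toy_tree()
  bad$edge.length[1] <- -0.5
  expect_error(shared_time_matrix(bad), "negative branch length")
})

test_that("lambda VCV interpolates between iid and Brownian structure", {
  t_ij <- shared_time_matrix(toy_tree())
  expect_equal(lambda_vcv(t_ij, 2, 0), diag(2, 3),
               ignore_attr = TRUE)
  c1 <- lambda_vcv(t_ij, 1, 1)
  expect_equal(unname(c1), unname(t_ij))
  c2 <- lambda_vcv(t_ij, 2, 0.5)
  expect_equal(c2["A", "B"], 0.5)
  expect_equal(unname(diag(c2)), rep(2, 3))
  expect_error(lambda_vcv(t_ij, 1, 1.2), "lambda")
  expect_error(lambda_vcv(t_ij, -1, 0.5), "sigma2")

  # positive definite for lambda in [0, 1) on random trees
  for (s in 1:20) {
    set.seed(100 + s)
    tree <- ape::rcoal(sample(4:50, 1))
    C <- lambda_vcv(shared_time_matrix(tree), 1.3, runif(1, 0, 0.999))
    expect_equal(C, t(C))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("profile likelihood at lambda = 0 equals the iid-normal MLE
           log-likelihood", {
  set.seed(21)
  tree <- ape::rcoal(15)
  y <- setNames(rnorm(15), tree$tip.label)
  fit <- fit_lambda_regression(y, tree)
  s2 <- mean((y - mean(y))^2)
  ll_iid <- sum(dnorm(y, mean(y), sqrt(s2), log = TRUE))
  expect_equal(fit$loglik0, ll_iid, tolerance = 1e-9)
})

test_that("profile fit agrees with a dense lambda grid and with an
           independent reference implementation", {
  for (s in 1:5) {
    set.seed(s)
    tree <- ape::rcoal(25)
    y <- simulate_latents(tree, lambda = runif(1), sigma2 = 1,
                          seed = 50 + s)
    # rcoal trees are ultrametric only to numerical precision of node ages
    fit <- fit_lambda_regression(y, tree)
    grid <- seq(0, 1, by = 1e-3)
    t_ij <- shared_time_matrix(tree)
    gl <- vapply(grid, function(l) {
      C <- lambda_vcv(t_ij, 1, l)
      R <- C / 1
      Ri <- solve(R)
      one <- rep(1, 25)
      mu <- sum(Ri %*% y[rownames(t_ij)]) / sum(Ri)
      r <- y[rownames(t_ij)] - mu
      s2 <- drop(t(r) %*% Ri %*% r) / 25
      -0.5 * (25 * log(2 * pi) + 25 * log(s2) +
                determinant(R)$modulus + 25)
    }, numeric(1))
    expect_lt(abs(fit$lambda - grid[which.max(gl)]), 1e-2)
  }

  skip_if_not_installed("phytools")
  set.seed(99)
  tree <- ape::rcoal(40)
  y <- simulate_latents(tree, lambda = 0.7, sigma2 = 2, seed = 123)
  fit <- fit_lambda_regression(y, tree)
  ref <- phytools::phylosig(tree, y, method = "lambda")
  expect_equal(fit$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(fit$loglik, ref$logL, tolerance = 1e-4)
})

test_that("boundary-mixture signal test follows the half chi-square", {
  f0 <- structure(list(loglik = -10, loglik0 = -10), class = "lambda_fit")
  expect_equal(unname(lambda_signal_test(f0)), c(0, 1))
  f6 <- structure(list(loglik = -7, loglik0 = -10), class = "lambda_fit")
  ts <- lambda_signal_test(f6)
  expect_equal(unname(ts["statistic"]), 6)
  expect_equal(unname(ts["p.value"]), 0.5 * pchisq(6, 1, lower.tail = FALSE))
  expect_equal(unname(ts["p.value"]), 0.00716, tolerance = 1e-3)
})

test_that("kriging imputation reproduces the 3-taxon worked example", {
  t_ij <- shared_time_matrix(toy_tree())
  fit <- structure(list(mu = 0, sigma2 = 1, lambda = 1),
                   class = "lambda_fit")
  pred <- impute_latent(fit, t_ij, c(A = 1.2, C = 3.0), "B")
  expect_equal(unname(pred), 0.6, tolerance = 1e-10)

  # lambda = 0: cross-covariance vanishes, prediction collapses to mu
  fit0 <- structure(list(mu = 1.5, sigma2 = 2, lambda = 0),
                    class = "lambda_fit")
  pred0 <- impute_latent(fit0, t_ij, c(A = 1.2, C = 3.0), "B")
  expect_equal(unname(pred0), 1.5, tolerance = 1e-12)

  # a target perfectly correlated with one observed tip inherits its value
  t1 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("obs", "tgt"),
                                                    c("obs", "tgt")))
  fit1 <- structure(list(mu = -2, sigma2 = 3, lambda = 1),
                    class = "lambda_fit")
  expect_equal(unname(impute_latent(fit1, t1, c(obs = 0.77), "tgt")), 0.77,
               tolerance = 1e-12)

  expect_error(impute_latent(fit, t_ij, c(A = 1), c("A", "B")), "disjoint")
  expect_error(impute_latent(fit, t_ij, c(A = 1), "Z"), "absent")
})

test_that("imputation is affine-equivariant under shifts of the data", {
  set.seed(33)
  tree <- ape::rcoal(30)
  y <- simulate_latents(tree, lambda = 0.8, sigma2 = 1, seed = 44)
  obs <- y[1:22]
  targets <- names(y)[23:30]
  t_ij <- shared_time_matrix(tree)
  f1 <- fit_lambda_regression(obs, tree)
  p1 <- impute_latent(f1, t_ij, obs, targets)
  f2 <- fit_lambda_regression(obs + 5, tree)
  p2 <- impute_latent(f2, t_ij, obs + 5, targets)
  expect_equal(p2, p1 + 5, tolerance = 1e-6)
})

test_that("impute_all_latents fills every species and recovers withheld
           truth on a lambda-structured simulation", {
  set.seed(8)
  n <- 150
  ptree <- simulate_tree(n, seed = 61, prefix = "p")
  btree <- simulate_tree(20, seed = 62, prefix = "b")
  truth <- cbind(dim1 = simulate_latents(ptree, 0.8, 1, seed = 63),
                 dim2 = simulate_latents(ptree, 0.8, 1, seed = 64))
  b_lat <- cbind(dim1 = simulate_latents(btree, 0.8, 1, seed = 65),
                 dim2 = simulate_latents(btree, 0.8, 1, seed = 66))
  withheld <- sample(rownames(truth), round(0.3 * n))
  known <- truth[setdiff(rownames(truth), withheld), ]

  out <- impute_all_latents(known, ptree, b_lat, btree)
  expect_setequal(rownames(out$plant_latents), ptree$tip.label)
  expect_false(anyNA(out$plant_latents))
  expect_identical(unname(out$provenance$plants[withheld]),
                   rep("imputed", length(withheld)))
  expect_identical(out$butterfly_latents, b_lat) # nothing to impute
  for (f in out$fits) {
    expect_gte(f$lambda, 0)
    expect_lte(f$lambda, 1)
  }
  r <- cor(out$plant_latents[withheld, 1], truth[withheld, 1])
  expect_gt(r, 0.5)
})

test_that("impute_all_latents faults on absent species and tiny fits", {
  ptree <- simulate_tree(5, seed = 1, prefix = "p")
  btree <- simulate_tree(5, seed = 2, prefix = "b")
  lat <- matrix(rnorm(10), 5, 2, dimnames = list(ptree$tip.label, NULL))
  blat <- matrix(rnorm(10), 5, 2, dimnames = list(btree$tip.label, NULL))
  expect_error(impute_all_latents(lat, ptree, blat, btree,
                                  plant_ids = c(ptree$tip.label, "ghost")),
               "ghost")
  expect_error(impute_all_latents(lat[1:2, ], ptree, blat, btree),
               ">= 3")
})
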