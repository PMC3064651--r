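test_that("phylogenetic covariance holds shared branch lengths", {
  V <- phylo_covariance(three_tip_tree())
  expect_equal(unname(diag(V)), rep(2, 3))
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["B", "C"], 0)

  Vs <- phylo_covariance(star_tree(6, depth = 3.5))
  expect_equal(unname(Vs), diag(3.5, 6))

  # ultrametric trees have a constant diagonal
  set.seed(5)
  tr <- simulate_tree(40, seed = 5)
  expect_equal(unname(diag(phylo_covariance(tr))), rep(1, 40),
               tolerance = 1e-9)
})

test_that("lambda scaling touches only the off-diagonal", {
  V <- phylo_covariance(three_tip_tree())
  expect_equal(scale_lambda(V, 1), V)
  expect_equal(scale_lambda(V, 0), diag(diag(V)), ignore_attr = TRUE)
  expect_equal(scale_lambda(V, 0.5)["A", "B"], 0.5)
  expect_equal(diag(scale_lambda(V, 0.5)), diag(V))
  expect_error(scale_lambda(V, 1.2), "\\[0, 1\\]")
  expect_error(scale_lambda(V, -0.1), "\\[0, 1\\]")
})

test_that("GLS reduces to OLS at V = identity and fits exact data exactly", {
  set.seed(31)
  n <- 12
  X <- cbind(1, stats::rnorm(n), stats::rnorm(n))
  y <- 2 + 0.5 * X[, 2] - 1.5 * X[, 3] + stats::rnorm(n)
  f <- gls_fit(y, X, diag(n))
  ols <- stats::lm.fit(X, y)
  expect_equal(unname(f$coefficients), unname(ols$coefficients),
               tolerance = 1e-10)
  # exact linear response: zero residuals under any covariance
  V <- phylo_covariance(simulate_tree(n, seed = 7))
  y_exact <- as.numeric(X %*% c(1, 2, 3))
  f2 <- gls_fit(y_exact, X, scale_lambda(V, 0.6))
  expect_equal(unname(f2$coefficients), c(1, 2, 3), tolerance = 1e-8)
  expect_lt(f2$rss, 1e-16)
  # collinear design is named
  Xs <- cbind(X, dup = X[, 2])
  colnames(Xs) <- c("(Intercept)", "a", "b", "dup")
  expect_error(gls_fit(y, Xs, diag(n)), "dup")
})

test_that("Cholesky GLS agrees with the explicit-inversion oracle to 1e-10", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- simulate_tree(8, seed = seed)
    V <- scale_lambda(phylo_covariance(tr), stats::runif(1))
    X <- cbind(1, stats::rnorm(8), stats::rnorm(8))
    y <- stats::rnorm(8)
    fast <- gls_fit(y, X, V)
    slow <- spermcomp:::gls_fit_bruteforce(y, X, V)
    expect_equal(unname(fast$coefficients), slow$coefficients,
                 tolerance = 1e-10)
    expect_equal(fast$rss, slow$rss, tolerance = 1e-10)
    expect_equal(fast$logLik, slow$logLik, tolerance = 1e-8)
  }
})

test_that("GLS coefficients match nlme::gls with a Pagel correlation at fixed lambda", {
  skip_if_not_installed("nlme")
  set.seed(88)
  tr <- simulate_tree(25, seed = 88)
  x <- as.numeric(simulate_bm_traits(tr, 1, 1, seed = 1))
  y <- 1 + 0.8 * x + as.numeric(simulate_bm_traits(tr, 1, 0.5, seed = 2))
  lam <- 0.7
  dat <- data.frame(y = y, x = x, species = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = dat,
                   correlation = ape::corPagel(lam, tr, form = ~species,
                                               fixed = TRUE),
                   method = "ML")
  mine <- gls_fit(y, cbind(1, x), scale_lambda(phylo_covariance(tr), lam))
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("profile likelihood at the lambda estimate dominates the boundaries", {
  for (seed in c(3, 14, 27)) {
    tr <- simulate_tree(30, seed = seed)
    y <- as.numeric(simulate_bm_traits(tr, 0.6, 1, seed = seed))
    X <- matrix(1, 30, 1)
    est <- estimate_lambda(y, X, phylo_covariance(tr))
    expect_gte(est$logLik, est$logLik0 - 1e-6)
    expect_gte(est$logLik, est$logLik1 - 1e-6)
    expect_true(est$lambda >= 0 && est$lambda <= 1)
  }
})

test_that("lambda estimation recovers strong and absent signal", {
  set.seed(99)
  tr <- simulate_tree(150, seed = 99)
  V <- phylo_covariance(tr)
  X <- matrix(1, 150, 1)
  lam1 <- replicate(15, {
    y <- as.numeric(simulate_bm_traits(tr, 1, 1))
    estimate_lambda(y, X, V)$lambda
  })
  expect_lt(abs(mean(lam1) - 1), 0.15)
  lam0 <- replicate(15, {
    y <- stats::rnorm(150)
    estimate_lambda(y, X, V)$lambda
  })
  expect_lt(abs(mean(lam0)), 0.15)
})

test_that("sequential SS matches a nested-refit oracle and sums to the total", {
  sim <- simulate_study(sim_config(n_species = 16, lambda_true = 0.4,
                                   seed = 21))
  fit <- pgls_regression(sim$table, sim$tree, "total_sperm",
                         c("body_mass", "testes_mass"))
  # oracle: refit nested models explicitly at the same lambda
  tab <- align_traits_tree(sim$table, sim$tree)$table
  W <- scale_lambda(phylo_covariance(sim$tree), fit$lambda)
  y <- log10(tab$total_sperm)
  X <- cbind(1, log10(tab$body_mass), log10(tab$testes_mass))
  rss0 <- spermcomp:::gls_fit_bruteforce(y, X[, 1, drop = FALSE], W)$rss
  rss1 <- spermcomp:::gls_fit_bruteforce(y, X[, 1:2], W)$rss
  rss2 <- spermcomp:::gls_fit_bruteforce(y, X, W)$rss
  ms <- rss2 / fit$df[2]
  expect_equal(unname(fit$F),
               c((rss0 - rss1) / ms, (rss1 - rss2) / ms),
               tolerance = 1e-8)
  # decomposition: sequential SS + residual SS = total SS (whitened scale)
  expect_equal(sum(fit$seq_ss) + fit$rss, fit$total_ss, tolerance = 1e-10)
})

test_that("orthogonal predictors give order-independent sequential F", {
  set.seed(4)
  n <- 20
  x1 <- stats::rnorm(n)
  x2 <- stats::residuals(stats::lm(stats::rnorm(n) ~ x1))  # orthogonal to x1 and 1
  x1 <- x1 - mean(x1)
  y <- 1 + x1 - 2 * x2 + stats::rnorm(n)
  df <- data.frame(species = paste0("sp", 1:n), n_males = 4,
                   body_mass = 10^x1, testes_mass = 10^x2,
                   total_sperm = 10^y, pct_normal = 50, pct_acrosome = 50,
                   pct_live = 50, pct_motile = 50)
  tab <- trait_table(df)
  tree <- star_tree(n)
  f_ab <- pgls_regression(tab, tree, "total_sperm",
                          c("body_mass", "testes_mass"), lambda = 0)
  f_ba <- pgls_regression(tab, tree, "total_sperm",
                          c("testes_mass", "body_mass"), lambda = 0)
  expect_equal(unname(f_ab$F["body_mass"]), unname(f_ba$F["body_mass"]),
               tolerance = 1e-8)
  expect_equal(unname(f_ab$F["testes_mass"]), unname(f_ba$F["testes_mass"]),
               tolerance = 1e-8)
})

test_that("PGLS at lambda 0 on an ultrametric tree reproduces OLS", {
  sim <- simulate_study(sim_config(n_species = 18, seed = 8))
  fit <- pgls_regression(sim$table, sim$tree, "total_sperm",
                         c("body_mass", "testes_mass"), lambda = 0)
  tab <- align_traits_tree(sim$table, sim$tree)$table
  ols <- stats::lm(log10(total_sperm) ~ log10(body_mass) +
                     log10(testes_mass), data = tab)
  a <- stats::anova(ols)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(unname(fit$F), a[1:2, "F value"], tolerance = 1e-8)
  expect_equal(fit$adj_r_squared, summary(ols)$adj.r.squared,
               tolerance = 1e-8)
})

test_that("reordering predictors changes sequential F but not the model fit", {
  sim <- simulate_study(sim_config(n_species = 20, lambda_true = 0.5,
                                   seed = 33))
  f_ab <- pgls_regression(sim$table, sim$tree, "total_sperm",
                          c("body_mass", "testes_mass"))
  f_ba <- pgls_regression(sim$table, sim$tree, "total_sperm",
                          c("testes_mass", "body_mass"))
  expect_equal(f_ab$lambda, f_ba$lambda, tolerance = 1e-5)
  expect_equal(f_ab$rss, f_ba$rss, tolerance = 1e-8)
  expect_equal(f_ab$adj_r_squared, f_ba$adj_r_squared, tolerance = 1e-8)
  expect_equal(sort(unname(f_ab$coefficients)),
               sort(unname(f_ba$coefficients)), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(unname(f_ab$F["testes_mass"]),
                                unname(f_ba$F["testes_mass"]))))
})

test_that("slopes are recovered on simulated data", {
  cfg <- sim_config(n_species = 40, lambda_true = 0, seed = 0)
  est <- vapply(1:40, function(s) {
    sim <- simulate_study(sim_config(n_species = 40, lambda_true = 0,
                                     seed = s))
    fit <- pgls_regression(sim$table, sim$tree, "total_sperm",
                           c("body_mass", "testes_mass"))
    unname(fit$coefficients["testes_mass"])
  }, numeric(1))
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - cfg$slope_testes), 2 * mc_se + 0.02)
})
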