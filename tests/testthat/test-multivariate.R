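test_that("correlation-matrix PCA conserves trace and known rank structure", {
  tab <- toy_table(12, seed = 1)
  pca <- pca_quality(tab)
  expect_equal(sum(pca$eigenvalues), 4, tolerance = 1e-10)
  expect_true(all(pca$eigenvalues >= -1e-12))
  expect_equal(pca$var_explained,
               pca$eigenvalues / 4 * 100, tolerance = 1e-12)

  # four mutually (nearly) uncorrelated traits: eigenvalues near 1
  set.seed(15)
  n <- 400
  df <- data.frame(species = paste0("sp", 1:n), n_males = 4,
                   body_mass = 10, testes_mass = 0.1, total_sperm = 10,
                   pct_normal = stats::runif(n, 1, 99),
                   pct_acrosome = stats::runif(n, 1, 99),
                   pct_live = stats::runif(n, 1, 99),
                   pct_motile = stats::runif(n, 1, 99))
  p2 <- pca_quality(trait_table(df))
  expect_true(all(abs(p2$eigenvalues - 1) < 0.25))
  expect_lt(abs(sum(p2$var_explained[1:2]) - 50), 8)

  # duplicated pairs of two orthogonal base traits: eigenvalues (2, 2, 0, 0)
  df3 <- as.data.frame(tab)
  df3$pct_live <- 60 +
    stats::residuals(stats::lm(df3$pct_live ~ df3$pct_normal))
  df3$pct_acrosome <- df3$pct_normal
  df3$pct_motile <- df3$pct_live
  p3 <- pca_quality(trait_table(df3))
  expect_equal(sort(p3$eigenvalues, decreasing = TRUE), c(2, 2, 0, 0),
               tolerance = 1e-6)

  df4 <- as.data.frame(tab)
  df4$pct_live <- 50
  expect_error(pca_quality(trait_table(df4)), "constant")
})

test_that("varimax preserves communalities and matches the angle-grid oracle", {
  set.seed(23)
  for (i in 1:5) {
    L <- matrix(stats::rnorm(12), 6, 2)
    rot <- varimax_rotate(L)
    # communalities unchanged to 1e-8
    expect_equal(rowSums(rot$loadings^2), rowSums(L^2), tolerance = 1e-8)
    # rotation is orthogonal
    expect_equal(t(rot$rotation) %*% rot$rotation, diag(2),
                 tolerance = 1e-10)
    # criterion does not decrease, and attains the brute-force optimum
    c_before <- varimax_criterion_test(L)
    c_after <- varimax_criterion_test(rot$loadings)
    expect_gte(c_after, c_before - 1e-12)
    expect_equal(c_after, varimax_bruteforce_2f(L), tolerance = 1e-4)
  }
  # perfect simple structure: rotation is the identity up to sign
  Ls <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.9), c(0, 0.7))
  rs <- varimax_rotate(Ls)
  expect_equal(abs(rs$loadings), abs(Ls), tolerance = 1e-6)
  # single factor passes through with a message
  expect_message(one <- varimax_rotate(matrix(c(0.9, 0.8), 2, 1)),
                 "single factor")
  expect_equal(one$loadings, matrix(c(0.9, 0.8), 2, 1))
})

test_that("overall quality scores are centred and the rules coincide for one dominant factor", {
  tab <- toy_table(15, seed = 2)
  pca <- pca_quality(tab)
  for (m in c("pc1", "rotated_f1", "eigen_weighted")) {
    s <- overall_quality_scores(pca, method = m)
    expect_equal(mean(s), 0, tolerance = 1e-10)
    expect_equal(length(s), 15L)
    expect_equal(attr(s, "method"), m)
  }
  expect_error(overall_quality_scores(pca, method = "nope"))

  # one dominant component: all rules proportional
  set.seed(30)
  base <- stats::runif(20, 30, 70)
  df <- data.frame(species = paste0("sp", 1:20), n_males = 4,
                   body_mass = 10, testes_mass = 0.1, total_sperm = 10,
                   pct_normal = base + stats::rnorm(20, 0, 0.02),
                   pct_acrosome = base + stats::rnorm(20, 0, 0.02),
                   pct_live = base + stats::rnorm(20, 0, 0.02),
                   pct_motile = base + stats::rnorm(20, 0, 0.02))
  pd <- pca_quality(trait_table(df))
  s1 <- overall_quality_scores(pd, "pc1")
  s2 <- overall_quality_scores(pd, "eigen_weighted")
  expect_gt(abs(stats::cor(s1, s2)), 0.995)
})

test_that("single-linkage clustering matches an exhaustive oracle", {
  set.seed(41)
  for (i in 1:5) {
    # random valid correlation matrix from random data
    Z <- matrix(stats::rnorm(40), 10, 4)
    R <- stats::cor(Z)
    dimnames(R) <- list(letters[1:4], letters[1:4])
    dend <- cluster_traits(R)
    oracle <- single_linkage_bruteforce(1 - R)
    expect_equal(dend$merges$height,
                 vapply(oracle, `[[`, numeric(1), "height"),
                 tolerance = 1e-10)
    expect_equal(strsplit(dend$merges$members[1], " \\+ ")[[1]],
                 oracle[[1]]$members)
    # single-linkage heights are non-decreasing
    expect_true(all(diff(dend$merges$height) >= -1e-12))
  }
})

test_that("clustering handles perfect correlation and permutation invariance", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 1
  R[1, 3] <- R[3, 1] <- 0.2
  R[2, 3] <- R[3, 2] <- 0.1
  dimnames(R) <- list(c("x", "y", "z"), c("x", "y", "z"))
  dend <- cluster_traits(R)
  expect_equal(dend$merges$height[1], 0)
  expect_equal(dend$merges$members[1], "x + y")

  perm <- c(3, 1, 2)
  dend2 <- cluster_traits(R[perm, perm])
  expect_equal(dend2$merges$height, dend$merges$height)
  expect_equal(dend2$merges$members, dend$merges$members)

  bad <- R
  bad[1, 2] <- 0.5
  expect_error(cluster_traits(bad), "symmetric")
  bad2 <- R
  diag(bad2) <- c(1, 1, 0.9)
  expect_error(cluster_traits(bad2), "unit diagonal")
})
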