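#' Configuration for the study simulator
#'
#' Bundles every knob of [simulate_study()] with defaults that emulate the
#' structure of the muroid study: 18 species, no phylogenetic signal in the
#' regression residuals (the fitted lambda on the real data is essentially
#' zero), allometric log-log dependence of testes mass on body mass, and a
#' sperm-number regression with slopes matching the fitted model (-0.60 on
#' log10 body mass, 1.16 on log10 testes mass).
#'
#' @param n_species Number of tips (>= 4).
#' @param birth_rate Speciation rate of the pure-birth tree (per unit
#'   time); the tree is rescaled to unit depth afterwards, so this only
#'   shapes relative node depths.
#' @param lambda_true Pagel's lambda of the residual structure, in
#'   \[0, 1\].
#' @param sigma2 Brownian-motion variance per unit branch length of the
#'   latent traits.
#' @param intercept,slope_body,slope_testes Regression structure of the
#'   response on log10 body mass and log10 testes mass.
#' @param resid_sd Residual SD of the response.
#' @param body_mean,body_sd Mean and BM-scale SD of log10 body mass (g).
#' @param allometry_a,allometry_b Allometry tying log10 testes mass to
#'   log10 body mass; species deviate from it by a lambda-structured
#'   deviation with SD `testes_dev_sd`.
#' @param testes_dev_sd SD of the allometric deviation in log10 testes
#'   mass (this deviation is what drives sperm competition differences).
#' @param quality_cor 4x4 positive semidefinite correlation target of the
#'   latent quality traits.
#' @param quality_sd Latent SD of quality traits (logit scale).
#' @param seed Integer seed; fully determines all outputs.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_species = 18L, birth_rate = 1, lambda_true = 0,
                       sigma2 = 1, intercept = 2.6, slope_body = -0.60,
                       slope_testes = 1.16, resid_sd = 0.25,
                       body_mean = 1.4, body_sd = 0.2,
                       allometry_a = 0.031, allometry_b = 0.77,
                       testes_dev_sd = 0.4,
                       quality_cor = NULL, quality_sd = 0.6,
                       seed = 1L) {
  if (n_species < 4L) stop("n_species must be >= 4", call. = FALSE)
  if (lambda_true < 0 || lambda_true > 1) {
    stop("lambda_true must lie in [0, 1]", call. = FALSE)
  }
  if (sigma2 < 0 || resid_sd < 0 || quality_sd < 0 || testes_dev_sd < 0) {
    stop("variances must be nonnegative", call. = FALSE)
  }
  if (is.null(quality_cor)) {
    # default correlation structure loosely matching the observed quality
    # traits: normal/acrosome/motile positively associated, live detached
    quality_cor <- matrix(c(1, 0.65, 0, 0.5,
                            0.65, 1, 0, 0.4,
                            0, 0, 1, 0.3,
                            0.5, 0.4, 0.3, 1), 4, 4)
  }
  quality_cor <- as.matrix(quality_cor)
  if (!isSymmetric(unname(quality_cor)) ||
      min(eigen(quality_cor, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("quality_cor must be symmetric positive semidefinite",
         call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species), birth_rate = birth_rate,
                 lambda_true = lambda_true, sigma2 = sigma2,
                 intercept = intercept, slope_body = slope_body,
                 slope_testes = slope_testes, resid_sd = resid_sd,
                 body_mean = body_mean, body_sd = body_sd,
                 allometry_a = allometry_a, allometry_b = allometry_b,
                 testes_dev_sd = testes_dev_sd, quality_cor = quality_cor,
                 quality_sd = quality_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree scaled to unit depth
#'
#' The simplest ultrametric null consistent with the lambda model; tree
#' shape is not a study variable, only the covariance structure it induces.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed (set for reproducibility).
#' @return An ultrametric [ape::phylo] tree with root-to-tip depth 1.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2L) stop("need at least 2 tips", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("sp", seq_len(n_species))
  tree
}

# draw k independent columns from N(0, sigma2 * V) via Cholesky
rmvn_chol <- function(k, V, sigma2 = 1) {
  n <- nrow(V)
  if (sigma2 == 0) return(matrix(0, n, k))
  C <- chol(sigma2 * V)
  Z <- matrix(stats::rnorm(n * k), n, k)
  t(C) %*% Z
}

#' Simulate lambda-structured Brownian traits on a tree
#'
#' Draws `k` independent traits from a zero-mean multivariate normal with
#' covariance sigma2 * V(lambda), the lambda-scaled Brownian-motion
#' covariance of the tree. This is the generative counterpart of the
#' lambda-model PGLS error structure.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param lambda_true Pagel's lambda in \[0, 1\].
#' @param sigma2 Variance per unit branch length (>= 0).
#' @param k Number of independent traits.
#' @param seed Optional integer seed.
#' @return Numeric matrix, tips x traits, rownames = tip labels.
#' @export
simulate_bm_traits <- function(tree, lambda_true = 1, sigma2 = 1, k = 1L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- scale_lambda(phylo_covariance(tree), lambda_true)
  X <- rmvn_chol(k, V, sigma2)
  rownames(X) <- tree$tip.label
  colnames(X) <- paste0("trait", seq_len(k))
  X
}

#' Simulate a full synthetic comparative study
#'
#' Generates, under one seed, a pure-birth tree and a species-mean trait
#' table with the statistical structure the analysis assumes: log10 body
#' mass is a Brownian trait; log10 testes mass follows the allometry plus a
#' lambda-structured deviation; log10 total sperm number follows the
#' configured regression on log10 body and testes mass with
#' lambda-structured residuals; and the four quality percentages arise from
#' correlated latent Gaussians (partly loaded on the testes-mass deviation)
#' squashed into (0, 100) by a logistic map. The logistic squashing keeps
#' percentages bounded without truncating the correlation structure; it is
#' a deliberate mismatch with the raw-percentage analysis scale, negligible
#' at the default parameter values.
#'
#' @param config A [sim_config()].
#' @return List with `table` (a [trait_table]), `tree`, and `truth` (the
#'   generating parameters, for recovery tests).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- simulate_tree(config$n_species, config$birth_rate)
  V <- scale_lambda(phylo_covariance(tree), config$lambda_true)
  n <- config$n_species

  lb <- config$body_mean + as.numeric(rmvn_chol(1, V, config$body_sd^2))
  dev <- as.numeric(rmvn_chol(1, V, config$testes_dev_sd^2))
  lt <- log10(config$allometry_a) + config$allometry_b * lb + dev
  eps <- as.numeric(rmvn_chol(1, V, config$resid_sd^2))
  ls <- config$intercept + config$slope_body * lb +
    config$slope_testes * lt + eps

  # latent quality: shared loading on the allometric deviation plus
  # lambda-structured correlated noise
  Zq <- rmvn_chol(4, V, 1)
  Cq <- chol(config$quality_cor)
  Q <- Zq %*% Cq * config$quality_sd
  load <- c(0.8, 0.6, 0.1, 0.7)   # live sperm nearly detached from RTM
  lat <- Q + outer(as.numeric(scale(dev)), load)
  pct <- 100 / (1 + exp(-(1.2 + lat)))

  df <- data.frame(species = tree$tip.label,
                   n_males = rep(5L, n),
                   body_mass = 10^lb,
                   testes_mass = 10^lt,
                   total_sperm = 10^ls,
                   pct_normal = pct[, 1],
                   pct_acrosome = pct[, 2],
                   pct_live = pct[, 3],
                   pct_motile = pct[, 4])
  list(table = trait_table(df),
       tree = tree,
       truth = list(lambda = config$lambda_true,
                    intercept = config$intercept,
                    slope_body = config$slope_body,
                    slope_testes = config$slope_testes,
                    resid_sd = config$resid_sd,
                    seed = config$seed))
}
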