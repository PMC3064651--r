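#' Phylogenetic variance-covariance matrix of a tree
#'
#' Under Brownian-motion trait evolution the expected covariance between two
#' tips is the branch length they share from the root to their most recent
#' common ancestor; the diagonal holds root-to-tip distances. Species order
#' follows the tree's tip order and is carried in the dimnames.
#'
#' @param tree An [ape::phylo] tree with nonnegative branch lengths.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  if (is.null(tree$edge.length)) {
    stop("phylogeny error: tree has no branch lengths; ",
         "use assign_branch_lengths() first", call. = FALSE)
  }
  ape::vcv.phylo(tree)
}

#' Pagel's lambda scaling of a phylogenetic covariance
#'
#' Multiplies the off-diagonal (shared-history) entries by lambda and leaves
#' the diagonal untouched. lambda = 1 is pure Brownian motion; lambda = 0
#' removes all phylogenetic covariance, leaving independent species with
#' variances proportional to their root-to-tip distances.
#'
#' @param V Phylogenetic covariance matrix, as from [phylo_covariance()].
#' @param lambda Scalar in \[0, 1\].
#' @return The lambda-scaled covariance matrix.
#' @export
scale_lambda <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a scalar in [0, 1]", call. = FALSE)
  }
  d <- diag(V)
  W <- V * lambda
  diag(W) <- d
  W
}

#' Generalized least squares with maximum-likelihood scale
#'
#' Fits y = X beta + e, e ~ N(0, sigma^2 V), by GLS. beta solves the normal
#' equations (X'V^-1 X)^-1 X'V^-1 y via a Cholesky whitening of V (no
#' explicit inversion); sigma^2 is profiled out by maximum likelihood
#' (RSS/n), and the multivariate-normal log-likelihood at the optimum is
#' returned.
#'
#' @param y Numeric response vector.
#' @param X Design matrix including the intercept column.
#' @param V Error covariance (up to scale), positive definite.
#' @return List with `coefficients`, `rss` (GLS-whitened residual sum of
#'   squares), `sigma2` (ML estimate), `logLik`, `fitted`, `residuals`
#'   (raw scale), and `n`.
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop("dimension mismatch between y, X and V", call. = FALSE)
  }
  if (n <= ncol(X)) {
    stop("need more observations than design columns", call. = FALSE)
  }
  C <- tryCatch(chol(V),
                error = function(e) stop("covariance matrix is not positive ",
                                         "definite", call. = FALSE))
  # whiten: solve t(C) %*% z = . ; then an ordinary least-squares problem
  Xw <- backsolve(C, X, transpose = TRUE)
  yw <- backsolve(C, y, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) {
    cols <- colnames(X)
    if (is.null(cols)) cols <- paste0("x", seq_len(ncol(X)))
    bad <- cols[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qrX, yw)
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(C)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  fitted <- as.numeric(X %*% beta)
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       rss = rss, sigma2 = sigma2, logLik = ll,
       fitted = fitted, residuals = y - fitted, n = n)
}

# reference implementation by explicit matrix inversion; used as a test
# oracle only, never on the analysis path
gls_fit_bruteforce <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) +
                  as.numeric(determinant(V)$modulus) + n)
  list(coefficients = as.numeric(beta), rss = rss, sigma2 = sigma2,
       logLik = ll)
}

#' Maximum-likelihood estimation of Pagel's lambda
#'
#' Profiles the GLS log-likelihood of the model y = X beta + e,
#' e ~ N(0, sigma^2 * V(lambda)), over lambda in \[0, 1\]. The search
#' evaluates a deterministic start grid {0, 0.25, 0.5, 0.75, 1} and runs a
#' bounded golden-section/parabolic search ([stats::optimize()], tolerance
#' 1e-6) in the bracket around the best grid point, guarding against local
#' optima. Likelihood-ratio tests against the fixed models lambda = 0 and
#' lambda = 1 use chi-squared(1) on twice the log-likelihood difference;
#' when the estimate sits on a boundary of the parameter space the p-value
#' is halved (50:50 mixture of chi-squared(0) and chi-squared(1)).
#'
#' @param y Response vector.
#' @param X Design matrix with intercept.
#' @param V Unscaled phylogenetic covariance (lambda = 1).
#' @param tol Optimizer tolerance.
#' @return List with `lambda`, `logLik` (at the estimate), `logLik0`,
#'   `logLik1`, `p_vs_0`, `p_vs_1`, and the fitted model `fit` at the
#'   estimate.
#' @export
estimate_lambda <- function(y, X, V, tol = 1e-6) {
  prof <- function(l) gls_fit(y, X, scale_lambda(V, l))$logLik
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  gll <- vapply(grid, prof, numeric(1))
  if (any(!is.finite(gll))) {
    stop("non-finite likelihood in lambda profile", call. = FALSE)
  }
  best <- which.max(gll)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(prof, lower = lo, upper = hi, maximum = TRUE,
                         tol = tol)
  cand_l <- c(opt$maximum, grid)
  cand_ll <- c(opt$objective, gll)
  k <- which.max(cand_ll)
  lambda <- cand_l[k]
  ll <- cand_ll[k]
  ll0 <- gll[1L]
  ll1 <- gll[length(grid)]
  at_boundary <- lambda < tol || lambda > 1 - tol
  lrt_p <- function(ll_restricted) {
    stat <- max(0, 2 * (ll - ll_restricted))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    if (at_boundary) p <- p / 2
    p
  }
  list(lambda = lambda, logLik = ll, logLik0 = ll0, logLik1 = ll1,
       p_vs_0 = lrt_p(ll0), p_vs_1 = lrt_p(ll1),
       fit = gls_fit(y, X, scale_lambda(V, lambda)))
}

#' Phylogenetic regression with sequential (Type I) sums of squares
#'
#' Fits a lambda-model PGLS of one trait on an ordered set of predictor
#' traits. Transformation tags recorded on the trait table are applied
#' first; lambda is estimated by maximum likelihood on the full model (or
#' fixed via `lambda`); each predictor's sequential F is the increment in
#' explained (GLS-whitened) sum of squares when it is added after the
#' predictors before it, divided by the full-model residual mean square,
#' on (1, n - p - 1) degrees of freedom. Predictor order is therefore
#' meaningful: entering body mass before testes mass credits the shared
#' allometric variance to body mass, so the testes-mass F measures sperm
#' competition's effect beyond body size.
#'
#' @param table A [trait_table].
#' @param tree An [ape::phylo] tree with branch lengths, tips matching the
#'   table (aligned via [align_traits_tree()] if needed).
#' @param response Trait name of the response, or a numeric vector of
#'   length `nrow(table)` (e.g. a composite score), in which case
#'   `response_name` labels it.
#' @param predictors Character vector of predictor trait names, in entry
#'   order.
#' @param lambda `"ML"` (default) or a fixed scalar in \[0, 1\].
#' @param response_name Label used when `response` is a numeric vector.
#' @return An object of class `pgls_fit`: coefficients, sequential `F`,
#'   `p.value`, `df` (1, residual df), `lambda`, log-likelihoods and
#'   boundary-aware LRT p-values against lambda = 0 and 1, `adj_r_squared`,
#'   and the underlying `fit`.
#' @export
pgls_regression <- function(table, tree, response, predictors,
                            lambda = "ML", response_name = "response") {
  stopifnot(inherits(table, "trait_table"))
  al <- align_traits_tree(table, tree)
  table <- al$table
  tree <- al$tree
  tags <- transform_tags(table)
  if (is.character(response)) {
    stopifnot(length(response) == 1L, response %in% trait_names())
    y <- apply_transform(table[[response]], tags[[response]])
    response_name <- response
  } else {
    y <- as.numeric(response)
    if (length(y) != nrow(table)) {
      stop("numeric response must have one value per species", call. = FALSE)
    }
  }
  stopifnot(all(predictors %in% trait_names()))
  X <- cbind(`(Intercept)` = 1,
             sapply(predictors, function(p)
               apply_transform(table[[p]], tags[[p]])))
  colnames(X) <- c("(Intercept)", predictors)
  V <- phylo_covariance(tree)
  n <- length(y)
  p <- length(predictors)
  df_res <- n - p - 1L

  if (identical(lambda, "ML")) {
    est <- estimate_lambda(y, X, V)
  } else {
    f <- gls_fit(y, X, scale_lambda(V, lambda))
    est <- list(lambda = lambda, logLik = f$logLik, logLik0 = NA_real_,
                logLik1 = NA_real_, p_vs_0 = NA_real_, p_vs_1 = NA_real_,
                fit = f)
  }
  W <- scale_lambda(V, est$lambda)

  # nested refits at the estimated lambda give the Type I decomposition
  rss <- numeric(p + 1L)
  rss[1L] <- gls_fit(y, X[, 1L, drop = FALSE], W)$rss
  for (k in seq_len(p)) {
    rss[k + 1L] <- gls_fit(y, X[, seq_len(k + 1L), drop = FALSE], W)$rss
  }
  rss_full <- rss[p + 1L]
  ms_full <- rss_full / df_res
  seq_ss <- rss[seq_len(p)] - rss[seq_len(p) + 1L]
  Fstat <- seq_ss / ms_full
  pval <- stats::pf(Fstat, 1, df_res, lower.tail = FALSE)

  tss <- rss[1L]
  r2 <- 1 - rss_full / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res

  structure(list(
    response = response_name,
    predictors = predictors,
    coefficients = est$fit$coefficients,
    seq_ss = stats::setNames(seq_ss, predictors),
    F = stats::setNames(Fstat, predictors),
    p.value = stats::setNames(pval, predictors),
    df = c(1L, df_res),
    lambda = est$lambda,
    logLik = est$logLik,
    logLik0 = est$logLik0,
    logLik1 = est$logLik1,
    lambda_p_vs_0 = est$p_vs_0,
    lambda_p_vs_1 = est$p_vs_1,
    r_squared = r2,
    adj_r_squared = adj_r2,
    rss = rss_full,
    total_ss = tss,
    n = n,
    fit = est$fit
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (lambda model):", x$response, "~",
      paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("lambda = %.4g (logLik %.3f; vs lambda=0 p=%.3g, vs lambda=1 p=%.3g)\n",
              x$lambda, x$logLik, x$lambda_p_vs_0, x$lambda_p_vs_1))
  tab <- data.frame(slope = x$coefficients[x$predictors],
                    F = x$F, p = x$p.value, row.names = x$predictors)
  print(round(tab, digits))
  cat(sprintf("Residual df = %d, adjusted R^2 = %.3f\n", x$df[2L],
              x$adj_r_squared))
  invisible(x)
}
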