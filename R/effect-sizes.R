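#' Effect size r from an F statistic
#'
#' Converts an F statistic on (1, df) degrees of freedom to the
#' correlation-scale effect size r = sqrt(F / (F + df)).
#'
#' @param F Nonnegative F statistic (numerator df 1).
#' @param df Residual degrees of freedom, >= 1.
#' @return Effect size in \[0, 1).
#' @export
effect_size_from_f <- function(F, df) {
  if (any(F < 0)) stop("F statistic must be nonnegative", call. = FALSE)
  if (any(df < 1)) stop("residual df must be >= 1", call. = FALSE)
  sqrt(F / (F + df))
}

#' Confidence limits for an effect size r
#'
#' The default method is the Fisher-z interval: atanh(r) +/- z * SE with
#' SE = 1 / sqrt(df - 3), reported on the transformed (z) scale, where the
#' interval is symmetric and may exceed 1 in magnitude; an interval
#' excluding 0 indicates significance. The alternative `"noncentral_f"`
#' method inverts the noncentral F distribution for the noncentrality delta
#' with pf(F; 1, df, delta) equal to the tail probabilities, maps each
#' bound to r through the partial eta-squared relation
#' r^2 = delta / (delta + df + 2), and reports on the r scale.
#'
#' @param r Effect size, |r| < 1.
#' @param df Residual degrees of freedom (> 3 for the default method).
#' @param level Coverage, default 0.95.
#' @param method `"fisher_z"` (default) or `"noncentral_f"`.
#' @return List with `lower`, `upper`, `scale` (`"z"` or `"r"`) and
#'   `method`.
#' @export
effect_confidence_limits <- function(r, df, level = 0.95,
                                     method = c("fisher_z", "noncentral_f")) {
  method <- match.arg(method)
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (method == "fisher_z") {
    if (df <= 3) stop("Fisher-z limits need df > 3", call. = FALSE)
    z <- atanh(r)
    half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(df - 3)
    return(list(lower = z - half, upper = z + half, scale = "z",
                method = method))
  }
  Fobs <- r^2 * df / (1 - r^2)
  alpha <- (1 - level) / 2
  ncp_bound <- function(target) {
    # delta with P(F(1, df, delta) <= Fobs) = target; 0 if unattainable
    f <- function(d) stats::pf(Fobs, 1, df, ncp = d) - target
    if (f(0) <= 0) return(0)
    hi <- max(4 * (Fobs + 1), 16)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-9)$root
  }
  d_up <- ncp_bound(alpha)        # larger delta -> smaller tail prob
  d_lo <- ncp_bound(1 - alpha)
  to_r <- function(d) sign(r) * sqrt(d / (d + df + 2))
  lims <- sort(c(to_r(d_lo), to_r(d_up)))
  list(lower = lims[1L], upper = lims[2L], scale = "r", method = method)
}

#' Phylogenetically corrected correlation between two traits
#'
#' Fits a single-predictor lambda-model PGLS between two (transformed)
#' traits and converts the predictor's F statistic to a signed effect size
#' r (sign of the GLS slope) on n - 2 residual df. The result is symmetric
#' in the two traits: lambda is estimated once by maximizing the pooled
#' profile log-likelihood, the sum of the two regression directions'
#' profiles, so a-on-b and b-on-a yield the same r and p.
#'
#' @param table A [trait_table].
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param trait_a,trait_b Trait names.
#' @param alpha Significance level for the `significant` flag.
#' @return List with `r`, `p.value`, `F`, `df`, `lambda`, `significant`.
#' @export
phylo_correlation <- function(table, tree, trait_a, trait_b, alpha = 0.05) {
  stopifnot(inherits(table, "trait_table"))
  al <- align_traits_tree(table, tree)
  table <- al$table
  tree <- al$tree
  tags <- transform_tags(table)
  xa <- apply_transform(table[[trait_a]], tags[[trait_a]])
  xb <- apply_transform(table[[trait_b]], tags[[trait_b]])
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    stop("correlation undefined for a constant trait", call. = FALSE)
  }
  n <- nrow(table)
  if (identical(trait_a, trait_b)) {
    return(list(r = 1, p.value = 0, F = Inf, df = n - 2L, lambda = NA_real_,
                significant = TRUE))
  }
  V <- phylo_covariance(tree)
  Xa <- cbind(1, xa)
  Xb <- cbind(1, xb)
  pooled <- function(l) {
    W <- scale_lambda(V, l)
    gls_fit(xb, Xa, W)$logLik + gls_fit(xa, Xb, W)$logLik
  }
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  gll <- vapply(grid, pooled, numeric(1))
  best <- which.max(gll)
  opt <- stats::optimize(pooled, lower = grid[max(1L, best - 1L)],
                         upper = grid[min(5L, best + 1L)], maximum = TRUE,
                         tol = 1e-6)
  lambda <- if (opt$objective > max(gll)) opt$maximum else grid[best]
  W <- scale_lambda(V, lambda)
  full <- gls_fit(xb, Xa, W)
  null <- gls_fit(xb, cbind(rep(1, n)), W)
  df_res <- n - 2L
  Fstat <- (null$rss - full$rss) / (full$rss / df_res)
  r <- sign(full$coefficients[2L]) * effect_size_from_f(Fstat, df_res)
  p <- stats::pf(Fstat, 1, df_res, lower.tail = FALSE)
  list(r = unname(r), p.value = p, F = Fstat, df = df_res, lambda = lambda,
       significant = p < alpha)
}

#' Pairwise phylogenetically corrected correlation matrix
#'
#' Assembles [phylo_correlation()] over all trait pairs. Symmetry holds by
#' construction (the pooled-likelihood lambda convention makes the two
#' regression directions identical) and is asserted.
#'
#' @param table A [trait_table].
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param traits Character vector of at least 2 trait names.
#' @param alpha Significance level.
#' @return Object of class `phylo_cor`: matrices `r`, `p.value`,
#'   `significant`, `lambda` plus `alpha`.
#' @export
correlation_matrix <- function(table, tree, traits, alpha = 0.05) {
  k <- length(traits)
  if (k < 2L) stop("need at least 2 traits", call. = FALSE)
  R <- diag(k)
  P <- matrix(0, k, k)
  L <- matrix(NA_real_, k, k)
  dimnames(R) <- dimnames(P) <- dimnames(L) <- list(traits, traits)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ab <- phylo_correlation(table, tree, traits[i], traits[j], alpha)
      ba <- phylo_correlation(table, tree, traits[j], traits[i], alpha)
      stopifnot(abs(ab$r - ba$r) < 1e-8)
      R[i, j] <- R[j, i] <- ab$r
      P[i, j] <- P[j, i] <- ab$p.value
      L[i, j] <- L[j, i] <- ab$lambda
    }
  }
  structure(list(r = R, p.value = P, significant = P < alpha & R != diag(k),
                 lambda = L, alpha = alpha),
            class = "phylo_cor")
}

#' @export
print.phylo_cor <- function(x, digits = 3, ...) {
  cat("Phylogenetically corrected correlation matrix (alpha =", x$alpha,
      ")\n")
  print(round(x$r, digits))
  cat("significant pairs marked TRUE:\n")
  sig <- x$significant
  diag(sig) <- NA
  print(sig)
  invisible(x)
}
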