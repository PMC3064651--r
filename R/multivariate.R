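#' Principal-component composite of ejaculate quality
#'
#' Reduces the (potentially correlated) quality percentages to a small
#' number of "quality components": the traits are standardized to zero mean
#' and unit variance, the correlation matrix is eigendecomposed, the first
#' `n_factors` components are retained as loadings (eigenvector times
#' sqrt(eigenvalue)), and a varimax rotation is applied for
#' interpretability. Each unrotated component is oriented so its
#' largest-magnitude loading is positive, making results reproducible
#' across eigen-solvers.
#'
#' @param table A [trait_table].
#' @param traits Quality trait names, default [quality_trait_names()].
#'   Traits enter untransformed regardless of the table's tags unless
#'   `use_transforms = TRUE`.
#' @param n_factors Number of components retained (default 2).
#' @param use_transforms Apply the table's transformation tags first.
#' @return Object of class `quality_pca`: `eigenvalues` (all),
#'   `var_explained` (percent per component, eigenvalue / #traits * 100),
#'   `loadings` (unrotated, retained), `rotated` (varimax), `rotation`
#'   matrix, `scores` (unrotated component scores, all species),
#'   `rotated_scores`, `traits`, `species`.
#' @export
pca_quality <- function(table, traits = quality_trait_names(),
                        n_factors = 2L, use_transforms = FALSE) {
  stopifnot(inherits(table, "trait_table"), length(traits) >= 2L)
  Z <- sapply(traits, function(tr) {
    v <- table[[tr]]
    if (use_transforms) v <- apply_transform(v, transform_tags(table)[[tr]])
    v
  })
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ", paste(traits[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(Z)
  R <- stats::cor(Z)
  e <- eigen(R, symmetric = TRUE)
  k <- min(n_factors, length(traits))
  # orient: largest-|loading| entry of each retained eigenvector positive
  Vk <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(Vk[, j]))
    if (Vk[m, j] < 0) Vk[, j] <- -Vk[, j]
  }
  L <- Vk %*% diag(sqrt(e$values[seq_len(k)]), k)
  dimnames(L) <- list(traits, paste0("factor", seq_len(k)))
  rot <- varimax_rotate(L)
  dimnames(rot$loadings) <- dimnames(L)
  scores <- Z %*% Vk
  colnames(scores) <- paste0("factor", seq_len(k))
  # rotated scores: standardized scores times the rotation
  scores_std <- scores %*% diag(1 / sqrt(e$values[seq_len(k)]), k)
  rotated_scores <- scores_std %*% rot$rotation
  colnames(rotated_scores) <- colnames(scores)
  structure(list(
    eigenvalues = e$values,
    var_explained = e$values / length(traits) * 100,
    loadings = L,
    rotated = rot$loadings,
    rotation = rot$rotation,
    scores = scores,
    rotated_scores = rotated_scores,
    traits = traits,
    species = table$species
  ), class = "quality_pca")
}

#' @export
print.quality_pca <- function(x, digits = 3, ...) {
  k <- ncol(x$loadings)
  cat("Quality-trait PCA on the correlation matrix\n")
  cat("eigenvalues:", round(x$eigenvalues, digits), "\n")
  cat(sprintf("top %d components explain %.1f%% of variance\n", k,
              sum(x$var_explained[seq_len(k)])))
  cat("varimax-rotated loadings:\n")
  print(round(x$rotated, digits))
  invisible(x)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the raw varimax criterion (variance of
#' squared loadings per factor), via [stats::varimax()] without Kaiser
#' normalization, so the optimum is directly comparable to an exhaustive
#' search over rotation angles. Row communalities (sums of squared
#' loadings) are preserved. A single-factor matrix is returned unchanged
#' with a message.
#'
#' @param loadings Trait-by-factor numeric matrix.
#' @return List with `loadings` (rotated) and `rotation` (orthogonal
#'   matrix; identity for a single factor).
#' @export
varimax_rotate <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 2L) {
    message("varimax: single factor, rotation is the identity")
    return(list(loadings = loadings, rotation = diag(1)))
  }
  v <- stats::varimax(loadings, normalize = FALSE)
  list(loadings = loadings %*% v$rotmat, rotation = v$rotmat)
}

# varimax objective: sum over factors of the variance of squared loadings
varimax_criterion <- function(L) {
  sq <- L^2
  sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
}

#' Scalar overall-quality score per species
#'
#' Collapses the retained quality components to a single "overall sperm
#' quality" value per species. The default rule is the unrotated first
#' principal-component score; alternatives are the varimax-rotated
#' factor-1 score and an eigenvalue-weighted sum of the retained rotated
#' scores. All rules produce zero-mean scores; the rule used is recorded
#' in the `"method"` attribute.
#'
#' @param composite A [pca_quality()] result.
#' @param method `"pc1"`, `"rotated_f1"` or `"eigen_weighted"`.
#' @return Named numeric vector of per-species scores.
#' @export
overall_quality_scores <- function(composite,
                                   method = c("pc1", "rotated_f1",
                                              "eigen_weighted")) {
  stopifnot(inherits(composite, "quality_pca"))
  method <- match.arg(method)
  k <- ncol(composite$scores)
  s <- switch(method,
    pc1 = composite$scores[, 1L],
    rotated_f1 = composite$rotated_scores[, 1L],
    eigen_weighted = {
      w <- composite$eigenvalues[seq_len(k)]
      as.numeric(composite$rotated_scores %*% (w / sum(w)))
    })
  s <- s - mean(s)
  names(s) <- composite$species
  attr(s, "method") <- method
  s
}

#' Single-linkage clustering of traits on a correlation distance
#'
#' Agglomerative single-linkage clustering of traits with distance
#' d = 1 - r, the complement of the (phylogenetically corrected)
#' correlation. Strongly associated traits merge first; single linkage
#' joins clusters at the minimum pairwise distance, so merge heights are
#' non-decreasing.
#'
#' @param r_matrix Symmetric correlation matrix with unit diagonal, or a
#'   `phylo_cor` object from [correlation_matrix()].
#' @return Object of class `trait_dendrogram`: the underlying
#'   [stats::hclust] object plus a `merges` data frame (height and member
#'   labels of each merge).
#' @export
cluster_traits <- function(r_matrix) {
  if (inherits(r_matrix, "phylo_cor")) r_matrix <- r_matrix$r
  r_matrix <- as.matrix(r_matrix)
  if (!isSymmetric(unname(r_matrix), tol = 1e-8)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(r_matrix) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  d <- stats::as.dist(1 - r_matrix)
  hc <- stats::hclust(d, method = "single")
  labs <- rownames(r_matrix)
  member_labels <- function(idx) {
    # hclust merge convention: negative = leaf, positive = earlier merge
    unlist(lapply(idx, function(i) {
      if (i < 0) labs[-i] else member_labels(hc$merge[i, ])
    }))
  }
  merges <- data.frame(
    step = seq_len(nrow(hc$merge)),
    height = hc$height,
    members = vapply(seq_len(nrow(hc$merge)), function(i)
      paste(sort(member_labels(hc$merge[i, ])), collapse = " + "),
      character(1))
  )
  structure(list(hclust = hc, merges = merges, labels = labs),
            class = "trait_dendrogram")
}

#' @export
print.trait_dendrogram <- function(x, digits = 3, ...) {
  cat("Single-linkage clustering of traits, distance = 1 - r\n")
  m <- x$merges
  m$height <- round(m$height, digits)
  print(m, row.names = FALSE)
  invisible(x)
}
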