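# shared fixtures and independent oracles, built in code

three_tip_tree <- function() {
  read_newick(text = "((A:1,B:1):1,C:2);")
}

star_tree <- function(n = 8, depth = 1) {
  tree <- ape::stree(n, type = "star")
  tree$edge.length <- rep(depth, nrow(tree$edge))
  tree$tip.label <- paste0("sp", seq_len(n))
  tree
}

# a small valid trait table built from scratch
toy_table <- function(n = 6, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    species = paste0("sp", seq_len(n)),
    n_males = sample(3:8, n, replace = TRUE),
    body_mass = exp(stats::rnorm(n, 3, 0.5)),
    testes_mass = exp(stats::rnorm(n, -1.5, 0.8)),
    total_sperm = exp(stats::rnorm(n, 3.5, 1)),
    pct_normal = stats::runif(n, 60, 95),
    pct_acrosome = stats::runif(n, 50, 99),
    pct_live = stats::runif(n, 50, 99),
    pct_motile = stats::runif(n, 40, 99)
  )
  trait_table(df)
}

# exhaustive single-linkage agglomeration, independent of hclust
single_linkage_bruteforce <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- min(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <-
      list(members = merged, height = best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# varimax via exhaustive search over the rotation angle (2 factors only)
varimax_bruteforce_2f <- function(L, n_grid = 20000) {
  angles <- seq(0, pi / 2, length.out = n_grid)
  crit <- function(theta) {
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    varimax_criterion_test(L %*% R)
  }
  vals <- vapply(angles, crit, numeric(1))
  max(vals)
}

varimax_criterion_test <- function(L) {
  sq <- L^2
  sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
}
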