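#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] adding the validation the pipeline
#' relies on: a single rooted tree, unique tip labels, and nonnegative branch
#' lengths where present. Trees without branch lengths are accepted as-is;
#' lengths are assigned later by [assign_branch_lengths()].
#'
#' @param path Path to a newick file, or a literal newick string via `text`.
#' @param text Optional newick string (ignores `path`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) {
      stop("file not found: ", path, call. = FALSE)
    }
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  # locate unbalanced parentheses before handing to the parser, so the
  # error can carry a character position
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("newick parse error: unbalanced ')' at position ", i,
           call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("newick parse error: no tree could be read", call. = FALSE)
  }
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L) {
    stop("phylogeny error: duplicate tip label(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("phylogeny error: negative branch length", call. = FALSE)
  }
  tree
}

#' Write a phylogeny to a newick file
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Assign branch lengths to a topology
#'
#' Comparative analyses need branch lengths, but published supplementary
#' trees often give topology only. The default rule is Grafen's method
#' (each node's height is its number of descendant tips minus one, rescaled
#' so every root-to-tip path has length 1), which yields an ultrametric
#' tree; `"unit"` sets every edge to length 1; `"keep"` requires lengths to
#' be present already.
#'
#' @param tree An [ape::phylo] tree, with or without branch lengths.
#' @param rule One of `"grafen"`, `"unit"`, `"keep"`.
#' @return The tree with branch lengths set.
#' @export
assign_branch_lengths <- function(tree, rule = c("grafen", "unit", "keep")) {
  rule <- match.arg(rule)
  validate_phylogeny(tree)
  if (rule == "keep") {
    if (is.null(tree$edge.length)) {
      stop("phylogeny error: tree has no branch lengths and rule is 'keep'",
           call. = FALSE)
    }
    return(tree)
  }
  if (rule == "unit") {
    tree$edge.length <- rep(1, nrow(tree$edge))
    return(tree)
  }
  ape::compute.brlen(tree, method = "Grafen", power = 1)
}

#' The fixture phylogeny of the 18 muroid species
#'
#' A consensus topology of the 18 fixture species assembled from standard
#' muroid taxonomy (vole clade: Clethrionomys, Arvicola, Chionomys,
#' Microtus with the Terricola species as sisters; mouse clade: Apodemus
#' sister to Mus, subgenus Coelomys basal within Mus, and the four
#' M. musculus subspecies as a clade). It is a synthetic stand-in for the
#' unpublished study tree: topology only, no inferred branch lengths, and
#' is installed as `muroid_tree_synthetic.nwk`. Because the fitted
#' phylogenetic signal on this dataset is essentially zero, downstream
#' results are insensitive to the branch-length rule.
#'
#' @param branch_lengths Branch-length rule passed to
#'   [assign_branch_lengths()]; `"none"` returns the bare topology.
#' @return An [ape::phylo] tree with 18 tips.
#' @export
muroid_tree <- function(branch_lengths = c("grafen", "unit", "none")) {
  branch_lengths <- match.arg(branch_lengths)
  path <- system.file("extdata", "muroid_tree_synthetic.nwk",
                      package = "spermcomp", mustWork = TRUE)
  tree <- read_newick(path)
  if (branch_lengths == "none") return(tree)
  assign_branch_lengths(tree, rule = branch_lengths)
}

#' Align a trait table and a phylogeny on their common species
#'
#' Restricts both objects to the species present in each (name matching is
#' exact after trimming whitespace and unifying underscores and spaces) and
#' puts them in one canonical order, the pruned tree's tip order. Species
#' found in only one input are dropped with a warning naming them.
#'
#' @param table A [trait_table].
#' @param tree An [ape::phylo] tree.
#' @return A list with elements `table` and `tree`.
#' @export
align_traits_tree <- function(table, tree) {
  stopifnot(inherits(table, "trait_table"))
  validate_phylogeny(tree)
  tip_norm <- normalize_species(tree$tip.label)
  common <- intersect(table$species, tip_norm)
  if (length(common) == 0L) {
    stop("no species shared between trait table and phylogeny", call. = FALSE)
  }
  drop_tab <- setdiff(table$species, common)
  drop_tree <- setdiff(tip_norm, common)
  if (length(drop_tab) > 0L || length(drop_tree) > 0L) {
    warning("dropping unmatched species: ",
            paste(c(drop_tab, drop_tree), collapse = ", "), call. = FALSE)
  }
  keep_tips <- tree$tip.label[tip_norm %in% common]
  tree2 <- ape::keep.tip(tree, keep_tips)
  order_norm <- normalize_species(tree2$tip.label)
  tab2 <- table[match(order_norm, table$species), , drop = FALSE]
  rownames(tab2) <- NULL
  attr(tab2, "transforms") <- attr(table, "transforms")
  class(tab2) <- class(table)
  if (length(common) < 3L) {
    stop("fewer than 3 species remain after alignment", call. = FALSE)
  }
  list(table = tab2, tree = tree2)
}
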