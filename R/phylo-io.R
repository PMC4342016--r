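#' Phylogeny input and patristic distances
#'
#' Trees are `ape::phylo` objects throughout. Readers reject trees with
#' missing branch lengths instead of silently zeroing them, because every
#' downstream dissimilarity is a sum of branch lengths.
#'
#' @name phylo_io
NULL

validate_phylogeny <- function(tree, what = "tree") {
  if (!inherits(tree, "phylo")) abort(paste0(what, " is not a phylo object."))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("Duplicate tip labels in ", what, ": ",
                 paste(dup, collapse = ", ")))
  }
  nb <- nrow(tree$edge)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nb ||
      anyNA(tree$edge.length)) {
    abort(paste0("Missing branch lengths in ", what,
                 "; trees without complete branch lengths are rejected."))
  }
  if (any(tree$edge.length < 0)) {
    abort(paste0("Negative branch lengths in ", what, "."))
  }
  invisible(tree)
}

# best-effort character offset of a Newick syntax problem
newick_error_offset <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  nchar(text)
}

#' Read a single Newick tree from a string
#'
#' @param text Newick string (must end in `;`), with branch lengths on every
#'   edge. Quoted labels and scientific-notation lengths are accepted.
#' @return a `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2):0;")
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort(paste0("Newick parse failure near character ",
                 newick_error_offset(text), "."))
  }
  validate_phylogeny(tree)
}

#' Read a set of trees (a posterior sample)
#'
#' Accepts a file or a character vector: one Newick tree per line, or a Nexus
#' file with a trees block. All trees are pruned to their common tip set; a
#' warning is raised when tip sets are heterogeneous.
#'
#' @param source path to a file, or a character vector of Newick strings.
#' @param max_trees keep at most this many trees (from the start).
#' @return object of class `tree_posterior`: list with elements `trees`
#'   (a `multiPhylo`) and `tips` (the shared, sorted tip set).
#' @export
read_tree_set <- function(source, max_trees = Inf) {
  trees <- NULL
  if (is.character(source) && length(source) == 1 && file.exists(source)) {
    head_txt <- readLines(source, n = 1L, warn = FALSE)
    if (grepl("^\\s*#NEXUS", head_txt, ignore.case = TRUE)) {
      trees <- ape::read.nexus(source)
    } else {
      source <- readLines(source, warn = FALSE)
    }
  }
  if (is.null(trees)) {
    if (!is.character(source)) abort("`source` must be a path or character vector.")
    lines <- source[nzchar(trimws(source))]
    if (length(lines) == 0) abort("No trees in input.")
    trees <- lapply(lines, read_newick)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) abort("No trees in input.")
  if (is.finite(max_trees)) trees <- trees[seq_len(min(max_trees, length(trees)))]
  trees <- lapply(seq_along(trees), function(i) {
    validate_phylogeny(trees[[i]], paste0("tree ", i))
  })
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  common <- Reduce(intersect, tipsets)
  if (length(common) < 2) abort("Trees share fewer than two tip labels.")
  if (!all(vapply(tipsets, identical, logical(1), y = sort(common)))) {
    warn("Heterogeneous tip sets; pruning all trees to the common tip set.")
    trees <- lapply(trees, prune_to_taxa, taxa = common)
  }
  structure(
    list(trees = structure(trees, class = "multiPhylo"), tips = sort(common)),
    class = "tree_posterior"
  )
}

#' @export
print.tree_posterior <- function(x, ...) {
  cat("Tree posterior:", length(x$trees), "trees,",
      length(x$tips), "shared tips\n")
  invisible(x)
}

#' Prune a tree to a taxon subset
#'
#' Retains exactly `taxa`; degree-2 nodes are collapsed with branch lengths
#' summed, so patristic distances among retained tips are unchanged.
#'
#' @param tree `phylo`.
#' @param taxa character vector, subset of the tip labels, length >= 2.
#' @return pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- as.character(taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Taxa not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(taxa) < 2) abort("Need at least two taxa after pruning.")
  ape::keep.tip(tree, taxa)
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths on the unique path between each pair of tips; the
#' d_ij used by the phylogenetic facet of Rao diversity.
#'
#' @param tree `phylo` with >= 2 tips and complete branch lengths.
#' @return labelled distance matrix (lexicographic label order).
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2) abort("Tree has fewer than two tips.")
  as_distance_matrix(ape::cophenetic.phylo(tree))
}

#' Posterior-mean patristic distance matrix
#'
#' Element-wise arithmetic mean of the per-tree patristic matrices, the
#' summary used as "the" phylogeny for downstream analyses.
#'
#' @param posterior a `tree_posterior`, `multiPhylo`, or list of `phylo`.
#' @return labelled distance matrix.
#' @export
mean_distance_matrix <- function(posterior) {
  trees <- if (inherits(posterior, "tree_posterior")) posterior$trees
           else posterior
  trees <- unclass(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) abort("Empty posterior.")
  tips <- sort(trees[[1]]$tip.label)
  mats <- lapply(seq_along(trees), function(i) {
    t <- trees[[i]]
    if (!identical(sort(t$tip.label), tips)) {
      abort("Trees do not share a common tip set; prune first.")
    }
    patristic_distances(t)[tips, tips]
  })
  as_distance_matrix(Reduce(`+`, mats) / length(mats))
}
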