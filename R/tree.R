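# Phylogenetic tree I/O and validation, thin wrappers over ape. The tree's
# tips are OTU ids; branch lengths are substitutions/site and must be
# non-negative.

#' Read and validate a rooted Newick tree
#'
#' @param path Newick file.
#' @param otu_ids optional OTU id set; an error lists any ids missing from
#'   the tree's tips.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path, otu_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  validate_tree(tree, otu_ids = otu_ids)
  tree
}

#' Validate a phylogenetic tree against the package's invariants
#'
#' Checks tip-label uniqueness, non-negative branch lengths, rootedness, and
#' (optionally) coverage of a supplied OTU id set.
#'
#' @param tree an `ape::phylo`.
#' @param otu_ids optional ids that must all be tips.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree, otu_ids = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is.null(otu_ids)) {
    missing <- setdiff(otu_ids, tree$tip.label)
    if (length(missing) > 0) {
      stop("OTUs absent from tree tips: ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (and %d more)",
                                             length(missing) - 10) else "")
    }
  }
  invisible(tree)
}

#' Write a tree to a Newick file
#'
#' @param tree an `ape::phylo`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Edge index used by UniFrac and Faith's PD: for every edge, the set of tips
# descending from it, as a tips x edges logical incidence matrix. Computed
# once per tree and reused across samples.
tree_edge_index <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  ne <- nrow(tr$edge)
  desc <- matrix(FALSE, ntip, ne)
  child <- tr$edge[, 2]
  parent <- tr$edge[, 1]
  for (e in seq_len(ne)) {
    ch <- child[e]
    if (ch <= ntip) {
      desc[ch, e] <- TRUE
    } else {
      below <- which(parent == ch)  # already processed: postorder
      desc[, e] <- rowSums(desc[, below, drop = FALSE]) > 0
    }
  }
  list(length = tr$edge.length, desc = desc, tips = tr$tip.label)
}

# sample x edge matrix of per-edge tip mass (counts, presence, or relative
# abundance) for a table whose OTUs are all tips of the indexed tree
edge_mass <- function(m, idx) {
  pos <- match(colnames(m), idx$tips)
  if (anyNA(pos)) {
    stop("OTUs absent from tree tips: ",
         paste(utils::head(colnames(m)[is.na(pos)], 10), collapse = ", "))
  }
  tipm <- matrix(0, nrow(m), length(idx$tips),
                 dimnames = list(rownames(m), idx$tips))
  tipm[, pos] <- m
  tipm %*% idx$desc
}
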