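# Phylogenies with stable branch identifiers and foreground marks.
#
# Internally a tree is an ape "phylo" object canonicalized to an unrooted,
# post-order edge ordering; a branch id is simply the row index of the edge
# in that ordering. Foreground branches (those assigned to the selected
# omega class in branch-site analyses) are carried as a set of branch ids,
# serialized in Newick as a "#k" suffix on the subtending node label.

#' Construct a PhyloTree
#'
#' Canonicalizes an `ape::phylo` object (unroots a rooted binary root,
#' reorders edges post-order) and attaches foreground branch marks. Branch
#' ids are row indices of `$phylo$edge` in post-order, so they are stable
#' for a given topology regardless of input rotation.
#'
#' @param phy an `ape::phylo` object (branch lengths optional).
#' @param foreground integer vector of branch ids marked as foreground.
#' @param mark_class integer vector parallel to `foreground` giving the
#'   omega-class index `k` of each mark (default all 1).
#' @return An object of class `PhyloTree`.
#' @export
phylo_tree <- function(phy, foreground = integer(0), mark_class = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2L)
    phy <- ape::unroot(phy)
  phy <- ape::reorder.phylo(phy, "postorder")
  if (!is.null(phy$edge.length)) phy$edge.length <- pmax(phy$edge.length, 0)
  foreground <- sort(unique(as.integer(foreground)))
  if (is.null(mark_class)) mark_class <- rep(1L, length(foreground))
  if (length(foreground) && any(foreground < 1L | foreground > nrow(phy$edge)))
    stop("foreground branch id out of range")
  structure(list(phylo = phy, foreground = foreground,
                 mark_class = as.integer(mark_class)),
            class = "PhyloTree")
}

#' @export
print.PhyloTree <- function(x, ...) {
  cat("PhyloTree:", length(x$phylo$tip.label), "tips,", n_branches(x),
      "branches")
  if (length(x$foreground))
    cat("; foreground:", paste(x$foreground, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Number of branches of a tree
#' @param tree a `PhyloTree`.
#' @export
n_branches <- function(tree) nrow(tree$phylo$edge)

#' Tip labels of a tree
#' @param tree a `PhyloTree`.
#' @export
tree_taxa <- function(tree) tree$phylo$tip.label

#' Branch lengths indexed by branch id
#' @param tree a `PhyloTree`.
#' @export
branch_lengths <- function(tree) {
  bl <- tree$phylo$edge.length
  if (is.null(bl)) rep(NA_real_, n_branches(tree)) else bl
}

# tips subtended by each branch: list of character vectors, index = branch id
.branch_leafsets <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  for (b in seq_len(nrow(phy$edge))) {   # postorder: children first
    p <- phy$edge[b, 1L]; ch <- phy$edge[b, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(phy$edge)), function(b) sort(below[[phy$edge[b, 2L]]]))
}

#' Describe branches by the leaf set they subtend
#'
#' Reports print branch ids next to the subtended tips, since numbering
#' conventions differ between programs.
#'
#' @param tree a `PhyloTree`.
#' @return data.frame with columns `branch`, `length`, `tips`.
#' @export
branch_table <- function(tree) {
  ls <- .branch_leafsets(tree)
  data.frame(branch = seq_len(n_branches(tree)),
             length = branch_lengths(tree),
             tips = vapply(ls, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}

#' Find the branch subtending (or separating off) a set of taxa
#'
#' Returns the branch id whose bipartition separates `taxa` from the rest of
#' the tree, or `NA` if no branch induces that split.
#'
#' @param tree a `PhyloTree`.
#' @param taxa character vector of tip labels.
#' @export
stem_branch <- function(tree, taxa) {
  taxa <- sort(taxa)
  all_tips <- sort(tree_taxa(tree))
  comp <- setdiff(all_tips, taxa)
  ls <- .branch_leafsets(tree)
  for (b in seq_along(ls)) {
    if (identical(ls[[b]], taxa) || identical(ls[[b]], comp)) return(b)
  }
  NA_integer_
}

#' Mark foreground branches
#'
#' @param tree a `PhyloTree`.
#' @param branches integer branch ids, or `NULL` to use `taxa`.
#' @param taxa if given, the branch separating this taxon set is marked.
#' @param k omega-class index written as the `#k` Newick suffix.
#' @return The tree with its foreground set replaced.
#' @export
mark_foreground <- function(tree, branches = NULL, taxa = NULL, k = 1L) {
  if (is.null(branches)) {
    if (is.null(taxa)) stop("give branches or taxa")
    branches <- stem_branch(tree, taxa)
    if (is.na(branches)) stop("no branch separates {",
                              paste(taxa, collapse = ","), "}")
  }
  phylo_tree(tree$phylo, foreground = branches,
             mark_class = rep(as.integer(k), length(branches)))
}

#' Read a Newick tree with optional #k foreground marks
#'
#' A `#k` suffix on a tip or internal node label marks the branch subtending
#' that node as foreground omega class `k`, e.g. `"(A,(B,C)#1);"`.
#'
#' @param path file path, or `NULL` when `text` is given.
#' @param text Newick string.
#' @return A [phylo_tree()].
#' @export
read_newick <- function(path = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(phy)) stop("parse error: not a Newick tree")
  mark_re <- "#([0-9]+)$"
  marked_sets <- list(); marked_k <- integer(0)
  ntip <- length(phy$tip.label)
  # tips: the "clade" is the tip itself
  hit_tip <- grepl(mark_re, phy$tip.label)
  for (w in which(hit_tip)) {
    marked_sets[[length(marked_sets) + 1L]] <-
      sub(mark_re, "", phy$tip.label[w])
    marked_k[length(marked_k) + 1L] <-
      as.integer(sub(paste0(".*", mark_re), "\\1", phy$tip.label[w]))
  }
  phy$tip.label <- sub(mark_re, "", phy$tip.label)
  if (!is.null(phy$node.label)) {
    hit_nd <- grepl(mark_re, phy$node.label)
    for (w in which(hit_nd)) {
      nd <- ntip + w
      tips <- if (nd == ntip + 1L) phy$tip.label else
        ape::extract.clade(phy, nd)$tip.label
      marked_sets[[length(marked_sets) + 1L]] <- sort(tips)
      marked_k[length(marked_k) + 1L] <-
        as.integer(sub(paste0(".*", mark_re), "\\1", phy$node.label[w]))
    }
    phy$node.label <- sub(mark_re, "", phy$node.label)
    if (all(phy$node.label == "")) phy$node.label <- NULL
  }
  tree <- phylo_tree(phy)
  fg <- integer(0); kk <- integer(0)
  for (i in seq_along(marked_sets)) {
    b <- stem_branch(tree, marked_sets[[i]])
    if (is.na(b))
      stop("parse error: marked clade {",
           paste(marked_sets[[i]], collapse = ","),
           "} is not a branch of the unrooted tree")
    fg <- c(fg, b); kk <- c(kk, marked_k[i])
  }
  o <- order(fg)
  phylo_tree(tree$phylo, foreground = fg[o], mark_class = kk[o])
}

#' Write a tree to Newick, serializing foreground marks as #k suffixes
#'
#' @param tree a `PhyloTree`.
#' @param path output file, or `NULL` to return the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
  for (i in seq_along(tree$foreground)) {
    b <- tree$foreground[i]
    k <- tree$mark_class[i]
    child <- phy$edge[b, 2L]
    if (child <= ntip) {
      phy$tip.label[child] <- paste0(phy$tip.label[child], "#", k)
    } else {
      phy$node.label[child - ntip] <-
        paste0(phy$node.label[child - ntip], "#", k)
    }
  }
  if (all(phy$node.label == "")) phy$node.label <- NULL
  txt <- .newick_string(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

# full-precision Newick serializer (ape's writer rounds to 10 digits,
# which breaks the 1e-10 round-trip contract on branch lengths)
.newick_string <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  fmt_len <- function(b)
    if (is.null(phy$edge.length)) "" else
      paste0(":", format(phy$edge.length[b], digits = 15, trim = TRUE,
                         scientific = FALSE))
  node_str <- function(nd, edge_in) {
    lab <- if (nd <= ntip) phy$tip.label[nd] else
      if (!is.null(phy$node.label)) phy$node.label[nd - ntip] else ""
    below <- kids[[as.character(nd)]]
    core <- if (is.null(below)) lab else
      paste0("(", paste(vapply(below, function(b)
        node_str(phy$edge[b, 2L], b), ""), collapse = ","), ")", lab)
    paste0(core, if (!is.na(edge_in)) fmt_len(edge_in) else "")
  }
  paste0(node_str(ntip + 1L, NA_integer_), ";")
}

#' Neighbor-joining guide tree from a codon alignment
#'
#' Builds pairwise nucleotide distances over the gap-free alignment
#' (p-distance by default, or Jukes-Cantor corrected) and applies the
#' canonical NJ agglomeration. Negative branch lengths are clamped to zero.
#' Distances are per nucleotide site; downstream model fitting re-estimates
#' branch lengths in substitutions per codon, so the NJ lengths act only as
#' topology and starting values.
#'
#' @param aln a gap-free `CodonAlignment` (run [complete_deletion()] first).
#' @param distance `"p"` (default) or `"JC"`.
#' @return A [phylo_tree()].
#' @export
neighbor_joining <- function(aln, distance = c("p", "JC")) {
  distance <- match.arg(distance)
  if (length(aln$taxa) < 3L) stop("neighbor joining needs at least 3 taxa")
  nuc <- do.call(cbind, lapply(seq_len(ncol(aln$codons)), function(j)
    do.call(rbind, strsplit(aln$codons[, j], ""))))
  n <- nrow(nuc)
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(nuc[i, ] != nuc[j, ])
    if (distance == "JC") {
      arg <- 1 - 4 * p / 3
      if (arg <= 0) stop("distance error: saturated pair ",
                         aln$taxa[i], "/", aln$taxa[j])
      p <- -0.75 * log(arg)
    }
    d[i, j] <- d[j, i] <- p
  }
  phy <- ape::nj(stats::as.dist(d))
  phy$edge.length <- pmax(phy$edge.length, 0)
  phylo_tree(phy)
}
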