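# Tree comparison: Newick I/O, bipartition extraction, Robinson-Foulds.

#' Parse and write Newick trees
#'
#' Thin wrappers over ape's Newick reader/writer adding the error contracts
#' this package relies on: a malformed string or duplicate leaf labels are
#' an error, not a silent `NULL`.
#'
#' @param text A Newick string (or a file path for `read_tree_file`).
#' @param tree A `phylo` object.
#' @return `parse_newick` returns a `phylo`; `write_newick` returns a
#'   Newick string.
#' @examples
#' write_newick(parse_newick("((A,B),(C,D));"))
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Nontrivial bipartitions of a tree
#'
#' Extracts the split induced by each internal edge of the unrooted form of
#' the tree. Each split is canonicalized as the side not containing the
#' lexicographically first taxon, so a split and its complement get the
#' same representation; rooting is ignored. Trivial splits (a single taxon,
#' or all of them) are dropped.
#'
#' @param tree A `phylo` tree.
#' @return Character vector of canonical split keys (taxon labels sorted
#'   and joined with `|`); empty for stars and 3-taxon trees.
#' @export
bipartitions <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  topo <- tree_postorder(tree)
  labels <- topo$tip.label
  n <- length(labels)
  ref <- sort(labels)[1]
  nnode <- topo$nnode
  below <- vector("list", nnode)
  for (i in seq_len(n)) below[[i]] <- labels[i]
  splits <- character(0)
  for (e in seq_len(nrow(topo$edge))) {
    par <- topo$edge[e, 1]; ch <- topo$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labels, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the bipartitions present in exactly one of the two trees (the
#' symmetric difference of their split sets). Branch lengths, supports and
#' rooting are ignored; only the unrooted topology matters.
#'
#' @param t1,t2 `phylo` trees on the same leaf label set.
#' @return Non-negative integer RF distance.
#' @examples
#' rf_distance(parse_newick("((A,B),C,(D,E));"),
#'             parse_newick("((A,C),B,(D,E));"))
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different taxa: ",
         paste(symdiff_chr(t1$tip.label, t2$tip.label), collapse = ", "))
  s1 <- bipartitions(t1)
  s2 <- bipartitions(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Normalized Robinson-Foulds distance
#'
#' Divides the RF distance by its maximum possible value,
#' `|splits(t1)| + |splits(t2)|`; for two fully resolved unrooted trees on
#' n taxa this is `2(n-3)`. Identical topologies score 0 and
#' split-disjoint ones 1. When both trees are stars the distance is
#' defined as 0 (with a warning).
#'
#' @inheritParams rf_distance
#' @return Numeric in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different taxa: ",
         paste(symdiff_chr(t1$tip.label, t2$tip.label), collapse = ", "))
  s1 <- bipartitions(t1)
  s2 <- bipartitions(t2)
  denom <- length(s1) + length(s2)
  if (denom == 0) {
    warning("both trees are stars; nRF defined as 0")
    return(0)
  }
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / denom
}

#' Compare two trees and print RF / nRF
#'
#' @param t1,t2 `phylo` objects or paths to Newick files.
#' @param quiet If `TRUE`, do not print.
#' @return List with `rf` and `nrf`, invisibly.
#' @export
compare_trees <- function(t1, t2, quiet = FALSE) {
  if (is.character(t1)) t1 <- parse_newick(paste(readLines(t1), collapse = ""))
  if (is.character(t2)) t2 <- parse_newick(paste(readLines(t2), collapse = ""))
  rf <- rf_distance(t1, t2)
  nrf <- suppressWarnings(normalized_rf(t1, t2))
  if (!quiet) cat(sprintf("RF %d nRF %.4f\n", rf, nrf))
  invisible(list(rf = rf, nrf = nrf))
}
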