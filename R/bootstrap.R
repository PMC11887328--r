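# Nonparametric bootstrap over matrix rows and majority-rule consensus.

#' Bootstrap replicate trees
#'
#' Standard nonparametric bootstrap: each replicate resamples the matrix
#' rows (sites) with replacement, refits the model and re-runs the NNI
#' search from the replicate's own neighbor-joining start tree.
#'
#' @param x 0/1 matrix, columns = taxa.
#' @param B Number of replicates (>= 1).
#' @param seed Seed for the row resampling (replicate b uses draws from a
#'   single seeded stream, so different seeds give different index
#'   multisets).
#' @param ncat,tol Passed to [binml()].
#' @return List of `B` `phylo` trees.
#' @export
bootstrap_trees <- function(x, B, seed = 42, ncat = 4, tol = 1e-6) {
  stopifnot(B >= 1)
  n <- nrow(x)
  idx <- with_seed(seed, lapply(seq_len(B), function(b)
    sample.int(n, n, replace = TRUE)))
  lapply(idx, function(ii) {
    xb <- x[ii, , drop = FALSE]
    binml(xb, ncat = ncat, tol = tol)$tree
  })
}

#' Majority-rule consensus and bootstrap supports
#'
#' Counts each nontrivial split's frequency across the replicate trees.
#' Returns (a) the strict majority-rule consensus — only splits present in
#' more than 50% of the replicates, annotated with their percentage — and
#' (b) if `besttree` is given, that tree annotated with each internal
#' edge's replicate frequency as node labels.
#'
#' @param trees List of `phylo` trees on the same taxon set.
#' @param besttree Optional `phylo` tree (e.g. the full-data ML tree) to
#'   annotate with support values.
#' @return List with `consensus` (phylo with `node.label` supports),
#'   `annotated` (the support-labelled `besttree`, or `NULL`) and
#'   `split_freq` (named numeric, percent per observed split).
#' @export
majority_consensus <- function(trees, besttree = NULL) {
  stopifnot(length(trees) >= 1)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, taxa))
      stop("trees are not all on the same taxon set")
  B <- length(trees)
  all_splits <- unlist(lapply(trees, bipartitions))
  freq <- 100 * table(all_splits) / B
  split_freq <- stats::setNames(as.numeric(freq), names(freq))

  maj <- names(split_freq)[split_freq > 50]
  cons <- consensus_from_splits(maj, taxa,
                                round(split_freq[maj]))
  annotated <- NULL
  if (!is.null(besttree)) {
    if (!setequal(besttree$tip.label, taxa))
      stop("besttree is not on the same taxon set")
    annotated <- annotate_supports(besttree, split_freq)
  }
  list(consensus = cons, annotated = annotated, split_freq = split_freq)
}

# Build a (possibly multifurcating) tree from a compatible split set.
# Splits are canonical keys from bipartitions(): the side not containing
# the reference (first sorted) taxon, so each is a clade when the tree is
# rooted next to that taxon. Majority splits are pairwise compatible, so
# the clades nest.
consensus_from_splits <- function(splits, taxa, supports = NULL) {
  clades <- lapply(strsplit(splits, "|", fixed = TRUE), sort)
  sizes <- lengths(clades)
  ord <- order(-sizes)
  clades <- clades[ord]
  labs <- if (is.null(supports)) rep(NA, length(clades)) else supports[ord]
  # parent of each clade = smallest strictly-containing clade (or root)
  nC <- length(clades)
  parent <- rep(0L, nC)
  if (nC > 1) {
    # clades sorted large -> small, so the smallest strictly-containing
    # clade is the containing one with the largest earlier index
    for (i in 2:nC) {
      for (j in (i - 1):1) {
        if (all(clades[[i]] %in% clades[[j]])) { parent[i] <- j; break }
      }
    }
  }
  leaf_parent <- rep(0L, length(taxa))
  names(leaf_parent) <- taxa
  for (i in seq_len(nC))
    for (leaf in clades[[i]])
      leaf_parent[leaf] <- i  # deepest clade wins: clades sorted big->small
  emit <- function(node) {
    kid_clades <- which(parent == node)
    if (node == 0L) kid_leaves <- names(leaf_parent)[leaf_parent == 0L]
    else kid_leaves <- clades[[node]][leaf_parent[clades[[node]]] == node]
    parts <- c(kid_leaves, vapply(kid_clades, emit, ""))
    inner <- paste(parts, collapse = ",")
    if (node == 0L) paste0("(", inner, ");")
    else if (is.na(labs[node])) paste0("(", inner, ")")
    else paste0("(", inner, ")", labs[node])
  }
  ape::read.tree(text = emit(0L))
}

# Label each internal edge of `tree` with its split's frequency (percent).
annotate_supports <- function(tree, split_freq) {
  tree <- canonicalize_phylo(tree)
  topo <- tree_postorder(tree)
  labels <- topo$tip.label
  n <- length(labels)
  ref <- sort(labels)[1]
  below <- vector("list", topo$nnode)
  for (i in seq_len(n)) below[[i]] <- labels[i]
  node_lab <- rep(NA_character_, topo$nnode)
  for (e in seq_len(nrow(topo$edge))) {
    par <- topo$edge[e, 1]; ch <- topo$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labels, side)
    key <- paste(sort(side), collapse = "|")
    f <- split_freq[key]
    node_lab[ch] <- if (is.na(f) || length(f) == 0) "0" else
      as.character(round(unname(f)))
  }
  internal <- (n + 1):topo$nnode
  tree$node.label <- ifelse(is.na(node_lab[internal]), "",
                            node_lab[internal])
  tree
}
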