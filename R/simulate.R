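# Simulators: random trees, binary characters under the two-state + gamma
# model, and DNA sequences under a uniform-rate 4-state chain. These supply
# ground truth for validating every pipeline stage.

# Serialize a tree given as an edge list (parent id, child id, length) and
# a tip id -> label map, making no assumption about edge-row ordering.
newick_from_edges <- function(parents, children, lengths, tip_labels) {
  kids <- split(seq_along(parents), parents)
  root <- setdiff(parents, children)[1]
  rec <- function(node) {
    ke <- kids[[as.character(node)]]
    if (is.null(ke)) return(tip_labels[[as.character(node)]])
    paste0("(", paste(vapply(ke, function(e) {
      paste0(rec(children[e]), ":", format(lengths[e], digits = 12))
    }, ""), collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

# Rebuild a phylo object from its own edge matrix via Newick, restoring the
# ordering invariants ape's C routines expect (used after NNI edge surgery).
canonicalize_phylo <- function(tree) {
  ntip <- length(tree$tip.label)
  labels <- as.list(tree$tip.label)
  names(labels) <- as.character(seq_len(ntip))
  len <- tree$edge.length
  if (is.null(len)) len <- rep(1, nrow(tree$edge))
  txt <- newick_from_edges(tree$edge[, 1], tree$edge[, 2], len, labels)
  ape::read.tree(text = txt)
}

#' Random unrooted binary tree
#'
#' Grows a topology by sequential random leaf attachment: starting from the
#' unique 3-taxon star, each further leaf is attached to an edge chosen
#' uniformly at random. Branch lengths are drawn uniformly from
#' `branch_range`.
#'
#' @param n_taxa Number of leaves (>= 3); labelled `t1 ... tn`.
#' @param seed Random seed (the same seed reproduces the tree exactly).
#' @param branch_range Length-2 numeric, uniform bounds for branch lengths
#'   in substitutions/site (default `c(0.02, 0.4)`).
#' @return An unrooted binary `phylo` tree (basal trifurcation).
#' @export
random_tree <- function(n_taxa, seed = NULL, branch_range = c(0.02, 0.4)) {
  if (n_taxa < 3) stop("need at least 3 taxa")
  with_seed(seed, {
    # ids: tips 1..n_taxa, internal nodes from n_taxa+1 upward
    next_internal <- n_taxa + 1
    parents <- rep(next_internal, 3)
    children <- 1:3
    next_internal <- next_internal + 1
    if (n_taxa > 3) {
      for (leaf in 4:n_taxa) {
        e <- sample.int(length(parents), 1)
        w <- next_internal; next_internal <- next_internal + 1
        v <- children[e]
        children[e] <- w
        parents <- c(parents, w, w)
        children <- c(children, v, leaf)
      }
    }
    lengths <- stats::runif(length(parents), branch_range[1], branch_range[2])
    labels <- as.list(paste0("t", seq_len(n_taxa)))
    names(labels) <- as.character(seq_len(n_taxa))
    ape::read.tree(text = newick_from_edges(parents, children, lengths, labels))
  })
}

#' Simulate binary characters along a tree
#'
#' Draws independent sites under the two-state + gamma model: per site a
#' rate category and a root state (from the stationary frequencies) are
#' drawn, then the state is propagated down every branch using the
#' closed-form transition probabilities.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param model A [binary_model()].
#' @param n_sites Number of characters to simulate.
#' @param seed Random seed.
#' @return Integer 0/1 matrix, rows = sites, columns = tree tips (named).
#' @export
simulate_binary_matrix <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(n_sites >= 1)
  with_seed(seed, {
    topo <- tree_postorder(tree)
    ntip <- length(topo$tip.label)
    nnode <- topo$nnode
    cat_idx <- sample.int(model$ncat, n_sites, replace = TRUE,
                          prob = model$weights)
    rate <- model$rates[cat_idx]
    pi1 <- model$pi[[2]]
    states <- matrix(NA_integer_, nnode, n_sites)
    states[topo$root, ] <- stats::rbinom(n_sites, 1, pi1)
    # preorder = reversed postorder edge list
    for (e in rev(seq_len(nrow(topo$edge)))) {
      par <- topo$edge[e, 1]; ch <- topo$edge[e, 2]
      ee <- exp(-model$beta * rate * topo$lengths[e])
      p1 <- ifelse(states[par, ] == 1L, pi1 + (1 - pi1) * ee, pi1 * (1 - ee))
      states[ch, ] <- as.integer(stats::runif(n_sites) < p1)
    }
    out <- t(states[seq_len(ntip), , drop = FALSE])
    colnames(out) <- topo$tip.label
    out
  })
}

#' Simulate DNA sequences along a tree
#'
#' Generates a root sequence i.i.d. uniform over {A,C,G,T} and evolves it
#' down the tree under a single-rate uniform 4-state chain: on a branch of
#' length `t` each site substitutes with probability `3/4 (1 - e^{-4t/3})`,
#' uniformly to one of the three other bases.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param seq_length Sequence length in bases (>= 1).
#' @param seed Random seed.
#' @return Named list of single-contig character vectors (same shape as
#'   [read_fasta()] output), one element per tip.
#' @export
simulate_dna <- function(tree, seq_length, seed = NULL) {
  stopifnot(seq_length >= 1)
  with_seed(seed, {
    topo <- tree_postorder(tree)
    ntip <- length(topo$tip.label)
    bases <- c("A", "C", "G", "T")
    states <- matrix(NA_integer_, topo$nnode, seq_length)
    states[topo$root, ] <- sample.int(4, seq_length, replace = TRUE)
    for (e in rev(seq_len(nrow(topo$edge)))) {
      par <- topo$edge[e, 1]; ch <- topo$edge[e, 2]
      p_sub <- 0.75 * (1 - exp(-4 * topo$lengths[e] / 3))
      s <- states[par, ]
      hit <- stats::runif(seq_length) < p_sub
      nhit <- sum(hit)
      if (nhit > 0) {
        # substitute to one of the three other bases, uniformly
        shift <- sample.int(3, nhit, replace = TRUE)
        s[hit] <- ((s[hit] - 1 + shift) %% 4) + 1
      }
      states[ch, ] <- s
    }
    out <- lapply(seq_len(ntip), function(i)
      paste(bases[states[i, ]], collapse = ""))
    names(out) <- topo$tip.label
    out
  })
}

#' Write simulated sequences to FASTA files
#'
#' @param records Named list of contig character vectors.
#' @param dir Output directory (one `<taxon>.fasta` per taxon).
#' @return Character vector of file paths, invisibly.
#' @export
write_fasta <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(records))
  for (i in seq_along(records)) {
    taxon <- names(records)[i]
    paths[i] <- file.path(dir, paste0(taxon, ".fasta"))
    contigs <- records[[i]]
    hdr <- if (length(contigs) == 1) paste0(">", taxon) else
      paste0(">", taxon, "_contig", seq_along(contigs))
    writeLines(as.vector(rbind(hdr, contigs)), paths[i])
  }
  invisible(paths)
}
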