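# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/split code paths: the likelihood oracle enumerates
# ancestral states exhaustively, the transition oracle exponentiates the
# rate matrix numerically, and RF distances are cross-checked against
# phangorn.

# Exponential-time likelihood: sum over all internal-node state
# assignments and rate categories. Feasible up to ~6 taxa.
brute_force_loglik <- function(tree, model, x) {
  topo <- kmerphylo:::tree_postorder(tree)
  ntip <- length(topo$tip.label)
  nnode <- topo$nnode
  internals <- setdiff(seq_len(nnode), seq_len(ntip))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
  total <- 0
  for (s in seq_len(nrow(x))) {
    col <- x[s, topo$tip.label]
    lik <- 0
    for (c in seq_len(model$ncat)) {
      Ps <- lapply(seq_len(nrow(topo$edge)), function(e)
        transition_matrix(topo$lengths[e], model$rates[c], model))
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[seq_len(ntip)] <- col
        st[internals] <- grid[g, ]
        p <- model$pi[[st[topo$root] + 1]]
        for (e in seq_len(nrow(topo$edge)))
          p <- p * Ps[[e]][st[topo$edge[e, 1]] + 1, st[topo$edge[e, 2]] + 1]
        lik <- lik + model$weights[c] * p
      }
    }
    total <- total + log(lik)
  }
  total
}

# Transition matrix via numerical matrix exponential of Q (eigen route),
# independent of the closed form used in the package.
expm_transition <- function(t, r, pi0) {
  pi1 <- 1 - pi0
  beta <- 1 / (2 * pi0 * pi1)
  Q <- beta * matrix(c(-pi1, pi1, pi0, -pi0), 2, 2, byrow = TRUE)
  eg <- eigen(Q * r * t)
  Re(eg$vectors %*% diag(exp(eg$values)) %*% solve(eg$vectors))
}

# Random tree whose internal branches are at least `min_internal`.
random_tree_min_internal <- function(n, seed, min_internal = 0.05) {
  tr <- random_tree(n, seed = seed)
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  tr$edge.length[internal] <- pmax(tr$edge.length[internal], min_internal)
  tr
}

# Deterministic toy records shared by k-mer tests (three taxa; the 7-mer
# ATAGCGC is private to T1, the 2-mer AT is universal).
toy_records <- function() {
  list(T1 = "ATAGCGC", T2 = "ATTTTTT", T3 = "GGGGGAT")
}
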