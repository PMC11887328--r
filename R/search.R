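# Tree search: neighbor-joining start tree and NNI hill climbing.

#' Neighbor-joining starting tree from a presence/absence matrix
#'
#' Computes pairwise normalized Hamming distances between taxon columns and
#' runs neighbor joining. Negative NJ branch lengths are clamped to
#' `t_min`. Identical columns have distance zero and come out as siblings.
#'
#' @param x 0/1 matrix, columns = taxa (>= 3).
#' @param t_min Lower bound applied to branch lengths.
#' @return An unrooted `phylo` tree.
#' @export
nj_start_tree <- function(x, t_min = 1e-8) {
  m <- ncol(x)
  if (m < 3) stop("need at least 3 taxa for a tree")
  d <- matrix(0, m, m, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(m - 1))
    for (j in (i + 1):m)
      d[i, j] <- d[j, i] <- mean(x[, i] != x[, j])
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, t_min)
  tree
}

# The two NNI neighbors across each internal edge of an unrooted tree
# (represented with a basal multifurcation). Swapping one child subtree of
# the edge's lower node with a fixed subtree on the upper side yields both
# distinct rearrangements; pendant branch lengths travel with their
# subtrees.
nni_neighbors <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  internal <- which(edge[, 2] > ntip)
  out <- list()
  for (ie in internal) {
    u <- edge[ie, 1]; v <- edge[ie, 2]
    kids_v <- which(edge[, 1] == v)
    sib <- setdiff(which(edge[, 1] == u), ie)[1] # one fixed u-side subtree
    if (is.na(sib) || length(kids_v) < 2) next
    for (ka in kids_v[1:2]) {
      nb <- tree
      nb$edge[ka, 1] <- u
      nb$edge[sib, 1] <- v
      attr(nb, "order") <- NULL
      # restore ape's ordering invariants before any traversal
      out[[length(out) + 1]] <- list(tree = canonicalize_phylo(nb),
                                     edge = ie, swapped = c(ka, sib))
    }
  }
  out
}

#' Maximum-likelihood topology search by NNI hill climbing
#'
#' Starting from `start` (default: the neighbor-joining tree), evaluates
#' both nearest-neighbor-interchange rearrangements of every internal edge,
#' re-optimizing branch lengths on each candidate, accepts the best
#' improving move, and repeats until no move improves the log-likelihood by
#' more than `tol`. The log-likelihood trajectory across accepted moves is
#' strictly increasing and the returned value is never below the start
#' tree's.
#'
#' @param x 0/1 matrix, columns = taxa (>= 4).
#' @param model A fitted [binary_model()]; kept fixed during the search.
#' @param start Starting `phylo` tree (default [nj_start_tree()]).
#' @param t_min,t_max,tol As in [optimize_branch_lengths()].
#' @param quick_sweeps Branch-length sweeps used when scoring candidate
#'   moves (the accepted tree gets a full re-optimization).
#' @return List with the best `tree` (attribute-free `phylo`), its
#'   `loglik`, and the `trajectory` of accepted log-likelihoods.
#' @export
nni_search <- function(x, model, start = NULL, t_min = 1e-8, t_max = 100,
                       tol = 1e-6, quick_sweeps = 2) {
  if (ncol(x) < 4) stop("need at least 4 taxa for an NNI search")
  if (is.null(start)) start <- nj_start_tree(x, t_min)
  cur_tree <- ape::reorder.phylo(start, "postorder")
  pat0 <- compress_patterns(x, sort(colnames(x)))
  eng <- likelihood_engine(cur_tree, x, pat0)
  opt <- optimize_lengths_engine(eng, model, t_min, t_max,
                                 tol = max(tol, 1e-4), refine = FALSE)
  cur_tree$edge.length <- opt$lengths
  cur <- opt$loglik
  trajectory <- cur
  repeat {
    nbs <- nni_neighbors(cur_tree)
    if (length(nbs) == 0) break
    best <- NULL; best_ll <- -Inf
    for (nb in nbs) {
      eng_nb <- likelihood_engine(nb$tree, x, pat0)
      sc <- optimize_lengths_engine(eng_nb, model, t_min, t_max,
                                    tol = 1e-2, max_sweeps = quick_sweeps,
                                    refine = FALSE)
      if (sc$loglik > best_ll) {
        best_ll <- sc$loglik
        best <- nb$tree
      }
    }
    if (best_ll <= cur + tol) break
    eng_b <- likelihood_engine(best, x, pat0)
    ob <- optimize_lengths_engine(eng_b, model, t_min, t_max,
                                  tol = max(tol, 1e-4), refine = FALSE)
    if (ob$loglik <= cur + tol) break
    cur_tree <- ape::reorder.phylo(best, "postorder")
    cur_tree$edge.length <- ob$lengths
    cur <- ob$loglik
    trajectory <- c(trajectory, cur)
  }
  # full-precision polish of the final tree
  fin <- optimize_lengths_engine(likelihood_engine(cur_tree, x, pat0), model,
                                 t_min, t_max, tol,
                                 lengths = cur_tree$edge.length)
  cur_tree$edge.length <- fin$lengths
  cur <- max(cur, fin$loglik)
  list(tree = cur_tree, loglik = cur, trajectory = trajectory)
}
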