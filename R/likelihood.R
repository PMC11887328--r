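# Likelihood engine: site patterns, transition-probability assembly and the
# C++ pruning kernel, shared by the optimizers and the user-facing wrappers.

# Collapse matrix rows (sites) to unique 0/1 patterns over the taxa, in the
# column order `taxa`. Keeps integer weights; logL over patterns equals the
# uncollapsed sum exactly.
compress_patterns <- function(x, taxa) {
  xs <- x[, taxa, drop = FALSE]
  storage.mode(xs) <- "integer"
  if (!all(xs == 0L | xs == 1L)) stop("matrix entries must be 0 or 1")
  m <- ncol(xs)
  if (m > 30) {
    key <- apply(xs, 1, paste, collapse = "")
  } else {
    key <- as.vector(xs %*% 2^(seq_len(m) - 1))
  }
  first <- which(!duplicated(key))
  idx <- match(key, key[first])
  list(patterns = xs[first, , drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(first))),
       index = idx)
}

# Postorder topology bookkeeping for a phylo tree.
tree_postorder <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ape::Ntip(po) + po$Nnode
  root <- setdiff(po$edge[, 1], po$edge[, 2])
  list(edge = po$edge, lengths = po$edge.length, root = root[1],
       nnode = nnode, tip.label = po$tip.label)
}

# Per-edge, per-category transition probabilities in the flat layout the
# C++ kernel expects: dims (4, ncat, E), entries (P00, P10, P01, P11) --
# column-major (4, .) slice index j+1 corresponds to P[2*x+y] row-major in
# C++, i.e. j = 0:3 -> P00, P01, P10, P11. Assemble accordingly.
edge_probs <- function(lengths, model) {
  E <- length(lengths)
  pi0 <- model$pi[[1]]; pi1 <- model$pi[[2]]
  ee <- exp(outer(model$rates, lengths, function(r, t) -model$beta * r * t))
  A <- array(0, dim = c(4, model$ncat, E))
  A[1, , ] <- pi0 + pi1 * ee   # P00
  A[2, , ] <- pi1 * (1 - ee)   # P01
  A[3, , ] <- pi0 * (1 - ee)   # P10
  A[4, , ] <- pi1 + pi0 * ee   # P11
  A
}

# Single-edge version: the (4 x ncat) slice for one branch length.
edge_probs_one <- function(t, model) {
  pi0 <- model$pi[[1]]; pi1 <- model$pi[[2]]
  ee <- exp(-model$beta * model$rates * t)
  rbind(pi0 + pi1 * ee, pi1 * (1 - ee), pi0 * (1 - ee), pi1 + pi0 * ee)
}

# Build a fast evaluator bound to one (tree topology, data) pair. The
# returned function takes edge lengths and a model, and returns total logL
# (optionally per-pattern values); used by all the branch/shape optimizers.
# `pat0` may carry patterns precompressed over sorted(colnames(x)), so a
# topology search does not recompress a large matrix for every candidate:
# the pattern columns are simply permuted into the tree's tip order.
likelihood_engine <- function(tree, x, pat0 = NULL) {
  topo <- tree_postorder(tree)
  if (!setequal(colnames(x), topo$tip.label))
    stop("matrix taxa and tree tip labels differ: ",
         paste(symdiff_chr(colnames(x), topo$tip.label), collapse = ", "))
  pat <- if (is.null(pat0)) compress_patterns(x, topo$tip.label) else {
    perm <- match(topo$tip.label, sort(colnames(x)))
    list(patterns = pat0$patterns[, perm, drop = FALSE],
         weights = pat0$weights, index = pat0$index)
  }
  eval_P <- function(P, model, per_pattern = FALSE) {
    res <- loglik_bin_cpp(topo$edge, as.numeric(P), pat$patterns,
                          pat$weights, unname(model$pi), model$weights,
                          topo$nnode, topo$root)
    if (per_pattern) res else res$loglik
  }
  eval_fn <- function(lengths, model, per_pattern = FALSE) {
    eval_P(edge_probs(lengths, model), model, per_pattern)
  }
  list(eval = eval_fn, eval_P = eval_P, topo = topo, patterns = pat)
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' Site log-likelihood of one 0/1 character
#'
#' Computes the likelihood of a single presence/absence column on a tree by
#' Felsenstein pruning, per rate category and mixed over categories. The
#' root partial likelihoods are marginalized against the stationary
#' frequencies. An impossible observation (e.g. differing states joined by
#' zero-length branches) yields `-Inf` rather than an error.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model A [binary_model()].
#' @param column Named 0/1 vector covering exactly the tree's tips.
#' @return List with `log_likelihood` (mixed over categories) and
#'   `category_likelihoods` (one per rate category, on the likelihood
#'   scale).
#' @export
site_log_likelihood <- function(tree, model, column) {
  stopifnot(all(column %in% c(0, 1)))
  if (is.null(names(column))) names(column) <- tree$tip.label
  x <- matrix(as.integer(column), nrow = 1,
              dimnames = list(NULL, names(column)))
  eng <- likelihood_engine(tree, x)
  cat_lik <- numeric(model$ncat)
  for (c in seq_len(model$ncat)) {
    mc <- model
    mc$rates <- model$rates[c]; mc$weights <- 1; mc$ncat <- 1L
    cat_lik[c] <- exp(eng$eval(eng$topo$lengths, mc))
  }
  mixed <- sum(model$weights * cat_lik)
  list(log_likelihood = log(mixed), category_likelihoods = cat_lik)
}

#' Total log-likelihood of a presence/absence matrix on a tree
#'
#' Sums the per-site log-likelihoods of every matrix row (sites are
#' independent under the model). Identical rows are internally collapsed to
#' unique patterns with multiplicities; the result is mathematically
#' identical to the uncollapsed sum. No correction is applied for the
#' unobservable all-zero pattern.
#'
#' @param tree A `phylo` tree with branch lengths; tip labels must equal
#'   the matrix column names.
#' @param model A [binary_model()].
#' @param x 0/1 matrix, rows = sites (k-mers), columns = taxa.
#' @param per_site If `TRUE`, also return the per-row log-likelihoods.
#' @return List with `loglik` and, if requested, `site_loglik` (one value
#'   per matrix row, in row order).
#' @export
loglik_binary <- function(tree, model, x, per_site = FALSE) {
  eng <- likelihood_engine(tree, x)
  res <- eng$eval(eng$topo$lengths, model, per_pattern = TRUE)
  if (!per_site) return(list(loglik = res$loglik))
  list(loglik = res$loglik,
       site_loglik = res$site_loglik[eng$patterns$index])
}
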