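# Branch-length and model-parameter optimization by coordinate ascent.

#' Optimize branch lengths by iterated one-dimensional search
#'
#' Sweeps over all branches, optimizing each in turn by bounded scalar
#' search (Brent) on `[t_min, t_max]` with the other branches fixed, and
#' repeats until a full sweep improves the log-likelihood by less than
#' `tol`. The log-likelihood never decreases across sweeps.
#'
#' @param tree `phylo` tree (starting branch lengths; missing lengths are
#'   initialized at 0.1).
#' @param model A [binary_model()].
#' @param x 0/1 presence/absence matrix (columns = taxa).
#' @param t_min,t_max Branch-length bounds (defaults 1e-8 and 100
#'   substitutions/site).
#' @param tol Convergence tolerance in log-likelihood units (default 1e-6).
#' @param max_sweeps Cap on the number of full sweeps.
#' @return The tree with optimized `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, model, x, t_min = 1e-8,
                                    t_max = 100, tol = 1e-6,
                                    max_sweeps = 50) {
  eng <- likelihood_engine(tree, x)
  res <- optimize_lengths_engine(eng, model, t_min, t_max, tol, max_sweeps)
  out <- ape::reorder.phylo(tree, "postorder")
  out$edge.length <- res$lengths
  attr(out, "loglik") <- res$loglik
  out
}

optimize_lengths_engine <- function(eng, model, t_min = 1e-8, t_max = 100,
                                    tol = 1e-6, max_sweeps = 50,
                                    lengths = NULL, edges = NULL,
                                    refine = TRUE) {
  len <- if (is.null(lengths)) eng$topo$lengths else lengths
  if (is.null(len)) len <- rep(0.1, nrow(eng$topo$edge))
  len <- pmin(pmax(len, t_min), t_max)
  if (is.null(edges)) edges <- seq_along(len)
  topo <- eng$topo
  pat <- eng$patterns
  npat <- nrow(pat$patterns)
  wt <- pat$weights
  ncat <- model$ncat
  P <- edge_probs(len, model)
  cur <- eng$eval_P(P, model)
  bounds <- log(c(t_min, t_max))
  sweep_once <- function(t_tol) {
    # one Brent per branch on log(t); inside/outside partials make each
    # candidate length O(npat) instead of a full tree traversal
    for (e in edges) {
      ep <- edge_partials_cpp(topo$edge, as.numeric(P), pat$patterns,
                              unname(model$pi), ncat, topo$nnode,
                              topo$root, e)
      site_ll <- function(t) {
        edge_loglik_cpp(ep$below, ep$out,
                        as.numeric(edge_probs_one(t, model)),
                        wt, model$weights)
      }
      opt <- stats::optimize(function(lt) -site_ll(exp(lt)),
                             interval = bounds, tol = t_tol)
      # snap to the lower bound when it is at least as good (identical taxa)
      at_min <- site_ll(t_min)
      cand_t <- if (at_min >= -opt$objective) t_min else exp(opt$minimum)
      cand_ll <- max(at_min, -opt$objective)
      if (cand_ll > cur) {
        len[e] <<- cand_t
        cur <<- cand_ll
      }
      P[, , e] <<- edge_probs_one(len[e], model)
    }
  }
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    sweep_once(t_tol = 1e-3)
    if (cur - prev < tol) break
  }
  if (refine) {
    for (sweep in 1:2) {
      prev <- cur
      sweep_once(t_tol = 1e-7)
      if (cur - prev < tol * 1e-3) break
    }
  }
  cur <- eng$eval_P(P, model)
  list(lengths = len, loglik = cur)
}

#' Fit the two-state + gamma model on a fixed topology
#'
#' Stationary frequencies are set to the empirical global frequencies of 0s
#' and 1s in the matrix. The gamma shape `alpha` is then optimized by
#' bounded scalar search on `alpha_bounds`, alternated with branch-length
#' sweeps, until the joint log-likelihood improvement falls below `tol`.
#' For an all-constant matrix `alpha` is unidentifiable and is fixed at 1
#' with a warning.
#'
#' @param x 0/1 matrix, columns = taxa.
#' @param tree `phylo` tree whose tips match the matrix columns.
#' @param ncat Number of gamma categories (default 4).
#' @param alpha_bounds Search interval for the gamma shape
#'   (default `c(0.02, 100)`).
#' @param t_min,t_max,tol As in [optimize_branch_lengths()].
#' @return List with the fitted `model` ([binary_model()]), the tree with
#'   re-optimized branch lengths, and the final `loglik`.
#' @export
fit_model <- function(x, tree, ncat = 4, alpha_bounds = c(0.02, 100),
                      t_min = 1e-8, t_max = 100, tol = 1e-6) {
  pi1 <- mean(x == 1)
  if (pi1 <= 0 || pi1 >= 1) {
    warning("matrix is all-constant; stationary frequencies are degenerate")
    pi1 <- min(max(pi1, 1e-6), 1 - 1e-6)
  }
  eng <- likelihood_engine(tree, x)
  constant <- all(apply(eng$patterns$patterns, 1,
                        function(r) length(unique(r)) == 1))
  variable <- any(apply(eng$patterns$patterns, 1,
                        function(r) length(unique(r)) > 1))
  if (!variable) {
    warning("no variable sites: gamma shape is unidentifiable, fixing alpha = 1")
    model <- binary_model(pi1 = pi1, alpha = 1, ncat = ncat)
    bl <- optimize_lengths_engine(eng, model, t_min, t_max, tol)
    out_tree <- ape::reorder.phylo(tree, "postorder")
    out_tree$edge.length <- bl$lengths
    return(list(model = model, tree = out_tree, loglik = bl$loglik))
  }
  alpha <- 1
  coarse <- max(tol, 1e-3) # cheap sweeps while alternating, full at the end
  model <- binary_model(pi1 = pi1, alpha = alpha, ncat = ncat)
  bl <- optimize_lengths_engine(eng, model, t_min, t_max, coarse,
                                refine = FALSE)
  cur <- bl$loglik
  iter <- 0
  repeat {
    prev <- cur
    iter <- iter + 1
    g <- function(a) {
      m <- binary_model(pi1 = pi1, alpha = a, ncat = ncat)
      -eng$eval(bl$lengths, m)
    }
    opt <- stats::optimize(g, interval = alpha_bounds, tol = 1e-4)
    if (-opt$objective > cur) {
      alpha <- opt$minimum
      cur <- -opt$objective
    }
    model <- binary_model(pi1 = pi1, alpha = alpha, ncat = ncat)
    bl <- optimize_lengths_engine(eng, model, t_min, t_max, coarse,
                                  lengths = bl$lengths, refine = FALSE)
    cur <- bl$loglik
    if (cur - prev < max(tol, 1e-4) || iter >= 10) break
  }
  bl <- optimize_lengths_engine(eng, model, t_min, t_max, tol,
                                lengths = bl$lengths)
  cur <- bl$loglik
  out_tree <- ape::reorder.phylo(tree, "postorder")
  out_tree$edge.length <- bl$lengths
  list(model = model, tree = out_tree, loglik = cur)
}
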