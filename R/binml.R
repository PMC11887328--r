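#' Maximum-likelihood phylogeny from a binary presence/absence matrix
#'
#' The package's central fit. Under a reversible two-state substitution
#' model with discrete-gamma rate heterogeneity, `binml()` estimates a tree
#' from a 0/1 character matrix: stationary frequencies are set empirically,
#' the gamma shape and branch lengths are optimized by coordinate ascent,
#' and the topology is improved by NNI hill climbing from a
#' neighbor-joining start tree. Each matrix row (k-mer) is one independent
#' site.
#'
#' Branch lengths are reported but should be treated as unreliable:
#' neighboring k-mers overlap on the genome, so one substitution perturbs
#' up to k sites at once and inflates apparent change. The topology is the
#' supported output.
#'
#' @param x 0/1 matrix, rows = sites (k-mers), columns = taxa (>= 4 for a
#'   topology search, >= 2 otherwise).
#' @param ncat Number of gamma rate categories (default 4).
#' @param search `"nni"` (default) for topology search, `"none"` to keep
#'   the start topology and only fit the model and branch lengths.
#' @param start Optional starting `phylo` tree (default: neighbor joining).
#' @param alpha_bounds,t_min,t_max,tol Optimization controls, see
#'   [fit_model()] and [optimize_branch_lengths()].
#' @return An object of class `binml`: list with `tree` (phylo), `logLik`,
#'   `model` ([binary_model()]), `site_loglik` (per matrix row),
#'   `trajectory` (accepted log-likelihoods of the NNI search), `data`
#'   summary and `call`.
#' @examples
#' tr <- random_tree(5, seed = 1)
#' x <- simulate_binary_matrix(tr, binary_model(), 300, seed = 2)
#' fit <- binml(x)
#' fit
#' @export
binml <- function(x, ncat = 4, search = c("nni", "none"), start = NULL,
                  alpha_bounds = c(0.02, 100), t_min = 1e-8, t_max = 100,
                  tol = 1e-6) {
  search <- match.arg(search)
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (is.null(colnames(x))) stop("matrix must have taxon column names")
  if (is.null(start)) {
    if (ncol(x) < 3) stop("need at least 3 taxa without a start tree")
    start <- nj_start_tree(x, t_min)
  }
  fit <- fit_model(x, start, ncat = ncat, alpha_bounds = alpha_bounds,
                   t_min = t_min, t_max = t_max, tol = tol)
  trajectory <- fit$loglik
  tree <- fit$tree
  if (search == "nni" && ncol(x) >= 4) {
    sr <- nni_search(x, fit$model, start = tree, t_min = t_min,
                     t_max = t_max, tol = tol)
    if (length(sr$trajectory) > 1) {
      # topology changed: refit the shape on the new topology
      fit <- fit_model(x, sr$tree, ncat = ncat, alpha_bounds = alpha_bounds,
                       t_min = t_min, t_max = t_max, tol = tol)
      tree <- fit$tree
      trajectory <- c(trajectory, sr$trajectory[-1], fit$loglik)
    } else {
      tree <- sr$tree
      trajectory <- sr$trajectory
    }
  }
  ll <- loglik_binary(tree, fit$model, x, per_site = TRUE)
  structure(list(tree = tree, logLik = ll$loglik, model = fit$model,
                 site_loglik = ll$site_loglik, trajectory = trajectory,
                 data = list(n_sites = nrow(x), n_taxa = ncol(x),
                             taxa = colnames(x)),
                 call = match.call()),
            class = "binml")
}

#' @export
print.binml <- function(x, ...) {
  cat("Two-state + gamma maximum-likelihood phylogeny\n")
  cat(sprintf("  %d taxa, %d sites; log-likelihood %.4f\n",
              x$data$n_taxa, x$data$n_sites, x$logLik))
  cat(sprintf("  alpha = %.4g, pi0 = %.4f, pi1 = %.4f (%d rate categories)\n",
              x$model$alpha, x$model$pi[1], x$model$pi[2], x$model$ncat))
  cat("  tree:", write_newick(x$tree), "\n")
  invisible(x)
}

#' @export
summary.binml <- function(object, ...) {
  out <- list(
    n_taxa = object$data$n_taxa, n_sites = object$data$n_sites,
    logLik = object$logLik, coef = coef(object),
    rates = object$model$rates,
    n_accepted_moves = max(0L, length(object$trajectory) - 1L),
    tree = write_newick(object$tree))
  class(out) <- "summary.binml"
  out
}

#' @export
print.summary.binml <- function(x, ...) {
  cat("Two-state + gamma ML phylogeny\n")
  cat(sprintf("Data: %d taxa x %d sites\n", x$n_taxa, x$n_sites))
  cat(sprintf("log-likelihood: %.4f\n", x$logLik))
  cat("Coefficients:\n"); print(x$coef)
  cat("Gamma category rates:", paste(sprintf("%.4f", x$rates),
                                     collapse = " "), "\n")
  cat("Accepted NNI moves:", x$n_accepted_moves, "\n")
  cat("Tree:", x$tree, "\n")
  invisible(x)
}

#' @export
logLik.binml <- function(object, ...) {
  # free parameters: branch lengths + gamma shape (frequencies are
  # empirical, not ML-estimated)
  val <- object$logLik
  attr(val, "df") <- nrow(object$tree$edge) + 1
  attr(val, "nobs") <- object$data$n_sites
  class(val) <- "logLik"
  val
}

#' @export
coef.binml <- function(object, ...) {
  c(alpha = unname(object$model$alpha),
    pi0 = unname(object$model$pi[1]), pi1 = unname(object$model$pi[2]))
}

#' @export
plot.binml <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
}

#' Simulate replicate matrices from a fitted binml model
#'
#' Parametric simulation: draws new 0/1 matrices under the fitted tree and
#' model with [simulate_binary_matrix()].
#'
#' @param object A [binml()] fit.
#' @param nsim Number of replicate matrices.
#' @param seed Random seed.
#' @param n_sites Sites per replicate (default: as in the fitted data).
#' @param ... Unused.
#' @return List of 0/1 matrices.
#' @export
simulate.binml <- function(object, nsim = 1, seed = NULL, n_sites = NULL,
                           ...) {
  if (is.null(n_sites)) n_sites <- object$data$n_sites
  seeds <- if (is.null(seed)) rep(list(NULL), nsim) else
    as.list(seed + seq_len(nsim) - 1)
  lapply(seeds, function(s)
    simulate_binary_matrix(object$tree, object$model, n_sites, seed = s))
}
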