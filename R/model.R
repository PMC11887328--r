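#' Two-state substitution model with gamma rate heterogeneity
#'
#' A reversible continuous-time Markov chain on states {0, 1} with
#' stationary frequencies `(pi0, pi1)`, scaled so the expected number of
#' substitutions per unit branch length is 1 at the mean rate, combined
#' with a mean-1 discrete-gamma mixture of per-site rate multipliers
#' (shape `alpha`, `ncat` equal-probability categories).
#'
#' @param pi1 Stationary frequency of state 1 (presence); `pi0 = 1 - pi1`.
#' @param alpha Gamma shape parameter (> 0); small values mean strong
#'   rate heterogeneity across sites.
#' @param ncat Number of discrete rate categories (default 4).
#' @return An object of class `binary_model` with elements `pi`, `alpha`,
#'   `ncat`, `rates`, `weights` and the scaling constant `beta`.
#' @examples
#' binary_model(pi1 = 0.4, alpha = 0.5)
#' @export
binary_model <- function(pi1 = 0.5, alpha = 1, ncat = 4) {
  stopifnot(pi1 > 0, pi1 < 1, alpha > 0, ncat >= 1)
  pi0 <- 1 - pi1
  g <- discrete_gamma_rates(alpha, ncat)
  structure(list(pi = c(pi0 = pi0, pi1 = pi1), alpha = alpha,
                 ncat = as.integer(ncat), rates = g$rates,
                 weights = g$weights, beta = 1 / (2 * pi0 * pi1)),
            class = "binary_model")
}

#' @export
print.binary_model <- function(x, ...) {
  cat(sprintf("Two-state model: pi0 = %.4f, pi1 = %.4f, alpha = %.4g, %d gamma categories\n",
              x$pi[1], x$pi[2], x$alpha, x$ncat))
  cat("category rates:", paste(sprintf("%.4f", x$rates), collapse = " "), "\n")
  invisible(x)
}

#' Discrete-gamma rate categories
#'
#' Discretizes a mean-1 gamma distribution with shape `alpha` into `ncat`
#' equal-probability categories, each represented by its conditional mean
#' (computed in closed form from the incomplete-gamma identity, so the
#' probability-weighted mean of the rates is exactly 1).
#'
#' @param alpha Gamma shape (> 0).
#' @param ncat Number of categories (>= 1).
#' @return List with `rates` (increasing, mean 1) and `weights`
#'   (all `1/ncat`).
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4) {
  stopifnot(alpha > 0, ncat >= 1)
  if (ncat == 1) return(list(rates = 1, weights = 1))
  # category boundaries at gamma quantiles; conditional mean on (a, b] of
  # Gamma(shape = alpha, rate = alpha) is ncat * (F_{alpha+1}(b) - F_{alpha+1}(a))
  cuts <- stats::qgamma(seq_len(ncat - 1) / ncat, shape = alpha, rate = alpha)
  upper <- stats::pgamma(c(cuts, Inf), shape = alpha + 1, rate = alpha)
  lower <- c(0, upper[-ncat])
  rates <- ncat * (upper - lower)
  list(rates = rates, weights = rep(1 / ncat, ncat))
}

#' Transition probabilities of the two-state chain
#'
#' Closed-form transition matrix over a branch of length `t` at rate
#' multiplier `r`: with `beta = 1/(2 pi0 pi1)` and `e = exp(-beta r t)`,
#' `P(0->0) = pi0 + pi1 e`, `P(0->1) = pi1 (1 - e)`, and symmetrically for
#' state 1. Rows sum to 1 and the chain satisfies detailed balance.
#'
#' @param t Branch length in expected substitutions per site (>= 0).
#' @param r Rate multiplier (>= 0, default 1).
#' @param model A [binary_model()].
#' @return 2x2 stochastic matrix with dimnames `c("0", "1")`.
#' @examples
#' transition_matrix(0.5, model = binary_model(pi1 = 0.5))
#' @export
transition_matrix <- function(t, r = 1, model = binary_model()) {
  stopifnot(t >= 0, r >= 0)
  pi0 <- model$pi[[1]]; pi1 <- model$pi[[2]]
  e <- exp(-model$beta * r * t)
  P <- matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
                pi1 * (1 - e), pi1 + pi0 * e), 2, 2,
              dimnames = list(c("0", "1"), c("0", "1")))
  P
}
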