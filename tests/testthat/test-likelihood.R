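test_that("degenerate site likelihoods collapse to stationarity or impossibility", {
  tr <- parse_newick("(A:0,B:0);")
  m <- binary_model(pi1 = 0.5, ncat = 1)
  res <- site_log_likelihood(tr, m, c(A = 1, B = 1))
  expect_equal(res$log_likelihood, log(0.5))
  # contradictory states joined by zero branches: impossible, -Inf not error
  res0 <- site_log_likelihood(tr, m, c(A = 0, B = 1))
  expect_equal(res0$log_likelihood, -Inf)
})

test_that("three-taxon star likelihood equals the root-state sum", {
  tr <- parse_newick("(A:0.1,B:0.1,C:0.1);")
  m <- binary_model(pi1 = 0.5, ncat = 1)
  res <- site_log_likelihood(tr, m, c(A = 1, B = 1, C = 0))
  P <- transition_matrix(0.1, model = m)
  manual <- sum(vapply(1:2, function(x)
    m$pi[[x]] * P[x, 2] * P[x, 2] * P[x, 1], 0))
  expect_equal(res$log_likelihood, log(manual), tolerance = 1e-12)
})

test_that("pruning agrees with exhaustive ancestral-state enumeration", {
  set.seed(51)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    tr <- random_tree(n, seed = rep * 7)
    m <- binary_model(pi1 = runif(1, 0.1, 0.9),
                      alpha = exp(runif(1, log(0.2), log(5))),
                      ncat = sample(1:4, 1))
    x <- simulate_binary_matrix(tr, m, sample(5:15, 1), seed = rep)
    expect_equal(loglik_binary(tr, m, x)$loglik,
                 brute_force_loglik(tr, m, x), tolerance = 1e-10)
  }
})

test_that("sites are independent: duplication doubles, permutation preserves logL", {
  tr <- random_tree(6, seed = 5)
  m <- binary_model(pi1 = 0.4, alpha = 0.8)
  x <- simulate_binary_matrix(tr, m, 100, seed = 6)
  ll <- loglik_binary(tr, m, x, per_site = TRUE)
  expect_equal(loglik_binary(tr, m, rbind(x, x))$loglik, 2 * ll$loglik,
               tolerance = 1e-9)
  expect_equal(sum(ll$site_loglik), ll$loglik, tolerance = 1e-9)
  set.seed(7)
  perm <- sample(nrow(x))
  expect_equal(loglik_binary(tr, m, x[perm, ])$loglik, ll$loglik,
               tolerance = 1e-9)
})

test_that("likelihood is invariant to rerooting the unrooted topology", {
  tr <- random_tree(7, seed = 8)
  m <- binary_model(pi1 = 0.35, alpha = 1.2)
  x <- simulate_binary_matrix(tr, m, 80, seed = 9)
  base <- loglik_binary(tr, m, x)$loglik
  ntip <- ape::Ntip(tr)
  for (node in (ntip + 2):(ntip + tr$Nnode)) {
    rr <- ape::root(tr, node = node, resolve.root = FALSE)
    expect_equal(loglik_binary(rr, m, x)$loglik, base, tolerance = 1e-8)
  }
})

test_that("pattern collapse is exact: compressed and raw site sums agree", {
  tr <- random_tree(5, seed = 10)
  m <- binary_model(pi1 = 0.5, alpha = 1, ncat = 2)
  x <- simulate_binary_matrix(tr, m, 400, seed = 11) # many repeated patterns
  ll <- loglik_binary(tr, m, x, per_site = TRUE)
  raw <- sum(vapply(seq_len(nrow(x)), function(i)
    site_log_likelihood(tr, m, x[i, ])$log_likelihood, 0))
  expect_equal(ll$loglik, raw, tolerance = 1e-8)
})

test_that("taxon mismatches are rejected with the offending labels", {
  tr <- random_tree(5, seed = 12)
  x <- simulate_binary_matrix(tr, binary_model(), 10, seed = 13)
  colnames(x)[1] <- "zz"
  expect_error(loglik_binary(tr, binary_model(), x), "zz")
})

test_that("constant matrices approach the stationary log-likelihood on long branches", {
  tr <- parse_newick("(A:50,B:50,C:50);")
  m <- binary_model(pi1 = 0.3, ncat = 1)
  x <- matrix(1L, 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(loglik_binary(tr, m, x)$loglik, 20 * 3 * log(0.3),
               tolerance = 1e-6)
})
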