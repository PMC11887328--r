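test_that("random trees are deterministic, binary and correctly sized", {
  t1 <- random_tree(8, seed = 91)
  t2 <- random_tree(8, seed = 91)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_false(identical(write_newick(t1), write_newick(random_tree(8, seed = 92))))
  expect_equal(ape::Ntip(t1), 8)
  expect_length(bipartitions(t1), 5) # n - 3 internal edges
  expect_equal(ape::Ntip(random_tree(3, seed = 1)), 3)
  expect_error(random_tree(2), "at least 3")
  rng <- range(t1$edge.length)
  expect_gte(rng[1], 0.02); expect_lte(rng[2], 0.4)
})

test_that("binary simulation respects branch lengths and stationarity", {
  tr <- parse_newick("(a:0,b:0,c:0);")
  x0 <- simulate_binary_matrix(tr, binary_model(), 50, seed = 93)
  expect_true(all(x0[, 1] == x0[, 2] & x0[, 2] == x0[, 3]))
  # far-apart leaves on a star: state-1 frequency near pi1
  star <- parse_newick("(a:10,b:10,c:10);")
  m <- binary_model(pi1 = 0.3)
  x <- simulate_binary_matrix(star, m, 10000, seed = 94)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_true(all(abs(colMeans(x) - 0.3) < 3 * se))
  expect_identical(simulate_binary_matrix(star, m, 100, seed = 9),
                   simulate_binary_matrix(star, m, 100, seed = 9))
})

test_that("DNA simulation has the uniform-chain limits", {
  tr0 <- parse_newick("(a:0,b:0);")
  recs0 <- simulate_dna(tr0, 500, seed = 95)
  expect_equal(recs0$a, recs0$b) # zero branches: identical leaves
  # long branches: ~3/4 of sites differ
  trX <- parse_newick("(a:50,b:50);")
  recsX <- simulate_dna(trX, 20000, seed = 96)
  da <- strsplit(recsX$a, "")[[1]]; db <- strsplit(recsX$b, "")[[1]]
  expect_equal(mean(da != db), 0.75, tolerance = 0.02)
  # moderate branch: divergence matches 3/4 (1 - e^{-4t/3})
  trM <- parse_newick("(a:0.1,b:0.1);")
  recsM <- simulate_dna(trM, 20000, seed = 97)
  expd <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  dm <- mean(strsplit(recsM$a, "")[[1]] != strsplit(recsM$b, "")[[1]])
  expect_equal(dm, expd, tolerance = 0.02)
})

test_that("model-recovery round trip: simulated data refit the generating parameters", {
  tr <- random_tree_min_internal(6, seed = 98)
  m <- binary_model(pi1 = 0.4, alpha = 1)
  x <- simulate_binary_matrix(tr, m, 3000, seed = 99)
  fit <- binml(x)
  expect_equal(normalized_rf(fit$tree, tr), 0)
  expect_equal(unname(fit$model$pi[2]), mean(x == 1), tolerance = 1e-12)
  expect_gt(fit$model$alpha, 0.5)
})

test_that("segment inversions are invisible to canonical counting except at breakpoints", {
  set.seed(100)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  mutate <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), n)
    v[idx] <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    paste(v, collapse = "")
  }
  recs <- list(A = base, B = mutate(base, 40), C = mutate(base, 40))
  # invert (reverse-complement) an internal segment of taxon C
  v <- strsplit(recs$C, "")[[1]]
  seg <- 501:1500
  v[seg] <- strsplit(reverse_complement(paste(v[seg], collapse = "")),
                     "")[[1]]
  inv <- recs
  inv$C <- paste(v, collapse = "")
  k <- 9
  can0 <- kmer_matrix(recs, k)
  can1 <- kmer_matrix(inv, k)
  nc0 <- kmer_matrix(recs, k, mode = "non-canonical")
  nc1 <- kmer_matrix(inv, k, mode = "non-canonical")
  # canonical matrices differ only near the two breakpoints
  diff_can <- length(setdiff(rownames(can0), rownames(can1))) +
    length(setdiff(rownames(can1), rownames(can0)))
  diff_nc <- length(setdiff(rownames(nc0), rownames(nc1))) +
    length(setdiff(rownames(nc1), rownames(nc0)))
  expect_lte(diff_can, 4 * (k - 1)) # only windows crossing the breakpoints
  expect_gt(diff_nc, 100) # strand-specific counting sees the whole segment
})
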