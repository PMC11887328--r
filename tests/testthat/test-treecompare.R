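test_that("Newick parsing round-trips topology, lengths and supports", {
  t1 <- parse_newick("((A,B),(C,D));")
  expect_equal(write_newick(t1), "((A,B),(C,D));")
  t2 <- parse_newick("((A:0.1,B:0.2)95:0.05,C:0.3);")
  expect_equal(sort(t2$tip.label), c("A", "B", "C"))
  expect_true("95" %in% t2$node.label)
  expect_equal(sort(t2$edge.length), sort(c(0.1, 0.2, 0.05, 0.3)))
  expect_error(parse_newick("((A,B);"), "malformed")
  expect_error(parse_newick("((A,A),B);"), "duplicate")
})

test_that("bipartitions read off the internal edges of the unrooted tree", {
  expect_setequal(bipartitions(parse_newick("((A,B),(C,D),E);")),
                  c("C|D", paste(sort(c("C", "D", "E")), collapse = "|")))
  expect_length(bipartitions(parse_newick("(A,B,C);")), 0)
  expect_length(bipartitions(parse_newick("(A,B,C,D,E);")), 0) # star
  # rooted and unrooted forms give identical splits
  expect_setequal(bipartitions(parse_newick("((A,B),(C,D));")),
                  bipartitions(parse_newick("(A,B,(C,D));")))
})

test_that("RF distance counts unmatched splits", {
  t1 <- parse_newick("((A,B),C,(D,E));")
  t2 <- parse_newick("((A,C),B,(D,E));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2) # DE|ABC shared, one split differs
  t3 <- parse_newick("((A,B),(C,D),E);")
  t4 <- parse_newick("((A,C),(B,D),E);")
  expect_equal(rf_distance(t3, t4), 4) # no shared splits
  expect_error(rf_distance(t1, parse_newick("((A,B),C,(D,F));")), "differ")
})

test_that("normalized RF divides by the joint split count", {
  t1 <- parse_newick("((A,B),C,(D,E));")
  t2 <- parse_newick("((A,C),B,(D,E));")
  expect_equal(normalized_rf(t1, t2), 0.5) # RF 2 over 2 + 2 splits
  expect_equal(normalized_rf(t1, t1), 0)
  t3 <- parse_newick("((A,B),(C,D),E);")
  t4 <- parse_newick("((A,C),(B,D),E);")
  expect_equal(normalized_rf(t3, t4), 1)
  expect_warning(v <- normalized_rf(parse_newick("(A,B,C,D);"),
                                    parse_newick("(A,B,C,D);")), "star")
  expect_equal(v, 0)
  # 14 fully resolved taxa differing by one NNI: 2 / (2 * (14 - 3))
  t5 <- random_tree(14, seed = 81)
  nb <- kmerphylo:::nni_neighbors(t5)[[1]]$tree
  expect_equal(normalized_rf(t5, nb), 2 / 22)
})

test_that("RF agrees with phangorn and is invariant to rooting and rotation", {
  skip_if_not_installed("phangorn")
  set.seed(82)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    t1 <- ape::rtree(n, rooted = FALSE)
    t2 <- ape::rtree(n, rooted = FALSE)
    expect_equal(rf_distance(t1, t2), phangorn::RF.dist(t1, t2))
  }
  t1 <- random_tree(7, seed = 83)
  rooted <- ape::root(t1, outgroup = "t1", resolve.root = TRUE)
  rotated <- parse_newick(write_newick(ape::rotateConstr(
    t1, sample(t1$tip.label))))
  expect_equal(rf_distance(t1, rooted), 0)
  expect_equal(rf_distance(t1, rotated), 0)
})

test_that("RF is a metric on resolved trees: symmetry and identity", {
  set.seed(84)
  trees <- lapply(1:6, function(i) ape::rtree(6, rooted = FALSE))
  for (i in 1:5) {
    a <- trees[[i]]; b <- trees[[i + 1]]
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_true((rf_distance(a, b) == 0) ==
                  (setequal(bipartitions(a), bipartitions(b))))
  }
  # triangle inequality spot-check
  for (i in 1:4) {
    d_ab <- rf_distance(trees[[i]], trees[[i + 1]])
    d_bc <- rf_distance(trees[[i + 1]], trees[[i + 2]])
    d_ac <- rf_distance(trees[[i]], trees[[i + 2]])
    expect_lte(d_ac, d_ab + d_bc)
  }
})

test_that("compare_trees prints RF and nRF for files and objects", {
  t1 <- random_tree(6, seed = 85)
  f1 <- tempfile(fileext = ".nwk")
  ape::write.tree(t1, f1)
  expect_output(res <- compare_trees(f1, f1), "RF 0 nRF 0\\.0000")
  expect_equal(res$rf, 0)
  t2 <- parse_newick("((t1,t2),t3,(t4,(t5,t6)));")
  res2 <- compare_trees(t1, t2, quiet = TRUE)
  expect_equal(res2$nrf, rf_distance(t1, t2) /
                 (length(bipartitions(t1)) + length(bipartitions(t2))))
})
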