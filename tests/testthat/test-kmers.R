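test_that("reverse complement follows Watson-Crick pairing and is an involution", {
  expect_equal(reverse_complement("AT"), "AT")
  expect_equal(reverse_complement("AAA"), "TTT")
  expect_equal(reverse_complement(c("ACGT", "GATTACA")),
               c("ACGT", "TGTAATC"))
  set.seed(11)
  for (k in c(1, 5, 12, 31)) {
    x <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = "")
    expect_equal(reverse_complement(reverse_complement(x)), x)
  }
  expect_error(reverse_complement("ANA"), "non-ACGT")
})

test_that("canonical form is the lexicographic minimum of a k-mer and its reverse complement", {
  expect_equal(canonical_form("TTT"), "AAA")
  # reverse complement of ATAGCGC is GCGCTAT, lexicographically larger
  expect_equal(canonical_form("ATAGCGC"), "ATAGCGC")
  expect_equal(canonical_form("ACGT"), "ACGT") # palindrome maps to itself
  set.seed(12)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
               collapse = "")
    cf <- canonical_form(x)
    expect_equal(cf, min(x, reverse_complement(x)))
    expect_equal(canonical_form(reverse_complement(x)), cf)
  }
})

test_that("k-mer enumeration slides windows, skips ambiguity codes and respects contig boundaries", {
  expect_true("ATAGCGC" %in% enumerate_kmers("ATAGCGC", 7))
  expect_equal(enumerate_kmers("AT", 2), "AT")
  expect_equal(enumerate_kmers("AT", 5), character(0)) # shorter than k
  # windows containing N are dropped entirely
  expect_equal(enumerate_kmers("ANAT", 2, mode = "non-canonical"), "AT")
  # two contigs never yield the junction-spanning k-mer
  joined <- enumerate_kmers("AAATTT", 4, mode = "non-canonical")
  split2 <- enumerate_kmers(c("AAA", "TTT"), 4, mode = "non-canonical")
  expect_true("AATT" %in% joined)
  expect_equal(split2, character(0))
  # lowercase input is accepted (uppercased on ingest)
  expect_equal(enumerate_kmers("atagcgc", 7), enumerate_kmers("ATAGCGC", 7))
})

test_that("canonical enumeration equals canonicalized non-canonical enumeration", {
  set.seed(13)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  for (k in c(3, 9, 15)) {
    nc <- enumerate_kmers(seq, k, mode = "non-canonical")
    can <- enumerate_kmers(seq, k, mode = "canonical")
    expect_equal(can, sort(unique(canonical_form(nc))))
  }
})

test_that("2-bit integer codes round-trip for k up to 31", {
  set.seed(14)
  for (k in c(1, 4, 15, 26, 31)) {
    kmers <- vapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
            collapse = ""), "")
    expect_equal(kmer_decode(kmer_encode(kmers), k), kmers)
  }
  # codes are ascending in the A<C<G<T string order
  expect_equal(kmer_encode(c("AA", "AC", "TT")),
               as.character(c(0, 1, 15)))
  expect_error(enumerate_kmers("ACGT", 32), "between 1 and 31")
})

test_that("FASTA reading merges contigs per taxon and rejects degenerate input", {
  dir <- withr::local_tempdir()
  fa1 <- file.path(dir, "T1.fasta")
  writeLines(c(">T1", "ATAGCGC"), fa1)
  fa2 <- file.path(dir, "T2.fasta")
  writeLines(c(">c1", "AAA", ">c2", "TTT"), fa2)
  recs <- read_fasta(c(fa1, fa2))
  expect_named(recs, c("T1", "T2"))
  expect_equal(recs$T1, "ATAGCGC")
  expect_equal(recs$T2, c("AAA", "TTT")) # contigs kept separate
  empty <- file.path(dir, "empty.fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
  expect_error(read_fasta(c(fa1, fa1)), "duplicate")
  # manifest TSV route
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(c(paste("alpha", fa1, sep = "\t"),
               paste("beta", fa2, sep = "\t")), manifest)
  recs2 <- read_fasta(manifest)
  expect_named(recs2, c("alpha", "beta"))
})
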