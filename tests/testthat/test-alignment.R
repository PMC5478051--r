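test_that("FASTA round trip preserves ids, order and sequences", {
  a <- alignment(c(s1 = "ACGTACGT", s2 = "ACGTTCGA", s3 = "ACG-NCGT"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(a, path)
  b <- read_alignment(path)
  expect_identical(names(b), names(a))
  expect_identical(unname(unclass(b)), unname(unclass(a)))
})

test_that("ragged or duplicated FASTA records are rejected", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTA"), path)
  expect_error(read_alignment(path), "ragged")
  expect_error(alignment(c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("concatenation joins fragments per id and adds lengths", {
  set.seed(42)
  rand_aln <- function(n, L) {
    alignment(setNames(
      replicate(n, paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")),
      paste0("s", seq_len(n))))
  }
  a <- rand_aln(5, 724)
  b <- rand_aln(5, 342)
  ab <- concat_alignments(a, b)
  expect_equal(nchar(ab[[1]]), 1066)
  expect_identical(unname(ab[3]), paste0(unname(a[3]), unname(b[3])))
  # id order comes from the first fragment even if b is shuffled
  b_shuf <- alignment(unclass(b)[c(3, 1, 2, 5, 4)])
  expect_identical(names(concat_alignments(a, b_shuf)), names(a))
  # zero-length second fragment is the identity
  empty <- alignment(setNames(rep("", 5), names(a)))
  expect_identical(unclass(concat_alignments(a, empty)), unclass(a))
  expect_error(concat_alignments(a, alignment(unclass(b)[-1])), "id sets")
})

test_that("haplotype collapsing uses strict string identity in order of appearance", {
  a <- alignment(c(x1 = "AAA", x2 = "AAT", x3 = "AAA", x4 = "AAT", x5 = "ATT"))
  h <- find_haplotypes(a)
  expect_equal(h$n_haplotypes, 3)
  expect_equal(unname(h$assignment), c(1, 2, 1, 2, 3))
  same <- alignment(setNames(rep("ACGT", 4), paste0("s", 1:4)))
  expect_equal(find_haplotypes(same)$n_haplotypes, 1)
  dist <- alignment(c(a = "AAAA", b = "AAAC", c = "AAAG"))
  expect_equal(find_haplotypes(dist)$n_haplotypes, 3)
})

test_that("p-distances count differences over pairwise-comparable sites", {
  a <- alignment(c(u = "AAAA", v = "AAAT"))
  expect_equal(pairwise_p_distances(a)["u", "v"], 0.25)
  # N is excluded pair-wise: 0 differences over 3 comparable sites
  b <- alignment(c(u = "AANA", v = "AATA"))
  expect_equal(pairwise_p_distances(b)["u", "v"], 0)
  c3 <- alignment(c(u = "ACGT", v = "ACGT"))
  expect_equal(pairwise_p_distances(c3)["u", "v"], 0)
  expect_error(pairwise_p_distances(alignment(c(u = "NNNN", v = "AAAA"))),
               "comparable")
})

test_that("p-distance matrix is a valid distance matrix in [0, 1]", {
  set.seed(7)
  seqs <- replicate(6, paste(sample(c("A", "C", "G", "T", "N", "-"), 40,
                                    TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)),
                             collapse = ""))
  d <- pairwise_p_distances(alignment(setNames(seqs, paste0("s", 1:6))))
  expect_true(all(d >= 0 & d <= 1))
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("nucleotide diversity equals the mean pairwise difference", {
  expect_equal(nucleotide_diversity(alignment(c(a = "AAAA", b = "AAAT"))), 0.25)
  expect_equal(nucleotide_diversity(
    alignment(c(a = "AAAA", b = "AAAT", c = "AATT"))), 1 / 3)
  expect_equal(nucleotide_diversity(
    alignment(setNames(rep("ACGT", 5), paste0("s", 1:5)))), 0)
  expect_error(nucleotide_diversity(alignment(c(a = "ACGT"))), "at least 2")
})

test_that("diversity is invariant to order and scales with monomorphic padding", {
  set.seed(11)
  seqs <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                      collapse = "")), paste0("s", 1:5))
  a <- alignment(seqs)
  pi0 <- nucleotide_diversity(a)
  expect_equal(nucleotide_diversity(alignment(seqs[c(4, 2, 5, 1, 3)])), pi0)
  # appending 20 identical columns halves the per-site diversity
  padded <- alignment(setNames(paste0(seqs, strrep("A", 20)), names(seqs)))
  expect_equal(nucleotide_diversity(padded), pi0 * 20 / 40)
  # column-wise counting oracle: sum over sites of per-site mismatch fraction
  code <- sapply(strsplit(unname(seqs), ""), identity)
  per_site <- apply(code, 1, function(col) {
    n <- length(col); sum(outer(col, col, "!=")[upper.tri(diag(n))]) / choose(n, 2)
  })
  expect_equal(pi0, mean(per_site))
})
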