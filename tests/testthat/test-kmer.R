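test_that("k-mer indexing is lexicographic base 4 over A<C<G<U", {
  expect_identical(nm_kmer_index("A"), 0)
  expect_identical(nm_kmer_index("CG"), 6)
  expect_identical(nm_kmer_index("UUU"), 63)
  expect_identical(nm_kmer_index(nm_kmers(2)), as.numeric(0:15))
  expect_error(nm_kmer_index("ACGU"), class = "nm_validation_error")
  expect_error(nm_kmer_index("AN"), class = "nm_validation_error")
})

test_that("frequency vector counts overlapping k-mers in canonical layout", {
  homo <- strrep("A", 41)
  fv <- nm_freq_vector(homo)
  expect_length(fv, 84)
  expect_identical(unname(fv[c("A", "C", "G", "U")]), c(41L, 0L, 0L, 0L))
  expect_identical(unname(fv["AA"]), 40L)
  expect_identical(unname(fv["AAA"]), 39L)
  expect_identical(sum(fv[5:20]), 40L)   # all other di counts zero

  acgu <- paste0(strrep("ACGU", 10), "A")
  expect_identical(unname(nm_freq_vector(acgu)[1:4]), c(11L, 10L, 10L, 10L))

  # against the substring-counting oracle on random windows
  set.seed(101)
  for (i in 1:20) {
    s <- random_window()
    for (k in 1:3) {
      block <- nm_freq_vector(s)[(4^k - 4) / 3 + seq_len(4^k)]
      expect_identical(as.integer(block), as.integer(o_freq(s, k)))
    }
  }
})

test_that("AAPIV sums 1-based start positions of every occurrence", {
  homo <- strrep("A", 41)
  aa <- nm_aapiv(homo)
  expect_identical(unname(aa[c("A", "C", "G", "U")]), c(861, 0, 0, 0))
  toy <- nm_aapiv("ACGA")
  expect_identical(unname(toy[c("A", "C", "G", "U")]), c(5, 2, 3, 0))
  set.seed(102)
  for (i in 1:20) {
    s <- random_window()
    got <- nm_aapiv(s)
    for (k in 1:3) {
      block <- got[(4^k - 4) / 3 + seq_len(4^k)]
      expect_equal(unname(block), unname(o_aapiv(s, k)))
    }
  }
})

test_that("RAAPIV is AAPIV of the reversed sequence", {
  expect_identical(unname(nm_raapiv(strrep("A", 41))["A"]), 861)
  toy <- nm_raapiv("ACGA")   # reversed: AGCA
  expect_identical(unname(toy[c("A", "C", "G", "U")]), c(5, 3, 2, 0))
  set.seed(103)
  for (i in 1:100) {
    s <- random_window()
    expect_identical(nm_raapiv(s), nm_aapiv(o_revseq(s)))
  }
})

test_that("PRIM matches the nested-loop oracle and zeroes absent rows", {
  homo <- strrep("A", 41)
  M <- nm_prim(homo, 1)
  expect_identical(unname(M["A", ]), c(820, 0, 0, 0))
  expect_true(all(M[c("C", "G", "U"), ] == 0))

  toy <- nm_prim("ACGA", 1)
  expect_identical(toy["A", "A"], 3)
  expect_identical(toy["A", "C"], 1)
  expect_identical(toy["A", "G"], 2)
  expect_identical(toy["C", "A"], 1)
  expect_true(all(toy["U", ] == 0))

  set.seed(104)
  for (i in 1:30) {
    s <- random_sequence(sample(5:41, 1))
    for (k in 1:3) {
      if (nchar(s) < k) next
      expect_identical(nm_prim(s, k), o_prim(s, k))
    }
  }
})

test_that("RPRIM is PRIM of the reversed sequence; reversal is an involution", {
  pal <- paste0(strrep("AC", 10), "G", strrep("CA", 10))  # palindrome
  for (k in 1:3) expect_identical(nm_rprim(pal, k), nm_prim(pal, k))
  expect_identical(nm_rprim("ACGA", 1), o_prim("AGCA", 1))
  set.seed(105)
  for (i in 1:100) {
    s <- random_window()
    k <- sample(1:3, 1)
    expect_identical(nm_rprim(s, k), nm_prim(o_revseq(s), k))
    # applying the reverse-direction map twice returns the forward result
    expect_identical(nm_rprim(o_revseq(s), k), nm_prim(s, k))
  }
})

test_that("block totals match their closed forms on random windows", {
  set.seed(106)
  for (i in 1:100) {
    s <- random_window()
    fv <- nm_freq_vector(s)
    expect_identical(as.integer(c(sum(fv[1:4]), sum(fv[5:20]), sum(fv[21:84]))),
                     c(41L, 40L, 39L))
    for (vec in list(nm_aapiv(s), nm_raapiv(s)))
      expect_equal(unname(c(sum(vec[1:4]), sum(vec[5:20]), sum(vec[21:84]))),
                   c(861, 820, 780))
  }
})

test_that("2-D code matrix reshapes row-major with zero padding", {
  homo <- strrep("A", 41)
  M <- nm_matrix2d(homo, 1)
  expect_identical(dim(M), c(7L, 7L))
  flat <- as.vector(t(M))
  expect_identical(flat, c(rep(1L, 41), rep(0L, 8)))

  set.seed(107)
  s <- random_window()
  for (k in 1:3) {
    M <- nm_matrix2d(s, k)
    expect_identical(dim(M), c(7L, 7L))
    flat <- as.vector(t(M))
    n_codes <- 41 - k + 1
    expect_identical(flat[seq_len(n_codes)],
                     as.integer(nm_kmer_index(o_kmer_tokens(s, k))) + 1L)
    expect_true(all(flat[-seq_len(n_codes)] == 0L))
  }
})
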