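test_that("local protein alignment matches an exhaustive DP oracle", {
  # classic small pair, expected value computed by the oracle at test time
  h <- alignProteinLocal("HEAGAWGHEE", "PAWHEAE")
  expect_equal(h$score, sw_score_oracle("HEAGAWGHEE", "PAWHEAE"))

  # no positive-scoring alignment between poly-A and poly-T "proteins"
  expect_null(alignProteinLocal("AAAA", "TTTT"))

  # property: scores equal the oracle on random pairs, and are symmetric
  set.seed(101)
  for (i in 1:30) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    ha <- alignProteinLocal(a, b)
    hb <- alignProteinLocal(b, a)
    sc <- sw_score_oracle(a, b)
    if (is.null(ha)) {
      expect_equal(sc, 0)
      expect_null(hb)
    } else {
      expect_equal(ha$score, sc)
      expect_equal(hb$score, sc)
      expect_true(ha$identities <= ha$length)
      expect_true(ha$q_end - ha$q_start <= ha$length)
    }
  }
})

test_that("self-alignment is perfect and empty input errors", {
  p <- random_protein(40)
  h <- alignProteinLocal(p, p)
  expect_equal(h$identities / h$length, 1.0)
  expect_equal(h$length, nchar(p))
  expect_error(alignProteinLocal("", "MKV"), "empty")
})

test_that("Karlin-Altschul E-values follow the defining algebra", {
  # bitscore chosen so that m * n * 2^-bits = 1
  m <- 200; n <- 1e6
  bits <- log2(m * n)
  expect_equal(evalueKA(bits, m, n), 1.0)
  # linear in database size
  b2 <- bitscoreKA(57)
  expect_equal(evalueKA(b2, m, 2 * n), 2 * evalueKA(b2, m, n))
  # direct arithmetic for score 100, gapped BLOSUM62 constants
  expected <- 200 * 1e6 * 2^(-(0.267 * 100 - log(0.041)) / log(2))
  expect_equal(evalueKA(bitscoreKA(100), 200, 1e6), expected)
})

test_that("seeded nucleotide alignment finds exact and mutated copies", {
  set.seed(202)
  g <- random_dna(2000)
  read <- substr(g, 501, 600)
  h <- alignNtLocal(read, g)
  expect_equal(h$identities[1], 100L)
  expect_equal(h$length[1], 100L)
  expect_equal(h$s_strand[1], "+")
  expect_equal(h$s_start[1], 500L)
  expect_equal(h$s_end[1], 600L)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h2 <- alignNtLocal(rc, g)
  expect_equal(h2$s_strand[1], "-")
  expect_equal(h2$identities[1], 100L)
  expect_equal(h2$s_start[1], 500L)

  # 10 planted substitutions leave exactly 90 identities (terminal
  # mismatches may be trimmed by the local alignment, matches never are)
  mut <- mutate_dna(read, 10)
  h3 <- alignNtLocal(mut, g)
  expect_equal(h3$identities[1], 90L)
  expect_lte(h3$length[1], 100L)
})

test_that("nucleotide self-alignment always spans the sequence", {
  set.seed(17)
  for (len in c(11, 25, 80, 300)) {
    x <- random_dna(len)
    h <- alignNtLocal(x, x)
    expect_gte(nrow(h), 1L)
    expect_equal(h$identities[1], len)
    expect_equal(h$identities[1] / h$length[1], 1.0)
  }
})

test_that("all-vs-all search respects thresholds and self-pair rules", {
  set.seed(303)
  p1 <- random_protein(120)
  p2 <- mutate_protein(p1, 30)  # clear homolog
  p3 <- random_protein(110)

  # a single protein against itself: self-pairs are excluded
  expect_equal(nrow(allVsAllProteins(c(x = p1))), 0L)

  # identical proteins across two sets are retained with identity 1
  h <- allVsAllProteins(c(a = p1), c(b = p1))
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)

  # self-mode table is symmetric: both orientations of each pair present
  hs <- allVsAllProteins(c(a = p1, b = p2, c = p3))
  key <- paste(hs$query_id, hs$subject_id)
  expect_true(all(paste(hs$subject_id, hs$query_id) %in% key))

  # the emitted pairs agree with direct per-pair alignment + thresholds
  n_db <- sum(nchar(c(p1, p2, p3)))
  direct <- alignProteinLocal(p1, p2, n_db = n_db)
  pass <- direct$evalue <= 1e-3 && direct$identities / direct$length >= 0.25
  expect_equal("a b" %in% key, pass)
  expect_equal(hs[key == "a b", "score"], direct$score)
})
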