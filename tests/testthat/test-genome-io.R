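test_that("FASTA reading parses IDs, uppercases, and round-trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "acgt"), f)
  gs <- readGenomeFasta(f)
  expect_s4_class(gs, "GenomeSet")
  expect_equal(names(gs), "g1")
  expect_equal(genomeSeqs(gs, "g1"), "ACGT")

  # round-trip with multiple records and long sequences (70-col wrapping)
  set.seed(11)
  seqs <- c(a1 = random_dna(500), b2 = random_dna(71), c3 = "ACGTN")
  out <- tempfile(fileext = ".fasta")
  writeGenomeFasta(GenomeSet(seqs), out)
  back <- readGenomeFasta(out)
  expect_equal(names(back), names(seqs))
  expect_equal(unname(as.character(genomeSeqs(back))), unname(seqs))
})

test_that("FASTA reading rejects bad input with informative errors", {
  f <- tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(readGenomeFasta(f), "empty")

  writeLines(c(">g1", "ACGT", ">g1", "ACGT"), f)
  expect_error(readGenomeFasta(f), "g1")

  writeLines(c(">g1", "ACGU"), f)
  expect_error(readGenomeFasta(f), "position 4")
})

test_that("GenomeSet validates IDs, topology and alphabet", {
  expect_error(GenomeSet(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(GenomeSet(c("ACGT")), "named")
  expect_error(GenomeSet(c(`bad id` = "ACGT")), "whitespace")
  expect_error(GenomeSet(c(a = "ACGT"), topology = "moebius"), "topology")
  gs <- GenomeSet(c(a = "acgtn"), topology = "circular", source = "MVG")
  expect_equal(genomeSeqs(gs, "a"), "ACGTN")
  expect_equal(unname(topology(gs)), "circular")
  expect_equal(unname(genomeSource(gs)), "MVG")
  expect_equal(unname(genomeLengths(gs)), 5L)
})

test_that("gcContent follows the (G+C)/(A+C+G+T) definition", {
  expect_equal(unname(gcContent("ATGC")), 0.5)
  expect_equal(unname(gcContent("GGCC")), 1.0)
  # N excluded from numerator and denominator
  expect_equal(unname(gcContent("ATGCNNNN")), 0.5)
  expect_error(gcContent("NNNN"), "undefined")
  # invariant under reverse complement
  set.seed(5)
  for (i in 1:10) {
    s <- random_dna(200, gc = runif(1, 0.2, 0.8))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(unname(gcContent(s)), unname(gcContent(rc)))
  }
})

test_that("GenBank CDS counting and sequence extraction work on fixtures", {
  f <- tempfile(fileext = ".gb")
  set.seed(21)
  seq <- random_dna(300)
  write_genbank_fixture(f, id = "SYN1", seq = seq, n_cds = 3)
  expect_equal(countGenbankCDS(f), 3L)
  gb <- readGenbankGenome(f)
  expect_equal(names(gb), "SYN1")
  expect_equal(genomeSeqs(gb, "SYN1"), seq)
  expect_equal(unname(topology(gb)), "circular")

  write_genbank_fixture(f, id = "SYN0", n_cds = 0)
  expect_equal(countGenbankCDS(f), 0L)

  writeLines(c("this is", "not genbank"), f)
  expect_error(countGenbankCDS(f), "LOCUS")
})

test_that("extractSubseq honors 0-based half-open coords and wrapping", {
  gs <- GenomeSet(c(g = "ACGTAC"), topology = "circular")
  expect_equal(extractSubseq(gs, "g", 4, 8, "+"), "ACAC")
  lin <- GenomeSet(c(g = "ACGT"), topology = "linear")
  expect_equal(extractSubseq(lin, "g", 0, 4, "-"), "ACGT")  # palindrome
  expect_error(extractSubseq(lin, "g", 2, 6, "+"), "linear")
  # full-length extraction is the sequence itself
  set.seed(3)
  s <- random_dna(40)
  gl <- GenomeSet(c(x = s))
  expect_equal(extractSubseq(gl, "x", 0, 40, "+"), s)
  # wrap then reverse complement is consistent with manual construction
  gc2 <- GenomeSet(c(y = "AACCGGTT"), topology = "circular")
  fwd <- extractSubseq(gc2, "y", 6, 10, "+")
  expect_equal(fwd, "TTAA")
  expect_equal(extractSubseq(gc2, "y", 6, 10, "-"), "TTAA")
})

test_that("virome reads load from FASTA and FASTQ, gzipped or plain", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGTACGT", ">r2", "GGGG"), fa)
  r <- readViromeReads(fa)
  expect_equal(length(r), 2L)
  expect_equal(as.character(r[["r2"]]), "GGGG")

  fq <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(fq, "w")
  writeLines(c("@r1 desc", "ACGTAC", "+", "IIIIII"), con)
  close(con)
  r2 <- readViromeReads(fq)
  expect_equal(names(r2), "r1")
  expect_equal(as.character(r2[[1]]), "ACGTAC")
})
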