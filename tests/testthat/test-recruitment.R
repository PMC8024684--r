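test_that("read length filter is inclusive at the threshold", {
  reads <- c(r1 = strrep("A", 49), r2 = strrep("C", 50),
             r3 = strrep("G", 120))
  kept <- filterReads(reads)
  expect_equal(names(kept), c("r2", "r3"))
  expect_equal(length(filterReads(character(0))), 0L)
  # order preserved
  expect_equal(names(filterReads(reads, 10)), names(reads))
})

test_that("single-read recruitment enforces identity and coverage", {
  set.seed(555)
  panel <- GenomeSet(c(g1 = random_dna(3000), g2 = random_dna(3000)))
  read <- substr(genomeSeqs(panel, "g1"), 1001, 1100)
  hit <- recruitRead(read, panel)
  expect_equal(hit$genome_id, "g1")
  expect_equal(hit$identities / hit$length, 1.0)
  expect_equal(hit$q_end - hit$q_start, 100L)

  # 31 mismatches push identity to 0.69 < 0.70
  expect_null(recruitRead(mutate_dna(read, 31), panel))

  # only 89 of 100 read bases align: coverage 0.89 < 0.90; the tail is
  # chosen to mismatch the genome continuation at every position so the
  # alignment cannot extend past it
  cont <- strsplit(substr(genomeSeqs(panel, "g1"), 1090, 1100), "")[[1]]
  tail_nt <- vapply(cont, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  chimeric <- paste0(substr(read, 1, 89), paste(tail_nt, collapse = ""))
  h89 <- alignNtLocal(chimeric, genomeSeqs(panel, "g1"))
  expect_lt((h89$q_end[1] - h89$q_start[1]) / 100, 0.90)
  expect_null(recruitRead(chimeric, panel))
})

test_that("breadth of coverage is an interval union, unwrapping circles", {
  expect_equal(breadthOfCoverage(2000, integer(0), integer(0)), 0)
  expect_equal(breadthOfCoverage(1000, 0, 1000), 1.0)
  expect_equal(breadthOfCoverage(2000, c(0, 400), c(600, 1000)), 0.5)
  # wrap: [1900, 2100) on a 2000-bp circle covers 100 + 100 bases
  expect_equal(breadthOfCoverage(2000, 1900, 2100), 0.1)
  # overlapping wrap and head intervals are not double counted
  expect_equal(breadthOfCoverage(2000, c(1900, 0), c(2100, 150)), 0.125)
})

test_that("KPKG normalization follows its defining arithmetic", {
  expect_equal(kpkg(10, 34774, 1e7), 10 / 34.774 / 0.01, tolerance = 1e-9)
  expect_equal(round(kpkg(10, 34774, 1e7), 2), 28.76)
  expect_equal(kpkg(0, 34774, 1e7), 0)
  # doubling the metagenome halves KPKG
  expect_equal(kpkg(5, 30000, 2e8), kpkg(5, 30000, 1e8) / 2)
  expect_error(kpkg(1, 1000, 0), "positive")
})

test_that("panel profiling recovers a planted single-genome community", {
  set.seed(666)
  panel <- GenomeSet(c(gA = random_dna(8000), gB = random_dna(8000)),
                     topology = "circular")
  sim <- simulateVirome(panel, c(gA = 1, gB = 0), n_reads = 600,
                        read_len = 100, error_rate = 0, seed = 9,
                        virome_id = "mono")
  se <- profilePanel(list(mono = list(reads = sim$reads,
                                      total_bases = sim$stats$total_bases)),
                     panel)
  a <- SummarizedExperiment::assays(se)
  expect_gt(a$breadth["gA", "mono"], 0.95)
  expect_gt(a$kpkg["gA", "mono"], 0)
  expect_equal(a$kpkg["gB", "mono"], 0)
  expect_equal(a$breadth["gB", "mono"], 0)

  # each read contributes to at most one genome
  total_read_kb <- sum(nchar(filterReads(sim$reads))) / 1000
  expect_lte(sum(a$recruited_kb[, "mono"]), total_read_kb)

  # KPKG is invariant under duplicating the virome
  dup <- c(sim$reads, stats::setNames(sim$reads,
                                      paste0(names(sim$reads), "_d")))
  se2 <- profilePanel(list(mono = list(reads = dup,
                                       total_bases = 2 * sim$stats$total_bases)),
                      panel)
  a2 <- SummarizedExperiment::assays(se2)
  expect_equal(a2$kpkg["gA", "mono"], a$kpkg["gA", "mono"], tolerance = 1e-9)
})

test_that("pure background viromes recruit nothing", {
  set.seed(777)
  panel <- GenomeSet(c(gA = random_dna(6000)), topology = "circular")
  bg <- simulateVirome(panel, c(gA = 1), n_reads = 300, read_len = 100,
                       error_rate = 0, background_fraction = 0.999999,
                       seed = 10, virome_id = "bg")
  # force pure background: regenerate until no panel read (tiny prob)
  expect_true(sum(bg$truth$source_counts) <= 1)
  se <- profilePanel(list(bg = list(reads = bg$reads,
                                    total_bases = bg$stats$total_bases)),
                     panel)
  expect_equal(sum(SummarizedExperiment::assays(se)$kpkg), 0)
})

test_that("low-breadth genomes report zero KPKG but positive raw KPKG", {
  fx <- recruitment_fixture()
  a <- SummarizedExperiment::assays(fx$se)
  g <- fx$rs$sparse_genome; v <- fx$rs$sparse_virome
  expect_lt(a$breadth[g, v], 0.40)
  expect_gt(a$kpkg_raw[g, v], 0)
  expect_equal(a$kpkg[g, v], 0)
})

test_that("KPKG ranks recover planted abundances across the grid", {
  fx <- recruitment_fixture()
  a <- SummarizedExperiment::assays(fx$se)
  mix <- colnames(fx$rs$abundances)
  k <- as.vector(a$kpkg[rownames(fx$rs$abundances), mix])
  tr <- as.vector(fx$rs$abundances)
  expect_gte(cor(k, tr, method = "spearman"), 0.9)
})

test_that("recruitment tables are written in long and wide form", {
  fx <- recruitment_fixture()
  lf <- tempfile(fileext = ".tsv"); wf <- tempfile(fileext = ".tsv")
  writeRecruitmentTsv(fx$se, long_path = lf, wide_path = wf)
  long <- read.table(lf, sep = "\t", header = TRUE)
  expect_equal(nrow(long), nrow(fx$se) * ncol(fx$se))
  wide <- read.table(wf, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(wide$genome_id, rownames(fx$se))
  a <- SummarizedExperiment::assays(fx$se)
  expect_equal(unname(as.matrix(wide[, -1])), unname(a$kpkg))
})
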