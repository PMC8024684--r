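revcomp_str <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("minimal ORF is called with exact coordinates and translation", {
  gs <- GenomeSet(c(g = "TAAATGAAATAA"))
  orfs <- callOrfs(gs, min_aa = 2)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$start, 3L)
  expect_equal(orfs$end, 12L)
  expect_equal(orfs$strand, "+")

  # the reverse complement carries the same single ORF on the minus strand
  rc <- GenomeSet(c(g = revcomp_str("TAAATGAAATAA")))
  orfs_rc <- callOrfs(rc, min_aa = 2)
  expect_equal(nrow(orfs_rc), 1L)
  expect_equal(orfs_rc$protein, "MK")
  expect_equal(orfs_rc$strand, "-")
  expect_equal(orfs_rc$start, 0L)
  expect_equal(orfs_rc$end, 9L)
})

test_that("calling mirrors under reverse complement and rotates on circles", {
  ref <- makeReferenceGenome(31, length = 6000, n_genes = 8, id = "S")
  s <- genomeSeqs(ref$genome, "S")
  L <- nchar(s)
  fw <- callOrfs(GenomeSet(c(S = s), topology = "circular"))
  rv <- callOrfs(GenomeSet(c(S = revcomp_str(s)), topology = "circular"))
  # mirror: interval [a,b) on + maps to [L-b, L-a) on -, modulo rotation
  key_f <- sort(paste((fw$start) %% L, (fw$end - fw$start), fw$strand))
  mir_start <- (L - rv$end) %% L
  key_r <- sort(paste(mir_start, rv$end - rv$start,
                      ifelse(rv$strand == "+", "-", "+")))
  expect_equal(key_f, key_r)

  # rotation invariance up to coordinate shift
  k <- 1234L
  rot <- paste0(substr(s, k + 1, L), substr(s, 1, k))
  ro <- callOrfs(GenomeSet(c(S = rot), topology = "circular"))
  key_rot <- sort(paste((ro$start + k) %% L, ro$end - ro$start, ro$strand))
  expect_equal(key_f, key_rot)
})

test_that("planted genes are recovered exactly, and proteins retranslate", {
  ref <- makeReferenceGenome(42)
  called <- callOrfs(ref$genome, min_aa = 30)
  key <- function(df) paste(df$start, df$end, df$strand)
  expect_true(all(key(ref$genes) %in% key(called)))
  m <- merge(ref$genes, called, by = c("start", "end", "strand"))
  expect_equal(nrow(m), nrow(ref$genes))
  expect_equal(m$protein.x, m$protein.y)

  # every called protein retranslates from its coordinates
  idx <- seq(1, nrow(called), by = 17)  # a spread of calls, both strands
  code11 <- Biostrings::getGeneticCode("11")
  for (i in idx) {
    nt <- extractSubseq(ref$genome, "REF", called$start[i], called$end[i],
                        called$strand[i])
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(nt, 1, nchar(nt) - 3)),
      genetic.code = code11, no.init.codon = TRUE))
    aa <- paste0("M", substr(aa, 2, nchar(aa)))
    expect_equal(aa, called$protein[i])
  }
})

test_that("annotation applies E-value, identity and coverage thresholds", {
  set.seed(77)
  p <- random_protein(200)
  gene <- data.frame(genome_id = "g", gene_index = 1L, start = 0L,
                     end = 603L, strand = "+", length_aa = 200L,
                     protein = p, protein_id = "g_1",
                     stringsAsFactors = FALSE)
  # identical reference: full-identity, full-coverage annotation
  ann <- annotateGenes(gene, c("refA exact match" = p))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$identity, 1.0)
  expect_equal(ann$coverage, 1.0)
  expect_equal(ann$subject_id, "refA")
  expect_equal(ann$label, "exact match")
  expect_lte(ann$evalue, 1e-3)

  # reference covering 99/200 residues: coverage 0.495 < 0.50, rejected
  ann99 <- annotateGenes(gene, c(ref99 = substr(p, 1, 99)))
  expect_equal(nrow(ann99), 0L)
  ann100 <- annotateGenes(gene, c(ref100 = substr(p, 1, 100)))
  expect_equal(nrow(ann100), 1L)
  expect_equal(ann100$coverage, 0.5)

  # identity threshold: a diverged homolog annotates only when id_min
  # is below its measured identity
  hom <- mutate_protein(p, 120)
  h <- alignProteinLocal(p, hom)
  measured <- h$identities / h$length
  expect_lt(measured, 0.6)
  ann_lo <- annotateGenes(gene, c(hom = hom), id_min = measured + 0.05)
  expect_equal(nrow(ann_lo), 0L)
  ann_hi <- annotateGenes(gene, c(hom = hom), id_min = measured - 0.05)
  expect_equal(nrow(ann_hi), 1L)

  # best-scoring hit wins when several pass
  ann_best <- annotateGenes(gene, c(weak = mutate_protein(p, 60),
                                    exact = p))
  expect_equal(ann_best$subject_id, "exact")
})

test_that("gene outputs round-trip through FASTA and TSV", {
  ref <- makeReferenceGenome(55, length = 6000, n_genes = 6, id = "W")
  genes <- callOrfs(ref$genome)
  faa <- tempfile(fileext = ".faa")
  tsv <- tempfile(fileext = ".tsv")
  writeGeneOutputs(genes, faa_path = faa, tsv_path = tsv)
  aa <- Biostrings::readAAStringSet(faa)
  expect_equal(names(aa), genes$protein_id)
  expect_equal(unname(as.character(aa)), genes$protein)
  tab <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(tab), nrow(genes))
  expect_equal(tab$start, genes$start)
})
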