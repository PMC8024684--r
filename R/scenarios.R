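#' Default synthetic study scenario: a reference and a 12-genome panel
#'
#' Generates the package's standard planted-truth scenario: a ~35-kb
#' circular reference genome with 55 genes, eleven related genomes at
#' nucleotide divergence 0.05 with gene retentions between 0.75 and 1.0
#' (subgroup I; 42-55 retained genes, mirroring the gene-count spread of
#' real environmental relatives), and one distant genome at divergence
#' 0.25 retaining 45% of the genes (subgroup II). The marker gene (the
#' longest planted gene, standing in for the universally retained
#' terminase large subunit) is never removed.
#'
#' @param seed master RNG seed; all child seeds derive from it.
#' @param length,n_genes,gc reference genome parameters.
#' @param div1,div2 nucleotide divergence of subgroups I and II.
#' @param retentions1 gene retentions of the eleven subgroup I genomes.
#' @param retention2 gene retention of the subgroup II genome.
#' @return list: `reference` ([makeReferenceGenome()] output), `panel`
#'   ([GenomeSet-class] of the 12 derived genomes), `truth` (data.frame
#'   with `genome_id`, `subgroup`, `nt_divergence`, `gene_retention`,
#'   `n_retained`), `marker_index` (reference gene index of the marker),
#'   `evolved` (per-genome truth lists).
#' @export
makeStudyScenario <- function(seed = 1L, length = 35000L, n_genes = 55L,
                              gc = 0.40, div1 = 0.05, div2 = 0.25,
                              retentions1 = c(1.00, 0.95, 0.95, 0.90, 0.90,
                                              0.88, 0.85, 0.85, 0.80, 0.78,
                                              0.75),
                              retention2 = 0.45) {
  ref <- makeReferenceGenome(child_seed(seed, 0L), length = length,
                             n_genes = n_genes, gc = gc, id = "REF")
  marker_index <- if (nrow(ref$genes))
    ref$genes$gene_index[order(-ref$genes$length_aa,
                               ref$genes$gene_index)][1L] else NA_integer_
  n1 <- base::length(retentions1)
  divs <- c(rep(div1, n1), div2)
  rets <- c(retentions1, retention2)
  ids <- sprintf("MVG%02d", seq_len(n1 + 1L))
  evolved <- lapply(seq_along(ids), function(i)
    evolveGenome(ref, nt_divergence = divs[i], gene_retention = rets[i],
                 seed = child_seed(seed, i), id = ids[i],
                 keep = marker_index))
  panel <- Reduce(combineGenomes, lapply(evolved, `[[`, "genome"))
  truth <- data.frame(
    genome_id = ids,
    subgroup = c(rep("I", n1), "II"),
    nt_divergence = divs,
    gene_retention = rets,
    n_retained = vapply(evolved, function(e) base::length(e$truth$retained),
                        integer(1)),
    stringsAsFactors = FALSE)
  list(reference = ref, panel = panel, truth = truth,
       marker_index = marker_index, evolved = evolved, seed = seed)
}

#' Synthetic recruitment grid: 5 genomes x 4 viromes with planted
#' abundances
#'
#' Five mutually unrelated ~35-kb genomes and four simulated viromes: three
#' mixture viromes with distinct planted abundance profiles (minimum panel
#' share 0.08, 10% unrelated background, 3000 reads of 100 bp at 1%
#' error), and one "sparse" virome in which a single genome receives ~2%
#' of the reads against 98% background, planting a breadth of coverage
#' below the 40% reporting threshold while still recruiting reads.
#'
#' @param seed master RNG seed.
#' @param n_reads reads per virome.
#' @param read_len read length in bp.
#' @param error_rate per-base error rate.
#' @return list: `panel` ([GenomeSet-class] of 5), `viromes` (named list of
#'   `list(reads, total_bases)`), `abundances` (genomes x viromes matrix of
#'   planted panel-relative abundances), `sparse_virome`, `sparse_genome`.
#' @export
makeRecruitmentScenario <- function(seed = 1L, n_reads = 3000L,
                                    read_len = 100L, error_rate = 0.01) {
  gids <- sprintf("G%d", 1:5)
  gens <- lapply(seq_along(gids), function(i)
    makeReferenceGenome(child_seed(seed, 100L + i), id = gids[i]))
  panel <- Reduce(combineGenomes, lapply(gens, `[[`, "genome"))
  ab <- cbind(v1 = c(0.35, 0.25, 0.18, 0.12, 0.10),
              v2 = c(0.10, 0.12, 0.18, 0.25, 0.35),
              v3 = c(0.22, 0.30, 0.08, 0.28, 0.12))
  rownames(ab) <- gids
  viromes <- list()
  for (v in colnames(ab)) {
    sim <- simulateVirome(panel, ab[, v], n_reads = n_reads,
                          read_len = read_len, error_rate = error_rate,
                          background_fraction = 0.10,
                          seed = child_seed(seed, 200L + match(v, colnames(ab))),
                          virome_id = v)
    viromes[[v]] <- list(reads = sim$reads,
                         total_bases = sim$stats$total_bases)
  }
  sparse <- simulateVirome(panel, c(1, 0, 0, 0, 0), n_reads = n_reads,
                           read_len = read_len, error_rate = error_rate,
                           background_fraction = 0.98,
                           seed = child_seed(seed, 300L),
                           virome_id = "v_sparse")
  viromes[["v_sparse"]] <- list(reads = sparse$reads,
                                total_bases = sparse$stats$total_bases)
  list(panel = panel, viromes = viromes, abundances = ab,
       sparse_virome = "v_sparse", sparse_genome = "G1", seed = seed)
}
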