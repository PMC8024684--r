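# Shared planted-truth scenarios, built once per test run and memoized.
# The seed is fixed so every expectation refers to the same realization.

.scenario_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.scenario_cache$study)) return(.scenario_cache$study)
  sc <- makeStudyScenario(seed = 101)
  genes_panel <- callOrfs(sc$panel)
  rg <- sc$reference$genes
  rg$genome_id <- names(sc$reference$genome)
  genes <- rbind(rg[, names(genes_panel)], genes_panel)
  prot <- stats::setNames(genes$protein, genes$protein_id)
  hits <- allVsAllProteins(prot)
  groups <- buildOrthogroups(hits, genes$protein_id)
  gmap <- stats::setNames(genes$genome_id, genes$protein_id)
  frac <- vapply(names(sc$panel), function(cid)
    sharedGeneFraction("REF", cid, groups, gene_genomes = gmap), numeric(1))
  decisions <- classifyMvg(names(sc$panel), genomeLengths(sc$panel), frac)
  D <- genomeDistanceMatrix(genes)
  marker_pid <- paste0("REF_", sc$marker_index)
  memb <- orthogroupMembership(groups)
  mg <- genes[genes$protein_id %in% groups[[memb[[marker_pid]]]], ,
              drop = FALSE]
  mg <- mg[order(-mg$length_aa, mg$protein_id), , drop = FALSE]
  mg <- mg[!duplicated(mg$genome_id), , drop = FALSE]
  markers <- stats::setNames(mg$protein, mg$genome_id)
  out <- list(sc = sc, genes = genes, hits = hits, groups = groups,
              gmap = gmap, frac = frac, decisions = decisions, D = D,
              markers = markers)
  .scenario_cache$study <- out
  out
}

recruitment_fixture <- function() {
  if (!is.null(.scenario_cache$recruit)) return(.scenario_cache$recruit)
  rs <- makeRecruitmentScenario(seed = 101)
  se <- profilePanel(rs$viromes, rs$panel)
  out <- list(rs = rs, se = se)
  .scenario_cache$recruit <- out
  out
}
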