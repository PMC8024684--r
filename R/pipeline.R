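#' Default pipeline configuration
#'
#' Nested list of every tunable of the pipeline, with thresholds at the
#' study defaults: annotation E <= 1e-3, identity >= 0.25, coverage >=
#' 0.50; membership shared-gene fraction >= 0.40 and length >= 25 kb;
#' dereplication at 70% ANI; reads >= 50 bp recruited at >= 70% identity
#' and >= 90% read coverage; KPKG zeroed below 40% breadth.
#'
#' @param outdir output directory for pipeline artifacts.
#' @param seed master seed for the simulate stage.
#' @return Nested configuration list (see sections `simulate`,
#'   `thresholds`, `tree`, `inputs`).
#' @export
defaultPipelineConfig <- function(outdir = "pipeline_out", seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    inputs = list(
      reference_fasta = NULL,  # defaults to files under outdir
      panel_fasta = NULL,
      viromes_tsv = NULL),
    simulate = list(
      length = 35000L, n_genes = 55L, gc = 0.40,
      div1 = 0.05, div2 = 0.25, retention2 = 0.45,
      retentions1 = c(1.00, 0.95, 0.95, 0.90, 0.90, 0.88, 0.85, 0.85,
                      0.80, 0.78, 0.75),
      n_reads = 2000L, read_len = 100L, error_rate = 0.01,
      background_fraction = 0.10, n_viromes = 3L),
    thresholds = list(
      e_max = 1e-3, id_min = 0.25, cov_min = 0.50,
      min_shared_fraction = 0.40, min_len = 25000L,
      ani_threshold = 0.70, frag_len = 1000L,
      read_min_len = 50L, read_id_min = 0.70, read_cov_min = 0.90,
      breadth_min = 0.40, inflation = 1.5, min_aa = 30L,
      word_size = 4L),
    tree = list(marker = "auto", bootstrap_reps = 0L,
                genus_threshold = 0.6, subfamily_threshold = 0.9))
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented range; stops with an
#' informative message on the first violation.
#'
#' @param config configuration list as from [defaultPipelineConfig()].
#' @return `config`, invisibly, when valid.
#' @export
validatePipelineConfig <- function(config) {
  th <- config$thresholds
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid config: ", msg)
  chk(is.character(config$outdir) && nzchar(config$outdir),
      "outdir must be a non-empty path")
  frac <- c("id_min", "cov_min", "min_shared_fraction", "ani_threshold",
            "read_id_min", "read_cov_min", "breadth_min")
  for (f in frac)
    chk(is.numeric(th[[f]]) && th[[f]] >= 0 && th[[f]] <= 1,
        sprintf("%s must be in [0,1]", f))
  chk(th$e_max > 0, "e_max must be positive")
  chk(th$min_len >= 0, "min_len must be non-negative")
  chk(th$frag_len >= 100, "frag_len must be at least 100")
  chk(th$read_min_len >= 1, "read_min_len must be at least 1")
  chk(th$inflation > 1, "inflation must exceed 1")
  chk(th$min_aa >= 1, "min_aa must be at least 1")
  chk(config$tree$genus_threshold >= 0 && config$tree$genus_threshold <= 1,
      "genus_threshold must be in [0,1]")
  chk(config$tree$subfamily_threshold >= 0 &&
        config$tree$subfamily_threshold <= 1,
      "subfamily_threshold must be in [0,1]")
  invisible(config)
}

#' Read a pipeline configuration file
#'
#' YAML file with the sections of [defaultPipelineConfig()]; keys omitted
#' from the file keep their defaults.
#'
#' @param path YAML config path.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(defaultPipelineConfig(), user)
  validatePipelineConfig(config)
  config
}

.p <- function(config, ...) file.path(config$outdir, ...)

.need <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("missing input for stage '%s': %s", stage, path))
  path
}

.write_manifest <- function(config) {
  inputs <- c(reference = .p(config, "reference.fasta"),
              panel = .p(config, "panel.fasta"))
  sums <- lapply(inputs[file.exists(inputs)], function(f)
    unname(tools::md5sum(f)))
  yaml::write_yaml(
    list(package = "mvgkit",
         version = as.character(utils::packageVersion("mvgkit")),
         seed = config$seed, config = config, input_md5 = sums),
    .p(config, "manifest.yaml"))
}

.read_genes_tsv <- function(config, stage) {
  genes <- utils::read.table(.need(.p(config, "genes.tsv"), stage),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  faa <- Biostrings::readAAStringSet(.need(.p(config, "proteins.faa"),
                                           stage))
  genes$protein <- as.character(faa)[genes$protein_id]
  genes
}

.read_panel <- function(config, stage) {
  ref <- readGenomeFasta(.need(.p(config, "reference.fasta"), stage),
                         topology = "circular", source = "isolate")
  panel <- readGenomeFasta(.need(.p(config, "panel.fasta"), stage),
                           topology = "circular", source = "MVG")
  combineGenomes(ref, panel)
}

.st_simulate <- function(config) {
  sim <- config$simulate
  sc <- makeStudyScenario(seed = config$seed, length = sim$length,
                          n_genes = sim$n_genes, gc = sim$gc,
                          div1 = sim$div1, div2 = sim$div2,
                          retentions1 = sim$retentions1,
                          retention2 = sim$retention2)
  writeGenomeFasta(sc$reference$genome, .p(config, "reference.fasta"))
  writeGenomeFasta(sc$panel, .p(config, "panel.fasta"))
  # curated reference annotation (the analysis queries the reference's
  # annotated gene set, not a six-frame re-calling of it)
  rg <- sc$reference$genes
  rg$genome_id <- names(sc$reference$genome)
  utils::write.table(rg[, c("genome_id", "gene_index", "start", "end",
                            "strand", "length_aa", "protein_id")],
                     .p(config, "reference_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGeneOutputs(rg, faa_path = .p(config, "reference_proteins.faa"))
  utils::write.table(sc$truth, .p(config, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir.create(.p(config, "viromes"), showWarnings = FALSE)
  k <- min(5L, length(sc$panel))
  srcs <- names(sc$panel)[seq_len(k)]
  vrows <- list()
  for (v in seq_len(sim$n_viromes)) {
    ab <- 2^-(seq_len(k))
    ab <- ab[((seq_len(k) + v - 2L) %% k) + 1L]  # rotate profile per virome
    ab <- ab / sum(ab)
    abund <- stats::setNames(rep(0, length(sc$panel)), names(sc$panel))
    abund[srcs] <- ab
    vid <- sprintf("virome%02d", v)
    svr <- simulateVirome(sc$panel, abund, n_reads = sim$n_reads,
                          read_len = sim$read_len,
                          error_rate = sim$error_rate,
                          background_fraction = sim$background_fraction,
                          seed = child_seed(config$seed, 400L + v),
                          virome_id = vid)
    fp <- .p(config, "viromes", paste0(vid, ".fasta"))
    writeGenomeFasta(svr$reads, fp)
    vrows[[v]] <- data.frame(virome_id = vid, path = fp,
                             total_bases = svr$stats$total_bases)
  }
  utils::write.table(do.call(rbind, vrows), .p(config, "viromes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(TRUE)
}

.st_annotate <- function(config) {
  gs <- .read_panel(config, "annotate")
  ref_id <- names(gs)[1L]
  contigs <- gs[setdiff(names(gs), ref_id)]
  genes <- callOrfs(contigs, min_aa = config$thresholds$min_aa)
  # the reference contributes its curated annotation when one exists
  # (mirrors querying a deposited genome record); otherwise it is called
  # ab initio like the contigs
  rg_tsv <- .p(config, "reference_genes.tsv")
  rg_faa <- .p(config, "reference_proteins.faa")
  if (file.exists(rg_tsv) && file.exists(rg_faa)) {
    rg <- utils::read.table(rg_tsv, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    faa <- Biostrings::readAAStringSet(rg_faa)
    rg$protein <- as.character(faa)[rg$protein_id]
  } else {
    rg <- callOrfs(gs[ref_id], min_aa = config$thresholds$min_aa)
  }
  genes <- rbind(rg[, names(genes)], genes)
  writeGeneOutputs(genes, faa_path = .p(config, "proteins.faa"))
  utils::write.table(genes[, c("genome_id", "gene_index", "start", "end",
                               "strand", "length_aa", "protein_id")],
                     .p(config, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(TRUE)
}

.st_group <- function(config) {
  th <- config$thresholds
  genes <- .read_genes_tsv(config, "group")
  gs <- .read_panel(config, "group")
  ref_id <- names(readGenomeFasta(.p(config, "reference.fasta")))[1L]
  prot <- stats::setNames(genes$protein, genes$protein_id)
  hits <- allVsAllProteins(prot, e_max = th$e_max, id_min = th$id_min,
                           word_size = th$word_size)
  groups <- buildOrthogroups(hits, genes$protein_id,
                             inflation = th$inflation)
  gmap <- stats::setNames(genes$genome_id, genes$protein_id)
  contigs <- setdiff(unique(genes$genome_id), ref_id)
  frac <- vapply(contigs, function(cid)
    sharedGeneFraction(ref_id, cid, groups, gene_genomes = gmap),
    numeric(1))
  dec <- classifyMvg(contigs, genomeLengths(gs)[contigs], frac,
                     min_fraction = th$min_shared_fraction,
                     min_len = th$min_len)
  writeGroupingOutputs(groups = groups, decisions = dec,
                       dir = config$outdir)
  invisible(TRUE)
}

.read_decisions <- function(config, stage) {
  utils::read.table(.need(.p(config, "membership.tsv"), stage), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

.st_dereplicate <- function(config) {
  th <- config$thresholds
  gs <- .read_panel(config, "dereplicate")
  dec <- .read_decisions(config, "dereplicate")
  members <- dec$contig_id[dec$is_member]
  keep <- gs[c(names(gs)[1L], members)]  # reference + member contigs
  ani <- aniMatrix(keep[members], frag_len = th$frag_len)
  reps <- dereplicateGenomes(keep[members], ani_threshold = th$ani_threshold,
                             ani = ani)
  writeGroupingOutputs(ani = ani, reps = reps, dir = config$outdir)
  invisible(TRUE)
}

.st_tree <- function(config) {
  genes <- .read_genes_tsv(config, "tree")
  dec <- .read_decisions(config, "tree")
  ref_id <- names(readGenomeFasta(.p(config, "reference.fasta")))[1L]
  keep_ids <- c(ref_id, dec$contig_id[dec$is_member])
  genes <- genes[genes$genome_id %in% keep_ids, , drop = FALSE]
  # marker: designated reference protein, or the longest reference gene
  marker_pid <- config$tree$marker
  refg <- genes[genes$genome_id == ref_id, , drop = FALSE]
  if (identical(marker_pid, "auto"))
    marker_pid <- refg$protein_id[order(-refg$length_aa,
                                        refg$gene_index)][1L]
  groups_df <- utils::read.table(.need(.p(config, "orthogroups.tsv"),
                                       "tree"), sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
  groups <- strsplit(groups_df$members, ",", fixed = TRUE)
  names(groups) <- groups_df$group_id
  marker_group <- groups[[which(vapply(groups, function(g)
    marker_pid %in% g, logical(1)))[1L]]]
  mg <- genes[genes$protein_id %in% marker_group, , drop = FALSE]
  mg <- mg[order(-mg$length_aa, mg$protein_id), , drop = FALSE]
  mg <- mg[!duplicated(mg$genome_id), , drop = FALSE]  # longest per genome
  markers <- stats::setNames(mg$protein, mg$genome_id)
  if (length(markers) >= 4L && config$tree$bootstrap_reps > 0L) {
    mt <- bootstrapMarkerTree(markers,
                              n_reps = config$tree$bootstrap_reps,
                              seed = child_seed(config$seed, 500L))
  } else if (length(markers) >= 3L) {
    mt <- markerTree(markers)
  } else {
    mt <- NULL
  }
  if (!is.null(mt)) ape::write.tree(mt, .p(config, "marker.nwk"))
  D <- genomeDistanceMatrix(genes, word_size = config$thresholds$word_size)
  if (nrow(D) >= 3L)
    ape::write.tree(neighborJoining(D), .p(config, "genome.nwk"))
  part <- rbind(rankPartition(D, config$tree$genus_threshold, "genus"),
                rankPartition(D, config$tree$subfamily_threshold,
                              "subfamily"))
  utils::write.table(part, .p(config, "partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(TRUE)
}

.st_recruit <- function(config) {
  th <- config$thresholds
  gs <- .read_panel(config, "recruit")
  reps <- readLines(.need(.p(config, "representatives.txt"), "recruit"))
  vtab <- utils::read.table(.need(config$inputs$viromes_tsv %||%
                                    .p(config, "viromes.tsv"), "recruit"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  viromes <- lapply(seq_len(nrow(vtab)), function(i)
    list(reads = readViromeReads(.need(vtab$path[i], "recruit")),
         total_bases = vtab$total_bases[i]))
  names(viromes) <- vtab$virome_id
  se <- profilePanel(viromes, gs[reps],
                     read_min_len = th$read_min_len,
                     id_min = th$read_id_min, cov_min = th$read_cov_min,
                     breadth_min = th$breadth_min)
  writeRecruitmentTsv(se, long_path = .p(config, "recruitment_long.tsv"),
                      wide_path = .p(config, "kpkg_matrix.tsv"))
  invisible(TRUE)
}

.st_report <- function(config) {
  dec <- .read_decisions(config, "report")
  part <- utils::read.table(.need(.p(config, "partition.tsv"), "report"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  genus <- part[part$rank == "genus", , drop = FALSE]
  sizes <- sort(table(genus$cluster_id), decreasing = TRUE)
  wide <- utils::read.table(.need(.p(config, "kpkg_matrix.tsv"), "report"),
                            sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  lines <- c(
    sprintf("contigs_screened\t%d", nrow(dec)),
    sprintf("group_members\t%d", sum(dec$is_member)),
    sprintf("genus_clusters\t%d", length(sizes)),
    sprintf("genus_cluster_sizes\t%s", paste(sizes, collapse = ",")),
    sprintf("recruited_genomes\t%d", nrow(wide)),
    sprintf("viromes\t%d", ncol(wide) - 1L))
  writeLines(lines, .p(config, "report.tsv"))
  invisible(TRUE)
}

.STAGES <- c("simulate", "annotate", "group", "dereplicate", "tree",
             "recruit", "report")

#' Run one pipeline stage (or all of them)
#'
#' Orchestrates the analysis stages over a shared output directory; each
#' stage reads the artifacts of its predecessors from that directory, so
#' running stages one at a time in order is identical to running `"all"`.
#' A manifest (`manifest.yaml`: configuration snapshot, seed, package
#' version, input checksums) is written on every invocation.
#'
#' @param name one of `"simulate"`, `"annotate"`, `"group"`,
#'   `"dereplicate"`, `"tree"`, `"recruit"`, `"report"`, `"all"`.
#' @param config configuration list ([defaultPipelineConfig()] /
#'   [readPipelineConfig()]).
#' @return invisibly `TRUE`; artifacts are written under `config$outdir`.
#' @export
runStage <- function(name, config = defaultPipelineConfig()) {
  if (!name %in% c(.STAGES, "all"))
    stop(sprintf("unknown subcommand '%s' (expected one of: %s, all)",
                 name, paste(.STAGES, collapse = ", ")))
  validatePipelineConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (name == "all") .STAGES else name
  for (s in stages) {
    message(sprintf("[mvgkit] stage=%s outdir=%s", s, config$outdir))
    switch(s,
           simulate = .st_simulate(config),
           annotate = .st_annotate(config),
           group = .st_group(config),
           dereplicate = .st_dereplicate(config),
           tree = .st_tree(config),
           recruit = .st_recruit(config),
           report = .st_report(config))
  }
  .write_manifest(config)
  invisible(TRUE)
}

#' @rdname runStage
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  runStage("all", config)
}
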