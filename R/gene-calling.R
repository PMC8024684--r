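#' Call open reading frames on phage genomes
#'
#' Deterministic six-frame maximal-ORF caller. In every frame of both
#' strands, each maximal ORF runs from the first start codon
#' (`ATG`/`GTG`/`TTG`) following an in-frame stop to the next in-frame stop
#' codon; the linear sequence start counts as following a stop. On circular
#' genomes frames continue across the origin and origin-spanning ORFs are
#' reported once with `end > genome length` (the wrap convention of
#' [extractSubseq()]). Proteins are translated with genetic code 11
#' (bacterial); the initiator codon is rendered as `M` regardless of which
#' start codon is used, and the terminal stop is not included in the
#' protein.
#'
#' Overlapping ORFs, on the same or on opposite strands, are all reported:
#' downstream analyses operate on orthologous groups, not on a
#' non-overlapping gene map.
#'
#' @param gs A [GenomeSet-class].
#' @param min_aa minimum protein length in amino acids (default 30).
#' @return A data.frame with one row per ORF: `genome_id`, `gene_index`
#'   (1-based ordinal along the genome), `start`, `end` (0-based half-open,
#'   stop codon included; `end` may exceed the genome length for
#'   origin-spanning ORFs), `strand`, `length_aa`, `protein`, and
#'   `protein_id` (`"<genome_id>_<gene_index>"`), sorted by `start`.
#' @examples
#' gs <- GenomeSet(c(g = "TAAATGAAATAA"))
#' callOrfs(gs, min_aa = 2)
#' @export
callOrfs <- function(gs, min_aa = 30L) {
  stopifnot(is(gs, "GenomeSet"))
  out <- lapply(seq_along(gs@seqs), function(i) {
    .call_orfs_one(as.character(gs@seqs[[i]]), gs@topology[i],
                   names(gs@seqs)[i], as.integer(min_aa))
  })
  do.call(rbind, out)
}

.STOPS <- c("TAA", "TAG", "TGA")
.STARTS <- c("ATG", "GTG", "TTG")

# scan the three forward frames of W for maximal ORFs;
# returns 0-based half-open nt intervals on W (stop codon included)
.scan_frames <- function(W, min_aa) {
  M <- nchar(W)
  res <- vector("list", 3L)
  for (f in 0:2) {
    ncod <- (M - f) %/% 3L
    if (ncod < min_aa + 1L) { res[[f + 1L]] <- NULL; next }
    p <- f + 3L * (seq_len(ncod) - 1L)           # 0-based codon starts
    cod <- substring(W, p + 1L, p + 3L)
    st <- which(cod %in% .STOPS)
    sa <- which(cod %in% .STARTS)
    if (length(st) == 0L || length(sa) == 0L) next
    prev <- c(0L, st[-length(st)])
    first <- sa[findInterval(prev, sa) + 1L]      # first start after prev stop
    ok <- !is.na(first) & first < st & (st - first) >= min_aa
    if (!any(ok)) next
    a <- first[ok]; s <- st[ok]
    res[[f + 1L]] <- cbind(start = f + 3L * (a - 1L), end = f + 3L * s)
  }
  m <- do.call(rbind, res)
  if (is.null(m)) matrix(integer(), ncol = 2L,
                         dimnames = list(NULL, c("start", "end"))) else m
}

.call_orfs_one <- function(seq, topo, id, min_aa) {
  L <- nchar(seq)
  if (L < 3L * (min_aa + 1L))
    stop(sprintf("genome %s too short for ORF calling at min_aa=%d",
                 id, min_aa))
  circular <- identical(topo, "circular")
  if (circular) {
    W <- strrep(seq, 3L)
    lo <- L
  } else {
    W <- seq
    lo <- 0L
  }
  keep_window <- function(m) {
    if (nrow(m) == 0L) return(m)
    m <- m[m[, 1L] >= lo & m[, 1L] < lo + L, , drop = FALSE]
    m[m[, 2L] - m[, 1L] <= L, , drop = FALSE]   # guard stop-free frames
  }
  fwd <- keep_window(.scan_frames(W, min_aa))
  rc <- revcomp_chr(W)
  rev <- keep_window(.scan_frames(rc, min_aa))
  M <- nchar(W)
  rows <- list()
  if (nrow(fwd) > 0L) {
    st <- (fwd[, 1L] - lo) %% max(L, 1L)
    rows[[1L]] <- data.frame(start = st, end = st + (fwd[, 2L] - fwd[, 1L]),
                             strand = "+", stringsAsFactors = FALSE)
  }
  if (nrow(rev) > 0L) {
    st0 <- M - rev[, 2L]
    st <- st0 %% max(L, 1L)
    rows[[2L]] <- data.frame(start = st, end = st + (rev[, 2L] - rev[, 1L]),
                             strand = "-", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(genome_id = character(), gene_index = integer(),
                      start = integer(), end = integer(),
                      strand = character(), length_aa = integer(),
                      protein = character(), protein_id = character(),
                      stringsAsFactors = FALSE))
  g <- do.call(rbind, rows)
  g <- unique(g)
  g <- g[order(g$start, g$end, g$strand), , drop = FALSE]
  # translate from coordinates (round-trip through the wrap convention)
  gs1 <- GenomeSet(stats::setNames(seq, id),
                   topology = if (circular) "circular" else "linear")
  nt <- vapply(seq_len(nrow(g)), function(i)
    extractSubseq(gs1, id, g$start[i], g$end[i], g$strand[i]), character(1))
  nt_nostop <- substr(nt, 1L, nchar(nt) - 3L)
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt_nostop),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  prot <- paste0("M", substr(prot, 2L, nchar(prot)))
  data.frame(genome_id = id, gene_index = seq_len(nrow(g)),
             start = g$start, end = g$end, strand = g$strand,
             length_aa = nchar(prot), protein = prot,
             protein_id = paste0(id, "_", seq_len(nrow(g))),
             stringsAsFactors = FALSE)
}

#' Annotate called genes by homology to reference proteins
#'
#' Each gene's protein is searched against a reference protein set with the
#' package's local aligner; the best-scoring reference hit passing all three
#' thresholds is emitted, otherwise the gene receives no annotation.
#' Coverage is the fraction of the query (gene) protein covered by the
#' alignment.
#'
#' @param genes gene table from [callOrfs()].
#' @param reference_proteins named character vector (or
#'   [Biostrings::AAStringSet]) of reference proteins. Names may carry a
#'   description after the first whitespace, which becomes the annotation
#'   label.
#' @param e_max,id_min,cov_min thresholds: E-value at most `e_max`
#'   (default 1e-3), identity fraction at least `id_min` (default 0.25),
#'   query coverage at least `cov_min` (default 0.50).
#' @param word_size exact-word prefilter size for the search (see
#'   [allVsAllProteins()]).
#' @return data.frame: `protein_id`, `subject_id`, `identity`, `coverage`,
#'   `evalue`, `bitscore`, `label`; one row per annotated gene.
#' @export
annotateGenes <- function(genes, reference_proteins, e_max = 1e-3,
                          id_min = 0.25, cov_min = 0.50, word_size = 4L) {
  if (length(reference_proteins) == 0L)
    stop("reference protein set is empty")
  refs <- as.character(reference_proteins)
  labels <- names(reference_proteins) %||%
    paste0("ref", seq_along(reference_proteins))
  ids <- sub("\\s.*$", "", labels)
  desc <- ifelse(grepl("\\s", labels), sub("^\\S+\\s+", "", labels), ids)
  if (nrow(genes) == 0L)
    return(data.frame(protein_id = character(), subject_id = character(),
                      identity = numeric(), coverage = numeric(),
                      evalue = numeric(), bitscore = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  eff_hits <- max(1L, min(2L, min(nchar(c(genes$protein, refs))) -
                            word_size + 1L))
  hits <- cpp_allvsall_protein(genes$protein, unname(refs), FALSE,
                               as.integer(word_size), eff_hits,
                               blosum62_128(), 11L, 1L)
  n_db <- sum(nchar(refs))
  out <- list()
  if (nrow(hits) > 0L) {
    qlen <- nchar(genes$protein)[hits$i]
    bits <- bitscoreKA(hits$score)
    ev <- qlen * n_db * 2^(-bits)
    identity <- hits$identities / hits$length
    coverage <- (hits$q_end - hits$q_start) / qlen
    keep <- ev <= e_max & identity >= id_min & coverage >= cov_min
    h <- hits[keep, , drop = FALSE]
    if (nrow(h) > 0L) {
      bits <- bits[keep]; ev <- ev[keep]
      identity <- identity[keep]; coverage <- coverage[keep]
      ord <- order(h$i, -h$score, ids[h$j])
      h <- h[ord, , drop = FALSE]
      first <- !duplicated(h$i)
      out <- data.frame(
        protein_id = genes$protein_id[h$i[first]],
        subject_id = ids[h$j[first]],
        identity = identity[ord][first],
        coverage = coverage[ord][first],
        evalue = ev[ord][first],
        bitscore = bits[ord][first],
        label = desc[h$j[first]],
        stringsAsFactors = FALSE)
      return(out)
    }
  }
  data.frame(protein_id = character(), subject_id = character(),
             identity = numeric(), coverage = numeric(),
             evalue = numeric(), bitscore = numeric(),
             label = character(), stringsAsFactors = FALSE)
}

#' Write called proteins to FASTA and coordinates to TSV
#'
#' @param genes gene table from [callOrfs()].
#' @param faa_path output protein FASTA path (IDs
#'   `"<genome_id>_<gene_index>"`); `NULL` to skip.
#' @param tsv_path output coordinate TSV path (`genome_id`, `gene_index`,
#'   `start`, `end`, `strand`, `length_aa`); `NULL` to skip.
#' @return invisibly, the gene table.
#' @export
writeGeneOutputs <- function(genes, faa_path = NULL, tsv_path = NULL) {
  if (!is.null(faa_path)) {
    aa <- Biostrings::AAStringSet(stats::setNames(genes$protein,
                                                  genes$protein_id))
    Biostrings::writeXStringSet(aa, filepath = faa_path, width = 70L)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(
      genes[, c("genome_id", "gene_index", "start", "end", "strand",
                "length_aa")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(genes)
}
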