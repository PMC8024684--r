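#' Length-filter viromic reads
#'
#' Keeps reads of at least `min_len` bp (inclusive), preserving order.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector of reads.
#' @param min_len minimum read length (default 50).
#' @return Same type as the input, filtered.
#' @export
filterReads <- function(reads, min_len = 50L) {
  if (length(reads) == 0L) return(reads)
  w <- if (is.character(reads)) nchar(reads) else Biostrings::width(reads)
  reads[w >= min_len]
}

#' Dataset size of a virome
#'
#' Total bases over all reads of the dataset, computed before any length
#' filtering: the per-gigabase term of the KPKG normalization describes the
#' dataset, not the filtered subset.
#'
#' @param reads the full (unfiltered) read set.
#' @param virome_id identifier.
#' @return list with `virome_id` and `total_bases`.
#' @export
viromeStats <- function(reads, virome_id = "virome") {
  w <- if (is.character(reads)) nchar(reads) else Biostrings::width(reads)
  tb <- sum(as.numeric(w))
  if (tb < 1) stop("virome has no bases")
  list(virome_id = virome_id, total_bases = tb)
}

# panel sequences sorted by ID, circular ones extended past the origin so
# wrap-spanning reads align contiguously (subject coordinates may then
# exceed the genome length, matching the wrap convention)
.panel_for_recruitment <- function(panel, max_query_len) {
  ids <- sort(names(panel))
  seqs <- as.character(genomeSeqs(panel))[ids]
  topo <- topology(panel)[ids]
  L <- nchar(seqs)
  ext <- pmin(L, max_query_len + 16L)
  seqs <- ifelse(topo == "circular",
                 paste0(seqs, substr(seqs, 1L, ext)), seqs)
  list(ids = ids, seqs = seqs, len = L)
}

#' Recruit a single read against a genome panel
#'
#' Best nucleotide hit across the panel with identity at least `id_min`
#' and aligned read fraction at least `cov_min`; "best" is the highest
#' scoring hit, ties broken by the lexicographically smallest genome ID.
#'
#' @param read a single read (character).
#' @param panel [GenomeSet-class] of candidate genomes.
#' @param id_min,cov_min recruitment thresholds (defaults 0.70 and 0.90).
#' @param seed_k seed length for the nucleotide aligner.
#' @return A one-row data.frame (`genome_id`, alignment columns), or `NULL`
#'   when no hit qualifies.
#' @export
recruitRead <- function(read, panel, id_min = 0.70, cov_min = 0.90,
                        seed_k = 11L) {
  p <- .panel_for_recruitment(panel, nchar(read))
  h <- cpp_recruit_batch(as.character(read), p$seqs, as.integer(seed_k),
                         2L, 3L, 5L, 2L, 8L, id_min, cov_min)
  if (nrow(h) == 0L) return(NULL)
  data.frame(genome_id = p$ids[h$genome[1L]], h[1L, -(1:2)],
             stringsAsFactors = FALSE)
}

#' Breadth of coverage from recruited hits
#'
#' Fraction of genome positions covered by at least one recruited read:
#' the size of the union of subject intervals divided by the genome
#' length. Intervals extending past the genome length (circular wrap) are
#' unwrapped before the union.
#'
#' @param genome_len genome length in bp.
#' @param s_start,s_end 0-based half-open subject intervals of the hits.
#' @return Breadth fraction in `[0, 1]`.
#' @examples
#' breadthOfCoverage(2000, c(0, 400), c(600, 1000))  # 0.5
#' @export
breadthOfCoverage <- function(genome_len, s_start, s_end) {
  if (length(s_start) == 0L) return(0)
  stopifnot(length(s_start) == length(s_end), all(s_end > s_start))
  s0 <- s_start %% genome_len
  e0 <- s0 + (s_end - s_start)
  wrap <- e0 > genome_len
  starts <- c(s0[!wrap], s0[wrap], rep(0L, sum(wrap)))
  ends <- c(e0[!wrap], rep(genome_len, sum(wrap)),
            pmin(e0[wrap] - genome_len, genome_len))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  min(sum(IRanges::width(ir)) / genome_len, 1)
}

#' KPKG abundance normalization
#'
#' Recruited kilobases of read nucleotides per kilobase of genome per
#' gigabase of metagenome:
#' `recruited_kb / (genome_len_bp/1000) / (total_bases/1e9)`.
#'
#' @param recruited_kb aligned read nucleotides, in kb.
#' @param genome_len_bp genome length (>= 1).
#' @param total_bases metagenome size in bases (> 0).
#' @return KPKG value.
#' @examples
#' kpkg(10, 34774, 1e7)  # ~28.76
#' @export
kpkg <- function(recruited_kb, genome_len_bp, total_bases) {
  stopifnot(genome_len_bp >= 1)
  if (any(total_bases <= 0)) stop("metagenome size must be positive")
  recruited_kb / (genome_len_bp / 1000) / (total_bases / 1e9)
}

#' Recruitment profile of a genome panel across viromes
#'
#' For every (genome, virome) pair: reads are length-filtered, each read is
#' recruited to its single best genome in the panel (identity and coverage
#' thresholds as in [recruitRead()]), aligned read nucleotides and subject
#' intervals are accumulated per genome, and breadth of coverage and KPKG
#' are computed. KPKG is zeroed where breadth falls below `breadth_min`
#' (the raw value is kept in the `kpkg_raw` assay).
#'
#' @param viromes named list; each element is either a read set
#'   ([Biostrings::DNAStringSet]/character) or a list with elements
#'   `reads` and optionally `total_bases` (defaulting to the total bases
#'   of the unfiltered reads).
#' @param panel [GenomeSet-class]; expected to be dereplicated upstream
#'   (see [dereplicateGenomes()]); not re-checked here.
#' @param read_min_len,id_min,cov_min read filters (defaults 50 bp, 0.70,
#'   0.90).
#' @param breadth_min breadth threshold below which KPKG is zeroed
#'   (default 0.40).
#' @param seed_k seed length for the nucleotide aligner.
#' @param count_full_read count the full read length instead of only its
#'   aligned nucleotides (default FALSE).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `kpkg`, `kpkg_raw`, `breadth`, `recruited_kb` (genomes x viromes),
#'   genome lengths in `rowData` and virome sizes in `colData`.
#' @export
profilePanel <- function(viromes, panel, read_min_len = 50L, id_min = 0.70,
                         cov_min = 0.90, breadth_min = 0.40, seed_k = 11L,
                         count_full_read = FALSE) {
  if (length(viromes) == 0L) stop("no viromes given")
  if (length(panel) == 0L) stop("empty genome panel")
  vids <- names(viromes) %||% paste0("virome", seq_along(viromes))
  gids <- sort(names(panel))
  lens <- genomeLengths(panel)[gids]
  nz <- function() matrix(0, length(gids), length(viromes),
                          dimnames = list(gids, vids))
  m_kb <- nz(); m_breadth <- nz()
  total_bases <- numeric(length(viromes))
  n_reads <- integer(length(viromes))
  n_filtered <- integer(length(viromes))
  n_recruited <- integer(length(viromes))
  for (v in seq_along(viromes)) {
    el <- viromes[[v]]
    reads <- if (is.list(el) && !is.null(el$reads)) el$reads else el
    reads <- as.character(reads)
    tb <- if (is.list(el) && !is.null(el$total_bases)) el$total_bases
          else sum(as.numeric(nchar(reads)))
    if (tb <= 0) stop(sprintf("virome %s has no bases", vids[v]))
    total_bases[v] <- tb
    n_reads[v] <- length(reads)
    reads <- filterReads(reads, read_min_len)
    n_filtered[v] <- length(reads)
    if (length(reads) == 0L) next
    p <- .panel_for_recruitment(panel, max(nchar(reads)))
    h <- cpp_recruit_batch(reads, p$seqs, as.integer(seed_k), 2L, 3L, 5L,
                           2L, 8L, id_min, cov_min)
    n_recruited[v] <- nrow(h)
    if (nrow(h) == 0L) next
    nt <- if (count_full_read) nchar(reads)[h$read] else h$q_end - h$q_start
    kb <- tapply(nt, h$genome, sum) / 1000
    m_kb[p$ids[as.integer(names(kb))], v] <- as.numeric(kb)
    for (g in unique(h$genome)) {
      sel <- h$genome == g
      m_breadth[p$ids[g], v] <- breadthOfCoverage(
        lens[p$ids[g]], h$s_start[sel], h$s_end[sel])
    }
  }
  raw <- sweep(sweep(m_kb, 1L, lens / 1000, "/"), 2L, total_bases / 1e9, "/")
  zeroed <- raw
  zeroed[m_breadth < breadth_min] <- 0
  SummarizedExperiment::SummarizedExperiment(
    assays = list(kpkg = zeroed, kpkg_raw = raw, breadth = m_breadth,
                  recruited_kb = m_kb),
    rowData = S4Vectors::DataFrame(genome_id = gids, length_bp = lens,
                                   topology = topology(panel)[gids]),
    colData = S4Vectors::DataFrame(virome_id = vids,
                                   total_bases = total_bases,
                                   n_reads = n_reads,
                                   n_reads_filtered = n_filtered,
                                   n_reads_recruited = n_recruited,
                                   row.names = vids))
}

#' Write recruitment outputs
#'
#' Long-format TSV (`virome_id`, `genome_id`, `recruited_kb`, `breadth`,
#' `kpkg_raw`, `kpkg`) and a wide genomes-x-viromes KPKG matrix TSV.
#'
#' @param se output of [profilePanel()].
#' @param long_path,wide_path output paths (`NULL` to skip either).
#' @return invisibly, `se`.
#' @export
writeRecruitmentTsv <- function(se, long_path = NULL, wide_path = NULL) {
  a <- SummarizedExperiment::assays(se)
  if (!is.null(long_path)) {
    long <- expand.grid(genome_id = rownames(se), virome_id = colnames(se),
                        stringsAsFactors = FALSE)
    long$recruited_kb <- as.vector(a$recruited_kb)
    long$breadth <- as.vector(a$breadth)
    long$kpkg_raw <- as.vector(a$kpkg_raw)
    long$kpkg <- as.vector(a$kpkg)
    long <- long[, c("virome_id", "genome_id", "recruited_kb", "breadth",
                     "kpkg_raw", "kpkg")]
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(wide_path)) {
    utils::write.table(data.frame(genome_id = rownames(se), a$kpkg,
                                  check.names = FALSE),
                       wide_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(se)
}
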