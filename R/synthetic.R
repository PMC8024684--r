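#' Generate a reference phage genome with planted genes
#'
#' Builds a circular dsDNA genome of the requested length carrying
#' `n_genes` non-overlapping protein-coding genes on the forward strand,
#' with intergenic filler at the target G+C. Gene lengths are drawn
#' between `min_gene` and `max_gene` nt (multiples of 3, rescaled to fit
#' the genome); each gene starts with `ATG`, has a stop-free interior of
#' non-stop codons drawn at the target G+C, and ends with a stop codon. An
#' in-frame `TAA` is placed immediately upstream of every gene start so
#' that the maximal-ORF caller recovers each planted gene exactly.
#'
#' The defaults emulate a coastal marine phage isolate genome: ~35 kb,
#' ~55 genes, G+C ~0.40.
#'
#' @param seed RNG seed; the output is a deterministic function of the
#'   arguments.
#' @param length genome length in bp.
#' @param n_genes number of planted genes.
#' @param gc target G+C fraction.
#' @param min_gene,max_gene gene length bounds in nt (coding, incl. stop).
#' @param id genome identifier.
#' @return list with `genome` (a one-record [GenomeSet-class], circular,
#'   source `"synthetic"`) and `genes` (data.frame of planted truth:
#'   `gene_index`, `start`, `end` 0-based half-open incl. stop, `strand`,
#'   `length_aa`, `protein`, `protein_id`), plus the generating `params`.
#' @export
makeReferenceGenome <- function(seed, length = 35000L, n_genes = 55L,
                                gc = 0.40, min_gene = 300L, max_gene = 1500L,
                                id = "REF") {
  stopifnot(length >= 1L, n_genes >= 0L, gc > 0, gc < 1)
  min_gene <- (min_gene %/% 3L) * 3L
  max_gene <- (max_gene %/% 3L) * 3L
  if (n_genes > 0L && n_genes * (min_gene + 3L) > length)
    stop("cannot pack the requested genes into the genome length")
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  res <- with_seed_(seed, {
    rand_nt <- function(n) {
      if (n <= 0L) return("")
      paste(sample(names(base_p), n, replace = TRUE, prob = base_p),
            collapse = "")
    }
    if (n_genes == 0L) {
      list(seq = rand_nt(length), genes = NULL)
    } else {
      lens <- 3L * sample(seq(min_gene %/% 3L, max_gene %/% 3L), n_genes,
                          replace = TRUE)
      budget <- length - 3L * n_genes   # reserve the upstream TAA spacers
      # rescale draws that exceed the genome, respecting the minimum
      for (it in 1:100) {
        if (sum(lens) <= budget) break
        red <- lens > min_gene
        if (!any(red)) stop("cannot pack genes; reduce n_genes")
        scale <- (budget - sum(lens[!red])) / sum(lens[red])
        lens[red] <- pmax(min_gene, 3L * as.integer((lens[red] * scale) %/% 3L))
      }
      if (sum(lens) > budget) stop("cannot pack genes; reduce n_genes")
      filler <- length - sum(lens) - 3L * n_genes
      gaps <- as.integer(stats::rmultinom(1L, filler,
                                          rep(1, n_genes + 1L)))
      # 61 non-stop codons; excluding the AT-rich stop codons biases the
      # coding G+C upward, so solve for the base composition whose
      # stop-free codon distribution hits the target exactly
      codons <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                                  b2 = c("A", "C", "G", "T"),
                                  b3 = c("A", "C", "G", "T")), 1L, paste,
                      collapse = "")
      keep <- !(codons %in% .STOPS)
      cod_ok <- codons[keep]
      gc_frac <- vapply(strsplit(cod_ok, ""), function(b)
        mean(b %in% c("G", "C")), numeric(1))
      codon_p_at <- function(g) {
        p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
        pr <- apply(expand.grid(p, p, p), 1L, prod)[keep]
        pr / sum(pr)
      }
      g_star <- stats::uniroot(function(g)
        sum(codon_p_at(g) * gc_frac) - gc, c(0.02, 0.98))$root
      cod_p <- codon_p_at(g_star)
      gene_seq <- function(len) {
        ncod <- len %/% 3L
        interior <- sample(cod_ok, ncod - 2L, replace = TRUE, prob = cod_p)
        paste0("ATG", paste(interior, collapse = ""),
               sample(.STOPS, 1L))
      }
      parts <- character(0)
      starts <- integer(n_genes)
      pos <- 0L
      for (g in seq_len(n_genes)) {
        fill <- rand_nt(gaps[g])
        parts <- c(parts, fill, "TAA")
        pos <- pos + gaps[g] + 3L
        starts[g] <- pos
        gs <- gene_seq(lens[g])
        parts <- c(parts, gs)
        pos <- pos + lens[g]
      }
      parts <- c(parts, rand_nt(gaps[n_genes + 1L]))
      list(seq = paste(parts, collapse = ""), starts = starts, lens = lens)
    }
  })
  genome <- GenomeSet(stats::setNames(res$seq, id), topology = "circular",
                      source = "synthetic")
  if (n_genes == 0L) {
    genes <- data.frame(gene_index = integer(), start = integer(),
                        end = integer(), strand = character(),
                        length_aa = integer(), protein = character(),
                        protein_id = character(), stringsAsFactors = FALSE)
  } else {
    nt <- substring(res$seq, res$starts + 1L, res$starts + res$lens - 3L)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt),
      genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE))
    prot <- paste0("M", substr(prot, 2L, nchar(prot)))
    genes <- data.frame(gene_index = seq_len(n_genes), start = res$starts,
                        end = res$starts + res$lens, strand = "+",
                        length_aa = nchar(prot), protein = prot,
                        protein_id = paste0(id, "_", seq_len(n_genes)),
                        stringsAsFactors = FALSE)
  }
  list(genome = genome, genes = genes,
       params = list(seed = seed, length = length, n_genes = n_genes,
                     gc = gc, min_gene = min_gene, max_gene = max_gene,
                     id = id))
}

#' Evolve a genome to a planted divergence and gene retention
#'
#' Derives a related genome from a reference: `floor((1 - retention) * n)`
#' randomly chosen genes (outside `keep`) are removed, and uniform random
#' substitutions are applied at rate `nt_divergence` to all positions
#' outside the start and stop codons of retained genes. Substitutions
#' inside retained genes are frame-aware: a substitution that would create
#' an in-frame stop codon is redirected to another base, so retained genes
#' stay intact as ORFs while the substitution count (and hence the planted
#' nucleotide divergence) is preserved.
#'
#' By default removed genes are *replaced* by fresh random sequence of
#' equal length at the reference G+C (`mode = "replace"`), emulating
#' environmental genomes that share only part of their gene complement
#' with the reference while keeping a realistic genome size;
#' `mode = "delete"` excises the intervals instead.
#'
#' @param ref output of [makeReferenceGenome()] (or a list with `genome`
#'   and `genes`).
#' @param nt_divergence substitution rate in `[0, 0.5]`.
#' @param gene_retention fraction of genes retained, in `[0, 1]`.
#' @param seed RNG seed.
#' @param id identifier of the derived genome.
#' @param mode `"replace"` (default) or `"delete"` for removed genes.
#' @param keep gene indices never removed (e.g. a marker gene).
#' @param gc G+C of replacement sequence (defaults to the reference
#'   target).
#' @return list with `genome` (one-record [GenomeSet-class], source
#'   `"MVG"`) and `truth` (retained/removed gene indices, realized
#'   substitution count, parameters).
#' @export
evolveGenome <- function(ref, nt_divergence, gene_retention, seed,
                         id = "MVG", mode = c("replace", "delete"),
                         keep = integer(0), gc = NULL) {
  mode <- match.arg(mode)
  stopifnot(nt_divergence >= 0, nt_divergence <= 0.5,
            gene_retention >= 0, gene_retention <= 1)
  genes <- ref$genes
  seq <- genomeSeqs(ref$genome, names(ref$genome))
  if (is.null(gc)) gc <- ref$params$gc %||% 0.5
  n <- nrow(genes)
  n_del <- floor((1 - gene_retention) * n)
  res <- with_seed_(seed, {
    candidates <- setdiff(seq_len(n), keep)
    if (n_del > length(candidates))
      stop("keep set too large for the requested retention")
    removed <- sort(sample(candidates, n_del))
    retained <- setdiff(seq_len(n), removed)
    chars <- strsplit(seq, "")[[1L]]
    L <- length(chars)
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    for (g in removed) {
      span <- (genes$start[g] + 1L):genes$end[g]
      chars[span] <- sample(names(base_p), length(span), replace = TRUE,
                            prob = base_p)
    }
    # positions protected from substitution: start + stop codons of
    # retained genes and their planted upstream in-frame stop (so retained
    # genes keep their exact ORF boundaries); gene interiors noted for
    # frame-aware substitution
    protected <- logical(L)
    frame_gene <- integer(L)   # 0 = intergenic, else retained gene index
    for (g in retained) {
      s <- genes$start[g]; e <- genes$end[g]
      if (s >= 3L) protected[(s - 2L):s] <- TRUE  # upstream spacer stop
      protected[(s + 1L):(s + 3L)] <- TRUE
      protected[(e - 2L):e] <- TRUE
      frame_gene[(s + 4L):(e - 3L)] <- g
    }
    if (mode == "replace") {
      for (g in removed) frame_gene[(genes$start[g] + 1L):genes$end[g]] <- -1L
    }
    eligible <- which(!protected & frame_gene >= 0L)
    n_sub <- stats::rbinom(1L, length(eligible), nt_divergence)
    sub_pos <- sort(sample(eligible, n_sub))
    bases <- c("A", "C", "G", "T")
    for (p in sub_pos) {
      alts <- setdiff(bases, chars[p])
      g <- frame_gene[p]
      if (g > 0L) {
        # avoid creating an in-frame stop in a retained gene
        s <- genes$start[g]
        cod0 <- s + 3L * ((p - 1L - s) %/% 3L)    # 0-based codon start
        ok <- vapply(alts, function(b) {
          cod <- chars[(cod0 + 1L):(cod0 + 3L)]
          cod[p - cod0] <- b
          !(paste(cod, collapse = "") %in% .STOPS)
        }, logical(1))
        alts <- alts[ok]
      }
      chars[p] <- if (length(alts)) sample(alts, 1L) else chars[p]
    }
    list(seq = paste(chars, collapse = ""), removed = removed,
         retained = retained, n_sub = n_sub)
  })
  out_seq <- res$seq
  if (mode == "delete" && length(res$removed)) {
    drop <- unlist(lapply(res$removed, function(g)
      (genes$start[g] + 1L):genes$end[g]))
    out_seq <- paste(strsplit(out_seq, "")[[1L]][-drop], collapse = "")
  }
  genome <- GenomeSet(stats::setNames(out_seq, id), topology = "circular",
                      source = "MVG")
  list(genome = genome,
       truth = list(id = id, reference_id = names(ref$genome),
                    retained = res$retained, removed = res$removed,
                    n_substitutions = res$n_sub,
                    nt_divergence = nt_divergence,
                    gene_retention = gene_retention, mode = mode,
                    seed = seed))
}

#' Simulate a viromic read set from a genome panel
#'
#' Reads of fixed length are drawn from panel genomes according to an
#' abundance vector (summing to 1 over the panel), from uniform start
#' positions (honoring circular topology) and uniform strands, with iid
#' per-base substitution errors at `error_rate`. A `background_fraction`
#' of reads is instead fresh uniform random sequence, emulating the
#' unrelated majority of a real virome. `total_bases` is
#' `n_reads * read_len` (the dataset size before any filtering).
#'
#' @param panel [GenomeSet-class].
#' @param abundances named numeric vector over the panel, summing to 1.
#' @param n_reads number of reads.
#' @param read_len read length (>= 50 for recruitment defaults).
#' @param error_rate per-base substitution error rate.
#' @param background_fraction fraction of background reads in `[0, 1)`.
#' @param seed RNG seed.
#' @param virome_id identifier.
#' @return list with `reads` (named character vector), `stats`
#'   (`virome_id`, `total_bases`), and `truth` (per-genome read counts and
#'   all parameters).
#' @export
simulateVirome <- function(panel, abundances, n_reads, read_len = 100L,
                           error_rate = 0.01, background_fraction = 0,
                           seed = 1L, virome_id = "virome") {
  ids <- names(panel)
  stopifnot(length(abundances) == length(ids),
            background_fraction >= 0, background_fraction < 1)
  if (is.null(names(abundances))) names(abundances) <- ids
  abundances <- abundances[ids]
  if (abs(sum(abundances) - 1) > 1e-8)
    stop("abundances must sum to 1 over the panel")
  seqs <- as.character(genomeSeqs(panel))
  topo <- topology(panel)
  L <- nchar(seqs)
  doubled <- ifelse(topo == "circular",
                    paste0(seqs, substr(seqs, 1L, read_len)), seqs)
  bases <- c("A", "C", "G", "T")
  res <- with_seed_(seed, {
    is_bg <- stats::runif(n_reads) < background_fraction
    src <- character(n_reads)
    src[!is_bg] <- sample(ids, sum(!is_bg), replace = TRUE,
                          prob = abundances)
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      if (is_bg[i]) {
        reads[i] <- paste(sample(bases, read_len, replace = TRUE),
                          collapse = "")
        next
      }
      g <- src[i]
      gi <- match(g, ids)
      max_start <- if (topo[gi] == "circular") L[gi] else L[gi] - read_len + 1L
      if (max_start < 1L)
        stop(sprintf("genome %s shorter than read length", g))
      start <- sample.int(max_start, 1L)
      r <- substr(doubled[gi], start, start + read_len - 1L)
      if (stats::runif(1) < 0.5) r <- revcomp_chr(r)
      if (error_rate > 0) {
        ne <- stats::rbinom(1L, read_len, error_rate)
        if (ne > 0L) {
          pos <- sample.int(read_len, ne)
          rc <- strsplit(r, "")[[1L]]
          for (p in pos) rc[p] <- sample(setdiff(bases, rc[p]), 1L)
          r <- paste(rc, collapse = "")
        }
      }
      reads[i] <- r
    }
    list(reads = reads, src = src, is_bg = is_bg)
  })
  names(res$reads) <- sprintf("%s_read%06d", virome_id, seq_len(n_reads))
  counts <- table(factor(res$src[!res$is_bg], levels = ids))
  list(reads = res$reads,
       stats = list(virome_id = virome_id,
                    total_bases = as.numeric(n_reads) * read_len),
       truth = list(virome_id = virome_id, abundances = abundances,
                    background_fraction = background_fraction,
                    n_reads = n_reads, read_len = read_len,
                    error_rate = error_rate, seed = seed,
                    source_counts = as.integer(counts),
                    source_ids = ids))
}
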