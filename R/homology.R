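#' Karlin-Altschul bit score and E-value
#'
#' Converts a raw local-alignment score into a bit score,
#' `(lambda * score - ln K) / ln 2`, and an expected number of chance hits,
#' `E = m * n * 2^(-bitscore)`. The default constants are the standard
#' gapped BLOSUM62 values (`lambda = 0.267`, `K = 0.041`); nucleotide
#' searches use different constants (see [alignNtLocal()]).
#'
#' @param score raw alignment score(s).
#' @param lambda,K Karlin-Altschul constants.
#' @return `bitscoreKA()`: numeric bit scores.
#' @export
bitscoreKA <- function(score, lambda = 0.267, K = 0.041) {
  (lambda * score - log(K)) / log(2)
}

#' @rdname bitscoreKA
#' @param bitscore bit score(s).
#' @param m query length in residues.
#' @param n total subject letters in the searched database.
#' @return `evalueKA()`: numeric E-values (`>= 0`).
#' @examples
#' evalueKA(bitscoreKA(100), m = 200, n = 1e6)
#' @export
evalueKA <- function(bitscore, m, n) {
  stopifnot(m >= 1, n >= 1)
  m * n * 2^(-bitscore)
}

#' Optimal local protein alignment (Smith-Waterman)
#'
#' Full-matrix Smith-Waterman under BLOSUM62 with affine gap costs (a gap of
#' length k costs `gap_open + k * gap_extend`; defaults 11/1). Returns the
#' single optimal local alignment, or `NULL` when no positive-scoring local
#' alignment exists. Ties among equal-scoring alignments are broken
#' deterministically (smallest end coordinates in row-major order).
#'
#' @param a,b protein sequences (single strings over the amino-acid
#'   alphabet; `X` allowed).
#' @param gap_open,gap_extend affine gap costs.
#' @param n_db total subject letters used for the E-value (defaults to
#'   `nchar(b)`, i.e. a single-sequence database).
#' @return A one-row data.frame (`q_start`, `q_end`, `s_start`, `s_end`
#'   0-based half-open; `length` alignment columns including gaps;
#'   `identities`; `score`; `bitscore`; `evalue`), or `NULL`.
#' @examples
#' alignProteinLocal("HEAGAWGHEE", "PAWHEAE")
#' @export
alignProteinLocal <- function(a, b, gap_open = 11L, gap_extend = 1L,
                              n_db = nchar(b)) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- cpp_sw_protein(toupper(a), toupper(b), blosum62_128(),
                      as.integer(gap_open), as.integer(gap_extend))
  if (!r$found) return(NULL)
  bits <- bitscoreKA(r$score)
  data.frame(q_start = r$q_start, q_end = r$q_end,
             s_start = r$s_start, s_end = r$s_end,
             length = r$length, identities = r$identities,
             score = r$score, bitscore = bits,
             evalue = evalueKA(bits, nchar(a), n_db))
}

.NT_LAMBDA <- 0.625
.NT_K <- 0.41

#' Seeded local nucleotide alignment
#'
#' BLAST-like heuristic: exact k-mer seeds (default `seed_k = 11`) of both
#' strands of the query against the forward subject are clustered by
#' diagonal, and each cluster is extended by banded affine-gap dynamic
#' programming (match +2, mismatch -3, gap open 5, gap extend 2). `N` never
#' matches. Hits with identity fraction below `id_min` are dropped.
#' Deterministic given its inputs.
#'
#' @param a query DNA string.
#' @param b subject DNA string.
#' @param seed_k exact seed length.
#' @param id_min identity floor for reported hits (default 0, report all).
#' @param match,mismatch,gap_open,gap_extend scoring (mismatch and gaps as
#'   positive costs).
#' @param band_pad half-width added around the seed diagonal range.
#' @return data.frame of hits sorted by decreasing score: `q_start`, `q_end`
#'   (0-based half-open on the forward query), `s_start`, `s_end`,
#'   `s_strand`, `length`, `identities`, `score`, `bitscore`, `evalue`;
#'   zero rows when nothing aligns.
#' @examples
#' g <- strrep("ACGT", 30)
#' alignNtLocal(substr(g, 10, 60), g)
#' @export
alignNtLocal <- function(a, b, seed_k = 11L, id_min = 0,
                         match = 2L, mismatch = 3L,
                         gap_open = 5L, gap_extend = 2L, band_pad = 8L) {
  a <- toupper(a); b <- toupper(b)
  strands <- list(`+` = a, `-` = revcomp_chr(a))
  m <- nchar(a)
  out <- lapply(names(strands), function(s) {
    h <- cpp_nt_hits(strands[[s]], b, as.integer(seed_k), as.integer(match),
                     as.integer(mismatch), as.integer(gap_open),
                     as.integer(gap_extend), as.integer(band_pad))
    if (nrow(h) == 0L) return(NULL)
    if (s == "-") {
      q0 <- m - h$q_end; q1 <- m - h$q_start
      h$q_start <- q0; h$q_end <- q1
    }
    h$s_strand <- s
    h
  })
  h <- do.call(rbind, out)
  if (is.null(h) || nrow(h) == 0L) {
    h <- empty_hits_df()
    return(h[, c("q_start", "q_end", "s_start", "s_end", "s_strand",
                 "length", "identities", "score", "bitscore", "evalue")])
  }
  h <- h[h$identities / h$length >= id_min, , drop = FALSE]
  bits <- bitscoreKA(h$score, .NT_LAMBDA, .NT_K)
  h$bitscore <- bits
  h$evalue <- evalueKA(bits, nchar(a), nchar(b))
  h <- h[order(-h$score, h$q_start, h$s_start, h$s_strand), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("q_start", "q_end", "s_start", "s_end", "s_strand", "length",
        "identities", "score", "bitscore", "evalue")]
}

#' All-vs-all protein search
#'
#' Computes, for every pair of proteins between two sets, the best local
#' alignment passing the E-value and identity thresholds. Pairs sharing no
#' exact word of `word_size` letters are skipped (BLAST-like word
#' prefilter; set `word_size` smaller for higher sensitivity). When `set_b`
#' is omitted the search is within `set_a`, excluding self-pairs, and the
#' result contains each unordered pair once in both orientations'
#' coordinates (query = the first-sorted member).
#'
#' @param set_a,set_b named character vectors of protein sequences.
#' @param e_max,id_min hit thresholds (defaults 1e-3 and 0.25, no coverage
#'   filter).
#' @param word_size exact-word prefilter length (default 4).
#' @param min_word_hits number of distinct shared words required before a
#'   pair is aligned (default 2, the two-hit heuristic; clamped for very
#'   short sequences).
#' @param n_db total database letters for the E-value; defaults to the
#'   total length of `set_b` (or of `set_a` in self mode).
#' @return data.frame of hits: `query_id`, `subject_id`, coordinates,
#'   `length`, `identities`, `identity`, `score`, `bitscore`, `evalue`.
#' @export
allVsAllProteins <- function(set_a, set_b = NULL, e_max = 1e-3,
                             id_min = 0.25, word_size = 4L,
                             min_word_hits = 2L, n_db = NULL) {
  if (length(set_a) == 0L) stop("empty protein set")
  a_ids <- names(set_a) %||% paste0("a", seq_along(set_a))
  self <- is.null(set_b)
  if (self) {
    set_b <- set_a
    b_ids <- a_ids
  } else {
    if (length(set_b) == 0L) stop("empty protein set")
    b_ids <- names(set_b) %||% paste0("b", seq_along(set_b))
  }
  if (is.null(n_db)) n_db <- sum(nchar(set_b))
  eff_hits <- max(1L, min(as.integer(min_word_hits),
                          min(nchar(c(set_a, set_b))) - word_size + 1L))
  h <- cpp_allvsall_protein(unname(as.character(set_a)),
                            unname(as.character(set_b)), self,
                            as.integer(word_size), eff_hits,
                            blosum62_128(), 11L, 1L)
  if (nrow(h) == 0L) return(empty_hits_df())
  bits <- bitscoreKA(h$score)
  ev <- evalueKA(bits, nchar(set_a)[h$i], n_db)
  identity <- h$identities / h$length
  keep <- ev <= e_max & identity >= id_min
  h <- h[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(empty_hits_df())
  out <- data.frame(query_id = a_ids[h$i], subject_id = b_ids[h$j],
                    q_start = h$q_start, q_end = h$q_end,
                    s_start = h$s_start, s_end = h$s_end,
                    s_strand = "+", length = h$length,
                    identities = h$identities,
                    score = h$score, bitscore = bits[keep],
                    evalue = ev[keep], stringsAsFactors = FALSE)
  out$identity <- out$identities / out$length
  if (self && nrow(out) > 0L) {
    # emit both orientations so the self-search table is symmetric
    mir <- out
    mir$query_id <- out$subject_id; mir$subject_id <- out$query_id
    mir$q_start <- out$s_start; mir$q_end <- out$s_end
    mir$s_start <- out$q_start; mir$s_end <- out$q_end
    mir$evalue <- evalueKA(mir$bitscore, nchar(set_a)[match(mir$query_id,
                                                            a_ids)], n_db)
    out <- rbind(out, mir[mir$evalue <= e_max, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Write hits in 12-column BLAST-style tabular format
#'
#' Mirrors BLAST `outfmt 6` (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`). Coordinates are converted to
#' 1-based inclusive in this format only; minus-strand nucleotide hits
#' follow the BLAST convention of swapped subject coordinates.
#'
#' @param hits a hit table from [allVsAllProteins()] or [alignNtLocal()]
#'   (the latter needs `query_id`/`subject_id` columns added).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeHitsTsv <- function(hits, path) {
  stopifnot(all(c("query_id", "subject_id") %in% names(hits)))
  strand <- if ("s_strand" %in% names(hits)) hits$s_strand else "+"
  aligned_q <- hits$q_end - hits$q_start
  gaps <- hits$length - pmin(aligned_q, hits$s_end - hits$s_start)
  mism <- hits$length - hits$identities - pmax(gaps, 0L)
  s1 <- ifelse(strand == "+", hits$s_start + 1L, hits$s_end)
  s2 <- ifelse(strand == "+", hits$s_end, hits$s_start + 1L)
  df <- data.frame(hits$query_id, hits$subject_id,
                   sprintf("%.3f", 100 * hits$identities / hits$length),
                   hits$length, pmax(mism, 0L), pmax(gaps, 0L),
                   hits$q_start + 1L, hits$q_end, s1, s2,
                   format(hits$evalue, digits = 3, scientific = TRUE),
                   sprintf("%.1f", hits$bitscore))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
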