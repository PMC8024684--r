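# Independent oracles used by the tests. These deliberately share no code
# with the package implementation.

# Smith-Waterman score by straightforward full-matrix affine-gap DP
# (scoring only, no traceback); gap of length k costs open + k * extend.
sw_score_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  B <- blosum62_oracle()
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             E[i, j + 1] - gap_extend)
      F[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             F[i + 1, j] - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + B[a[i], b[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

blosum62_oracle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

random_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# substitute exactly n positions of a DNA string (each to a different base)
mutate_dna <- function(x, n) {
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# substitute exactly n positions of a protein
mutate_protein <- function(x, n) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(aas, ch[p]), 1)
  paste(ch, collapse = "")
}

# minimal GenBank flat-file writer for fixtures
write_genbank_fixture <- function(path, id = "SYNREC1", seq = NULL,
                                  n_cds = 3, circular = TRUE) {
  if (is.null(seq)) seq <- random_dna(600)
  lines <- c(sprintf("LOCUS       %s             %d bp    DNA     %s   PHG",
                     id, nchar(seq), if (circular) "circular" else "linear"),
             sprintf("DEFINITION  synthetic fixture record %s.", id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(seq)))
  if (n_cds > 0) {
    for (k in seq_len(n_cds)) {
      s <- 10 * k
      lines <- c(lines,
                 sprintf("     CDS             %d..%d", s, s + 29),
                 sprintf("                     /product=\"orf%d\"", k))
    }
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1, nchar(seq), by = 60)
  for (p in pos) {
    chunk <- tolower(substr(seq, p, min(p + 59, nchar(seq))))
    grps <- sapply(seq(1, nchar(chunk), by = 10), function(q)
      substr(chunk, q, min(q + 9, nchar(chunk))))
    lines <- c(lines, sprintf("%9d %s", p, paste(grps, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
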