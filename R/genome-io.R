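#' Read genomes from a FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file into a
#' [GenomeSet-class]. The record ID is the first whitespace-delimited token
#' of each header line. Sequences are uppercased on loading; characters
#' outside `{A,C,G,T,N}` are rejected with the offending position.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @param topology `"circular"` or `"linear"`, recycled across records.
#' @param source provenance tag stored with each record.
#' @return A [GenomeSet-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 a phage", "acgt"), f)
#' readGenomeFasta(f)
#' @export
readGenomeFasta <- function(path, topology = "linear", source = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA header with empty ID")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate ID in %s: %s", path, ids[duplicated(ids)][1L]))
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  .check_dna_alphabet(seqs, ids)
  GenomeSet(seqs, topology = topology, source = source)
}

#' Write genomes to a FASTA file
#'
#' Multi-record FASTA, wrapped at 70 columns. Round-trips exactly with
#' [readGenomeFasta()].
#'
#' @param gs A [GenomeSet-class] (or named character vector of sequences).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(gs, path) {
  seqs <- if (is(gs, "GenomeSet")) gs@seqs else Biostrings::DNAStringSet(gs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read viromic reads from FASTA or FASTQ
#'
#' Format is auto-detected from the first non-empty character (`>` FASTA,
#' `@` FASTQ); gzip-compressed input is handled transparently. Qualities,
#' when present, are not retained: downstream filtering is length-based
#' only.
#'
#' @param path path to the read file.
#' @return A named [Biostrings::DNAStringSet] of reads.
#' @export
readViromeReads <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- gzfile(path, "r")
  first <- ""
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    if (nzchar(trimws(ln))) { first <- substr(trimws(ln), 1L, 1L); break }
  }
  close(con)
  if (first == "")
    stop(sprintf("empty read file: %s", path))
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                stop(sprintf("unrecognized read format in %s", path)))
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' G+C content of a sequence
#'
#' Fraction `(G + C) / (A + C + G + T)`; `N` bases are excluded from both
#' numerator and denominator. Invariant under reverse complement.
#'
#' @param x A [GenomeSet-class], [Biostrings::DNAStringSet], or character
#'   vector of DNA sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gcContent(c("ATGC", "GGCC"))
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' @rdname gcContent
#' @export
setMethod("gcContent", "GenomeSet", function(x) gcContent(x@seqs))

#' @rdname gcContent
#' @export
setMethod("gcContent", "DNAStringSet", function(x) {
  fr <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(fr)
  if (any(denom == 0))
    stop("GC content undefined: sequence contains no A/C/G/T")
  stats::setNames((fr[, "G"] + fr[, "C"]) / denom, names(x))
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "character", function(x)
  gcContent(Biostrings::DNAStringSet(toupper(x))))

#' Count CDS features in a GenBank flat file
#'
#' Minimal read-only GenBank support: counts `CDS` feature keys in the
#' FEATURES table of the (first) record.
#'
#' @param path path to a GenBank flat file.
#' @return Integer count of CDS features.
#' @export
countGenbankCDS <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines)))
    stop(sprintf("malformed GenBank file (no LOCUS line): %s", path))
  sum(grepl("^ {5}CDS( |$)", lines))
}

#' Extract the sequence of a GenBank record
#'
#' Parses the ORIGIN block of a GenBank flat file into an uppercase DNA
#' string. Topology is taken from the LOCUS line when present.
#'
#' @param path path to a GenBank flat file.
#' @param id identifier for the resulting record; defaults to the LOCUS name.
#' @return A [GenomeSet-class] with one genome.
#' @export
readGenbankGenome <- function(path, id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L)
    stop(sprintf("malformed GenBank file (no LOCUS line): %s", path))
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  if (is.null(id)) id <- toks[2L]
  topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  o <- grep("^ORIGIN", lines)
  if (length(o) == 0L) stop(sprintf("no ORIGIN block in %s", path))
  end <- grep("^//", lines)
  end <- end[end > o[1L]][1L]
  if (is.na(end)) end <- length(lines) + 1L
  body <- lines[(o[1L] + 1L):(end - 1L)]
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
  if (!nzchar(seq)) stop(sprintf("empty ORIGIN block in %s", path))
  GenomeSet(stats::setNames(seq, id), topology = topo, source = "genbank")
}

#' Extract a (possibly wrap-around) subsequence
#'
#' Coordinates are 0-based, half-open, on the forward strand. For circular
#' genomes `end` may exceed the genome length, meaning the interval wraps
#' the origin; the result is reverse-complemented when `strand` is `"-"`.
#'
#' @param gs A [GenomeSet-class].
#' @param id genome ID.
#' @param start,end 0-based half-open interval; `0 <= start < length`;
#'   `end <= length` for linear genomes, `end <= start + length` for
#'   circular ones.
#' @param strand `"+"` or `"-"`.
#' @return Character string with the extracted sequence.
#' @examples
#' gs <- GenomeSet(c(g = "ACGTAC"), topology = "circular")
#' extractSubseq(gs, "g", 4, 8)  # wraps: "ACAC"
#' @export
extractSubseq <- function(gs, id, start, end, strand = "+") {
  stopifnot(is(gs, "GenomeSet"), strand %in% c("+", "-"))
  seq <- genomeSeqs(gs, id)
  L <- nchar(seq)
  topo <- topology(gs)[[id]]
  if (start < 0 || start >= L) stop("start out of range")
  if (end <= start) stop("end must exceed start")
  if (end > L) {
    if (topo != "circular")
      stop(sprintf("interval [%d,%d) exceeds linear genome %s (length %d)",
                   start, end, id, L))
    if (end > start + L) stop("interval longer than the genome")
    out <- paste0(substr(seq, start + 1L, L), substr(seq, 1L, end - L))
  } else {
    out <- substr(seq, start + 1L, end)
  }
  if (strand == "-") out <- revcomp_chr(out)
  out
}
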