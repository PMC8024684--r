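#' @import methods
#' @importFrom Biostrings DNAStringSet width
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' GenomeSet: a collection of phage genome sequences
#'
#' Holds genome sequences together with their topology (circular or linear)
#' and a free-text provenance tag per record. Sequences are stored as a
#' [Biostrings::DNAStringSet] restricted to the alphabet `{A,C,G,T,N}`;
#' identifiers are the `names()` of that set and must be unique,
#' whitespace-free and non-empty.
#'
#' Coordinates on genomes are 0-based, half-open, forward-strand throughout
#' the package. On circular genomes an interval may wrap the origin, which is
#' represented by `end > length(genome)` (normalized modulo length).
#'
#' @slot seqs DNAStringSet of genome sequences (named).
#' @slot topology character vector, one of `"circular"` or `"linear"` per
#'   genome.
#' @slot source character vector, free-text provenance tag per genome
#'   (e.g. `"isolate"`, `"MVG"`, `"synthetic"`).
#'
#' @seealso [GenomeSet()] for construction, [readGenomeFasta()] for reading.
#' @exportClass GenomeSet
setClass("GenomeSet",
  slots = c(seqs = "DNAStringSet", topology = "character",
            source = "character"))

setValidity("GenomeSet", function(object) {
  n <- length(object@seqs)
  ids <- names(object@seqs)
  msgs <- character()
  if (is.null(ids) && n > 0L)
    msgs <- c(msgs, "genomes must be named")
  if (!is.null(ids)) {
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate genome ID: %s",
                              ids[duplicated(ids)][1L]))
    if (any(!nzchar(ids)) || any(grepl("\\s", ids)))
      msgs <- c(msgs, "genome IDs must be non-empty and whitespace-free")
  }
  if (length(object@topology) != n || length(object@source) != n)
    msgs <- c(msgs, "topology and source must match the number of genomes")
  if (!all(object@topology %in% c("circular", "linear")))
    msgs <- c(msgs, "topology must be 'circular' or 'linear'")
  if (n > 0L && any(Biostrings::width(object@seqs) < 1L))
    msgs <- c(msgs, "empty sequence not allowed")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeSet
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet]. Sequences
#'   are uppercased; characters outside `{A,C,G,T,N}` are rejected.
#' @param topology `"circular"` or `"linear"`, recycled across genomes.
#' @param source free-text provenance tag, recycled across genomes.
#' @return A [GenomeSet-class] object.
#' @examples
#' gs <- GenomeSet(c(g1 = "ACGTACGT"), topology = "circular")
#' genomeLengths(gs)
#' @export
GenomeSet <- function(seqs, topology = "linear", source = "") {
  if (is.character(seqs)) {
    seqs <- toupper(seqs)
    .check_dna_alphabet(seqs, names(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  } else {
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  }
  n <- length(seqs)
  new("GenomeSet", seqs = seqs,
      topology = rep_len(as.character(topology), n),
      source = rep_len(as.character(source), n))
}

.check_dna_alphabet <- function(x, ids = NULL) {
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    id <- if (!is.null(ids) && !is.na(ids[i])) ids[i] else paste0("record ", i)
    stop(sprintf("illegal character '%s' at position %d in %s",
                 substr(x[i], bad[i], bad[i]), bad[i], id))
  }
  invisible(TRUE)
}

#' @describeIn GenomeSet Number of genomes.
#' @param x A GenomeSet.
#' @export
setMethod("length", "GenomeSet", function(x) length(x@seqs))

#' @describeIn GenomeSet Genome identifiers.
#' @export
setMethod("names", "GenomeSet", function(x) names(x@seqs))

#' Subset a GenomeSet
#' @param x A GenomeSet.
#' @param i index vector (numeric, logical or genome IDs).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GenomeSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  if (is.logical(i)) i <- which(i)
  new("GenomeSet", seqs = x@seqs[i], topology = x@topology[i],
      source = x@source[i])
})

setMethod("show", "GenomeSet", function(object) {
  n <- length(object)
  cat(sprintf("GenomeSet with %d genome%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    k <- min(n, 6L)
    w <- Biostrings::width(object@seqs)
    for (i in seq_len(k))
      cat(sprintf("  %-30s %8d bp  %-8s %s\n", names(object@seqs)[i], w[i],
                  object@topology[i], object@source[i]))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
  invisible(NULL)
})

#' @rdname GenomeSet-accessors
#' @name GenomeSet-accessors
#' @title Accessors for GenomeSet
#' @param x A GenomeSet.
#' @param id optional genome ID to select a single record.
#' @return `genomeSeqs()` the DNAStringSet (or a single character string when
#'   `id` is given); `topology()` and `genomeSource()` character vectors;
#'   `genomeLengths()` named integer vector of sequence lengths in bp.
NULL

#' @rdname GenomeSet-accessors
#' @export
genomeSeqs <- function(x, id = NULL) {
  stopifnot(is(x, "GenomeSet"))
  if (is.null(id)) return(x@seqs)
  i <- match(id, names(x@seqs))
  if (is.na(i)) stop(sprintf("unknown genome ID '%s'", id))
  as.character(x@seqs[[i]])
}

#' @rdname GenomeSet-accessors
#' @export
topology <- function(x) {
  stopifnot(is(x, "GenomeSet"))
  stats::setNames(x@topology, names(x@seqs))
}

#' @rdname GenomeSet-accessors
#' @export
genomeSource <- function(x) {
  stopifnot(is(x, "GenomeSet"))
  stats::setNames(x@source, names(x@seqs))
}

#' @rdname GenomeSet-accessors
#' @export
genomeLengths <- function(x) {
  stopifnot(is(x, "GenomeSet"))
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
}

#' Combine two GenomeSets
#' @param x,y GenomeSet objects with disjoint IDs.
#' @return A GenomeSet holding both.
#' @export
combineGenomes <- function(x, y) {
  stopifnot(is(x, "GenomeSet"), is(y, "GenomeSet"))
  new("GenomeSet", seqs = c(x@seqs, y@seqs),
      topology = c(x@topology, y@topology),
      source = c(x@source, y@source))
}
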