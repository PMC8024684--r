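# internal helpers

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seed, kept under 2^31
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1103L + as.numeric(k) * 12347) %% 2147483629
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 128x128 ASCII-indexed BLOSUM62 with unknown residues mapped to X
blosum62_128 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    B <- data_env$BLOSUM62
    m <- matrix(0L, 128, 128)
    letters_all <- LETTERS
    xs <- B["X", "X"]
    for (a in letters_all) {
      for (b in letters_all) {
        aa <- if (a %in% rownames(B)) a else "X"
        bb <- if (b %in% colnames(B)) b else "X"
        m[utf8ToInt(a) + 1L, utf8ToInt(b) + 1L] <- as.integer(B[aa, bb])
      }
    }
    star <- utf8ToInt("*") + 1L
    m[star, ] <- as.integer(xs)
    m[, star] <- as.integer(xs)
    cache <<- m
    m
  }
})

empty_hits_df <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             s_strand = character(), length = integer(),
             identities = integer(), score = integer(),
             bitscore = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}
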