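#' Build orthologous groups by Markov clustering of a protein hit graph
#'
#' Builds an undirected similarity graph over proteins with edge weight
#' `-log10(max(E, 1e-180))`, symmetrized by averaging the two directed
#' E-value weights where both are present, and clusters it with Markov
#' clustering (MCL): expansion 2, the given inflation, column-stochastic
#' normalization with unit self-loops, pruning of entries below `prune`,
#' iterated to convergence. The connected components of the limit matrix
#' are the groups; proteins without any hit become singleton groups. The
#' result is a partition of the input protein universe.
#'
#' @param hits hit table with columns `query_id`, `subject_id`, `evalue`
#'   (already filtered at the retrieval thresholds, E <= 1e-3 and identity
#'   >= 0.25; see [allVsAllProteins()]).
#' @param protein_ids character vector of all protein IDs (the universe to
#'   partition, including proteins with no hits).
#' @param inflation MCL inflation parameter (default 1.5).
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence tolerance on the iteration matrix.
#' @param max_iter iteration cap.
#' @return A list of character vectors, one per orthogroup, each sorted;
#'   the list is ordered by first member and named `OG1`, `OG2`, ...
#' @export
buildOrthogroups <- function(hits, protein_ids, inflation = 1.5,
                             prune = 1e-6, tol = 1e-8, max_iter = 200L) {
  protein_ids <- unique(as.character(protein_ids))
  n <- length(protein_ids)
  if (n == 0L) stop("empty protein universe")
  if (nrow(hits) > 0L) {
    if (!all(hits$query_id %in% protein_ids) ||
        !all(hits$subject_id %in% protein_ids))
      stop("hit table mentions proteins outside the given universe")
    qi <- match(hits$query_id, protein_ids)
    sj <- match(hits$subject_id, protein_ids)
    w <- -log10(pmax(hits$evalue, 1e-180))
    off <- qi != sj
    qi <- qi[off]; sj <- sj[off]; w <- w[off]
    # average the two directions of each unordered pair
    lo <- pmin(qi, sj); hi <- pmax(qi, sj)
    key <- paste(lo, hi)
    wbar <- tapply(w, key, mean)
    pl <- as.integer(sub(" .*", "", names(wbar)))
    ph <- as.integer(sub(".* ", "", names(wbar)))
    # self-loops at each node's maximum incident weight (canonical MCL
    # regularization; unit loops for isolated nodes)
    loop <- rep(1, n)
    for (k in seq_along(wbar)) {
      loop[pl[k]] <- max(loop[pl[k]], wbar[k])
      loop[ph[k]] <- max(loop[ph[k]], wbar[k])
    }
    adj <- Matrix::sparseMatrix(i = c(pl, ph, seq_len(n)),
                                j = c(ph, pl, seq_len(n)),
                                x = c(wbar, wbar, loop),
                                dims = c(n, n))
  } else {
    adj <- Matrix::Diagonal(n, 1)
  }
  M <- .mcl_limit(adj, inflation, prune, tol, max_iter)
  supp <- methods::as(M, "generalMatrix")
  g <- igraph::graph_from_adjacency_matrix(abs(supp) + Matrix::t(abs(supp)),
                                           mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)$membership
  groups <- split(protein_ids, comp)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  names(groups) <- paste0("OG", seq_along(groups))
  groups
}

.mcl_limit <- function(adj, inflation, prune, tol, max_iter) {
  norm_cols <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- norm_cols(methods::as(adj, "dMatrix"))
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                    # expansion 2
    M2 <- methods::as(M2, "CsparseMatrix")
    M2@x <- M2@x^inflation           # inflation
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- norm_cols(M2)
    if (max(abs(M2 - M)) < tol) return(M2)
    M <- M2
  }
  M
}

#' Orthogroup membership of each protein
#'
#' @param groups orthogroup list from [buildOrthogroups()].
#' @return Named character vector mapping protein ID to group name.
#' @export
orthogroupMembership <- function(groups) {
  stats::setNames(rep(names(groups), lengths(groups)),
                  unlist(groups, use.names = FALSE))
}

#' Fraction of reference genes shared with a contig
#'
#' The fraction of the reference genome's genes whose orthogroup contains
#' at least one gene of the contig. This uses the reference gene count as
#' the denominator (robust to contig truncation); pass
#' `denominator = "contig"` for the other convention.
#'
#' @param reference_id,contig_id genome IDs.
#' @param groups orthogroup list from [buildOrthogroups()].
#' @param gene_genomes named character vector mapping protein ID to genome
#'   ID; by default derived by stripping the trailing `"_<index>"` from
#'   protein IDs as produced by [callOrfs()].
#' @param denominator `"reference"` (default) or `"contig"`.
#' @return Shared gene fraction in `[0, 1]`.
#' @export
sharedGeneFraction <- function(reference_id, contig_id, groups,
                               gene_genomes = NULL,
                               denominator = c("reference", "contig")) {
  denominator <- match.arg(denominator)
  all_prot <- unlist(groups, use.names = FALSE)
  if (is.null(gene_genomes))
    gene_genomes <- stats::setNames(sub("_[0-9]+$", "", all_prot), all_prot)
  if (denominator == "contig") {
    tmp <- reference_id; reference_id <- contig_id; contig_id <- tmp
  }
  ref_prot <- all_prot[gene_genomes[all_prot] == reference_id]
  if (length(ref_prot) == 0L)
    stop(sprintf("genome %s has no genes in the grouping", reference_id))
  membership <- orthogroupMembership(groups)
  contig_groups <- unique(membership[gene_genomes[all_prot] == contig_id])
  mean(membership[ref_prot] %in% contig_groups)
}

#' Classify contigs as group members
#'
#' A contig belongs to the reference-defined phage group when it shares at
#' least `min_fraction` of the reference genes (via orthologous groups) and
#' is at least `min_len` bp long; both thresholds are inclusive.
#'
#' @param contig_id character vector of contig IDs.
#' @param length_bp integer vector of contig lengths (N bases counted).
#' @param shared_fraction shared gene fraction per contig, from
#'   [sharedGeneFraction()].
#' @param min_fraction,min_len inclusive thresholds (defaults 0.40 and
#'   25000 bp).
#' @return data.frame: `contig_id`, `length_bp`, `shared_fraction`,
#'   `is_member`.
#' @examples
#' classifyMvg("c1", 25000, 0.40)   # boundary case: member
#' @export
classifyMvg <- function(contig_id, length_bp, shared_fraction,
                        min_fraction = 0.40, min_len = 25000L) {
  stopifnot(all(shared_fraction >= 0 & shared_fraction <= 1))
  data.frame(contig_id = contig_id, length_bp = as.integer(length_bp),
             shared_fraction = shared_fraction,
             is_member = shared_fraction >= min_fraction - 1e-12 &
               length_bp >= min_len,
             stringsAsFactors = FALSE)
}

#' Fragment-based average nucleotide identity
#'
#' The first genome is cut into consecutive non-overlapping windows of
#' `frag_len` bp (the trailing partial window is dropped); each fragment is
#' aligned to the second genome with the seeded nucleotide aligner, and
#' fragments whose best hit spans at least `frag_cov` of the fragment count
#' as aligned. The directional ANI is the mean identity fraction of aligned
#' fragments; the reported ANI averages the two directions (using the
#' defined one when only one direction has aligned fragments, `NA` when
#' neither does).
#'
#' @param gs A [GenomeSet-class].
#' @param id_a,id_b genome IDs (both at least `frag_len` bp).
#' @param frag_len fragment length (default 1000).
#' @param frag_cov fraction of a fragment its best hit must span to count
#'   as aligned (default 0.70).
#' @param seed_k seed length passed to the nucleotide aligner.
#' @return A list: `genome_a`, `genome_b`, `ani` (fraction or `NA`),
#'   `aligned_fragments`, `total_fragments` (both summed over the two
#'   directions).
#' @export
computeANI <- function(gs, id_a, id_b, frag_len = 1000L, frag_cov = 0.70,
                       seed_k = 11L) {
  a <- genomeSeqs(gs, id_a); b <- genomeSeqs(gs, id_b)
  if (nchar(a) < frag_len || nchar(b) < frag_len)
    stop(sprintf("genomes must be at least frag_len=%d bp", frag_len))
  one_dir <- function(q, s) {
    nf <- nchar(q) %/% frag_len
    starts <- (seq_len(nf) - 1L) * frag_len
    frags <- substring(q, starts + 1L, starts + frag_len)
    h <- cpp_recruit_batch(frags, s, as.integer(seed_k), 2L, 3L, 5L, 2L, 8L,
                           0.0, 0.0)
    if (nrow(h) == 0L) return(list(n = nf, aligned = 0L, ids = numeric(0)))
    span <- (h$q_end - h$q_start) / frag_len
    ok <- span >= frag_cov
    list(n = nf, aligned = sum(ok),
         ids = (h$identities / h$length)[ok])
  }
  d1 <- one_dir(a, b)
  d2 <- one_dir(b, a)
  anis <- c(if (d1$aligned > 0) mean(d1$ids),
            if (d2$aligned > 0) mean(d2$ids))
  list(genome_a = id_a, genome_b = id_b,
       ani = if (length(anis)) mean(anis) else NA_real_,
       aligned_fragments = d1$aligned + d2$aligned,
       total_fragments = d1$n + d2$n)
}

#' Pairwise ANI matrix
#'
#' @inheritParams computeANI
#' @return Symmetric matrix of ANI values (`NA` where undefined), unit
#'   diagonal.
#' @export
aniMatrix <- function(gs, frag_len = 1000L, frag_cov = 0.70, seed_k = 11L) {
  ids <- names(gs)
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- computeANI(gs, ids[i], ids[j], frag_len, frag_cov, seed_k)
      m[i, j] <- m[j, i] <- r$ani
    }
  }
  m
}

#' Dereplicate genomes at an ANI threshold
#'
#' Single-linkage clusters over genome pairs with defined ANI at or above
#' `ani_threshold`; within each cluster only the longest genome is kept
#' (ties broken by lexicographically smallest ID). Idempotent.
#'
#' @param gs A [GenomeSet-class] (at least one genome).
#' @param ani_threshold clustering threshold (default 0.70).
#' @param ani optional precomputed ANI matrix from [aniMatrix()]; computed
#'   when omitted.
#' @param ... passed to [aniMatrix()].
#' @return Character vector of representative genome IDs, in input order.
#' @export
dereplicateGenomes <- function(gs, ani_threshold = 0.70, ani = NULL, ...) {
  ids <- names(gs)
  if (length(ids) == 0L) stop("empty genome set")
  if (length(ids) == 1L) return(ids)
  if (is.null(ani)) ani <- aniMatrix(gs, ...)
  ani <- ani[ids, ids]
  linked <- !is.na(ani) & ani >= ani_threshold - 1e-12
  diag(linked) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  comp <- igraph::components(g)$membership
  lens <- genomeLengths(gs)
  reps <- vapply(split(ids, comp), function(members) {
    members[order(-lens[members], members)][1L]
  }, character(1))
  ids[ids %in% reps]
}

#' Write grouping outputs
#'
#' @param groups orthogroup list ([buildOrthogroups()]).
#' @param decisions decision table ([classifyMvg()]).
#' @param ani ANI matrix ([aniMatrix()]).
#' @param reps representative IDs ([dereplicateGenomes()]).
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeGroupingOutputs <- function(groups = NULL, decisions = NULL, ani = NULL,
                                 reps = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(groups)) {
    df <- data.frame(group_id = names(groups),
                     members = vapply(groups, paste, character(1),
                                      collapse = ","))
    utils::write.table(df, file.path(dir, "orthogroups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(decisions))
    utils::write.table(decisions, file.path(dir, "membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ani))
    utils::write.table(data.frame(genome = rownames(ani), ani,
                                  check.names = FALSE),
                       file.path(dir, "ani_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(reps))
    writeLines(reps, file.path(dir, "representatives.txt"))
  invisible(dir)
}
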