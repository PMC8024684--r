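#' Corrected marker distance between two proteins
#'
#' Distance used for marker (e.g. large terminase subunit) trees:
#' `p = 1 - identities/length` over the optimal local alignment, corrected
#' as `-ln(1 - p)` (Poisson) and capped at 5.0. Unalignable pairs (no
#' positive-scoring local alignment) receive the cap.
#'
#' @param p1,p2 protein sequences.
#' @param cap maximum distance (default 5.0).
#' @return Non-negative distance.
#' @examples
#' markerDistance("MKVLAW", "MKVLAW")   # 0
#' @export
markerDistance <- function(p1, p2, cap = 5.0) {
  h <- alignProteinLocal(p1, p2)
  if (is.null(h)) return(cap)
  p <- 1 - h$identities / h$length
  min(-log(max(1 - p, exp(-cap))), cap)
}

#' Pairwise marker distance matrix
#'
#' @param proteins named character vector of marker proteins.
#' @param cap distance cap.
#' @return Symmetric matrix with zero diagonal.
#' @export
markerDistanceMatrix <- function(proteins, cap = 5.0) {
  ids <- names(proteins) %||% paste0("p", seq_along(proteins))
  n <- length(proteins)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- markerDistance(proteins[[i]], proteins[[j]], cap)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining. Negative branch lengths are
#' clamped to zero; ties in the Q criterion are broken by the
#' lexicographically smallest pair of subtree labels (a subtree is labelled
#' by its smallest leaf), so the result is deterministic. The returned tree
#' is unrooted (trifurcating root node in the `phylo` encoding).
#'
#' @param d symmetric distance matrix with labelled rows/columns, `n >= 3`.
#' @return An [ape::read.tree] `phylo` object.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighborJoining(d)
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite, >= 0")
  nwk <- as.list(labels)       # newick fragment per active node
  minlab <- labels             # smallest leaf label per active node
  active <- seq_len(n)
  D <- d
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        lab <- sort(c(minlab[i], minlab[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (lab[1L] < best$lab[1L] ||
              (lab[1L] == best$lab[1L] && lab[2L] < best$lab[2L])))) {
          best <- list(q = q, i = i, j = j, lab = lab)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[[i]], fmt(li), nwk[[j]], fmt(lj))
    new_min <- min(minlab[i], minlab[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    minlab <- c(minlab[keep], new_min)
    active <- seq_len(m - 1L)
  }
  # final trifurcation via the three-point formulas
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[[1]], fmt(l1),
                 nwk[[2]], fmt(l2), nwk[[3]], fmt(l3))
  ape::read.tree(text = txt)
}

#' Marker tree without bootstrap
#'
#' Neighbor joining on the [markerDistanceMatrix()] of the given proteins.
#'
#' @inheritParams markerDistanceMatrix
#' @return A `phylo` tree.
#' @export
markerTree <- function(proteins, cap = 5.0) {
  neighborJoining(markerDistanceMatrix(proteins, cap))
}

# ---- progressive profile MSA ---------------------------------------------

.AA_ALPHA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V","X")

.aa_submatrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    cache <<- env$BLOSUM62[.AA_ALPHA, .AA_ALPHA]
    cache
  }
})

.profile_of <- function(aln) {
  # aln: character matrix (seqs x columns); returns 21 x columns frequency
  nr <- nrow(aln)
  apply(aln, 2L, function(col) {
    col[!(col %in% .AA_ALPHA) & col != "-"] <- "X"
    tab <- table(factor(col[col != "-"], levels = .AA_ALPHA))
    as.numeric(tab) / nr
  })
}

# global profile-profile alignment with affine gaps; returns merged matrix
.merge_alignments <- function(A, B, go = 11, ge = 1) {
  PA <- .profile_of(A); PB <- .profile_of(B)
  S <- t(PA) %*% .aa_submatrix() %*% PB
  ca <- ncol(A); cb <- ncol(B)
  NEG <- -1e9
  H <- matrix(NEG, ca + 1L, cb + 1L)
  E <- matrix(NEG, ca + 1L, cb + 1L)  # gap in A-profile (consume B)
  F_ <- matrix(NEG, ca + 1L, cb + 1L) # gap in B-profile (consume A)
  tb <- matrix(0L, ca + 1L, cb + 1L)  # 1 diag, 2 up(consume A), 3 left(consume B)
  H[1L, 1L] <- 0
  for (j in seq_len(cb)) {
    E[1L, j + 1L] <- -go - ge * j
    H[1L, j + 1L] <- E[1L, j + 1L]
    tb[1L, j + 1L] <- 3L
  }
  for (i in seq_len(ca)) {
    F_[i + 1L, 1L] <- -go - ge * i
    H[i + 1L, 1L] <- F_[i + 1L, 1L]
    tb[i + 1L, 1L] <- 2L
    for (j in seq_len(cb)) {
      e <- max(H[i + 1L, j] - go - ge, E[i + 1L, j] - ge)
      f <- max(H[i, j + 1L] - go - ge, F_[i, j + 1L] - ge)
      dg <- H[i, j] + S[i, j]
      h <- dg; t <- 1L
      if (f > h) { h <- f; t <- 2L }
      if (e > h) { h <- e; t <- 3L }
      H[i + 1L, j + 1L] <- h
      E[i + 1L, j + 1L] <- e
      F_[i + 1L, j + 1L] <- f
      tb[i + 1L, j + 1L] <- t
    }
  }
  # traceback
  i <- ca; j <- cb
  colsA <- integer(0); colsB <- integer(0) # 0 = gap column
  while (i > 0L || j > 0L) {
    t <- tb[i + 1L, j + 1L]
    if (t == 1L) { colsA <- c(i, colsA); colsB <- c(j, colsB); i <- i - 1L; j <- j - 1L }
    else if (t == 2L) { colsA <- c(i, colsA); colsB <- c(0L, colsB); i <- i - 1L }
    else { colsA <- c(0L, colsA); colsB <- c(j, colsB); j <- j - 1L }
  }
  take <- function(M, cols) {
    out <- matrix("-", nrow(M), length(cols))
    nz <- cols > 0L
    out[, nz] <- M[, cols[nz], drop = FALSE]
    rownames(out) <- rownames(M)
    out
  }
  rbind(take(A, colsA), take(B, colsB))
}

#' Progressive multiple alignment of marker proteins
#'
#' Profile-profile progressive alignment (BLOSUM62, affine gaps 11/1) along
#' a midpoint-rooted neighbor-joining guide tree built from
#' [markerDistanceMatrix()].
#'
#' @param proteins named character vector (>= 2 sequences).
#' @return Character matrix (sequences x alignment columns) with sequence
#'   IDs as rownames.
#' @export
progressiveMSA <- function(proteins) {
  ids <- names(proteins) %||% paste0("p", seq_along(proteins))
  names(proteins) <- ids
  n <- length(proteins)
  if (n < 2L) stop("need at least 2 sequences")
  as_mat <- function(id) {
    m <- matrix(strsplit(toupper(proteins[[id]]), "")[[1L]], nrow = 1L)
    rownames(m) <- id
    m
  }
  if (n == 2L) return(.merge_alignments(as_mat(ids[1L]), as_mat(ids[2L])))
  guide <- neighborJoining(markerDistanceMatrix(proteins))
  guide <- phangorn::midpoint(guide)
  align_node <- function(node) {
    nt <- length(guide$tip.label)
    if (node <= nt) return(as_mat(guide$tip.label[node]))
    kids <- guide$edge[guide$edge[, 1L] == node, 2L]
    aln <- align_node(kids[1L])
    for (k in kids[-1L]) aln <- .merge_alignments(aln, align_node(k))
    aln
  }
  root <- length(guide$tip.label) + 1L
  aln <- align_node(root)
  aln[ids[ids %in% rownames(aln)], , drop = FALSE]
}

# Poisson-corrected pairwise distances from an alignment (optionally a
# column subset); pairs with no shared ungapped column get the cap.
.msa_distances <- function(aln, cols = NULL, cap = 5.0) {
  if (!is.null(cols)) aln <- aln[, cols, drop = FALSE]
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- aln[i, ] != "-" & aln[j, ] != "-"
      if (!any(ok)) { d[i, j] <- d[j, i] <- cap; next }
      p <- mean(aln[i, ok] != aln[j, ok])
      d[i, j] <- d[j, i] <- min(-log(max(1 - p, exp(-cap))), cap)
    }
  }
  d
}

# canonical bipartition keys for every internal non-root node of a phylo
.bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  total <- nt + tree$Nnode
  desc <- vector("list", total)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1L]; ch <- eo[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  anchor <- min(tree$tip.label)
  root <- nt + 1L
  nodes <- setdiff((nt + 1L):total, root)
  keys <- vapply(nodes, function(nd) {
    side <- desc[[nd]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "\r")
  }, character(1))
  names(keys) <- nodes
  # only informative bipartitions (>= 2 tips on each side)
  sizes <- vapply(nodes, function(nd) length(desc[[nd]]), integer(1))
  keys[sizes >= 2L & sizes <= nt - 2L]
}

#' Bootstrapped marker tree
#'
#' Builds a progressive multiple alignment of the marker proteins, a
#' neighbor-joining tree from its Poisson-corrected distances, and
#' bootstrap supports: alignment columns are resampled with replacement
#' `n_reps` times (seeded, reproducible), a tree is built per replicate,
#' and each internal bipartition of the full-data tree is annotated with
#' the percentage of replicates containing it (stored in `node.label`;
#' the root label is empty, as is any uninformative node).
#'
#' @param proteins named character vector of at least 4 sequences.
#' @param n_reps bootstrap replicates (default 100; 0 returns the tree
#'   without support annotations).
#' @param seed RNG seed for column resampling.
#' @return A `phylo` tree with `node.label` supports in `[0, 100]`.
#' @export
bootstrapMarkerTree <- function(proteins, n_reps = 100L, seed = 1L) {
  if (length(proteins) < 4L)
    stop("bootstrap needs at least 4 sequences (no internal bipartition)")
  aln <- progressiveMSA(proteins)
  full <- neighborJoining(.msa_distances(aln))
  if (n_reps == 0L) return(full)
  keys <- .bipartitions(full)
  counts <- stats::setNames(numeric(length(keys)), keys)
  nc <- ncol(aln)
  with_seed_(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      rep_tree <- neighborJoining(.msa_distances(aln, cols))
      rk <- .bipartitions(rep_tree)
      hit <- keys %in% rk
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- round(100 * counts / n_reps)
  labs <- character(full$Nnode)
  nt <- length(full$tip.label)
  idx <- as.integer(names(keys)) - nt
  labs[idx] <- as.character(supports)
  full$node.label <- labs
  full
}

#' Whole-proteome genome distance
#'
#' All-vs-all protein hits between the two proteomes (retrieval thresholds
#' E <= 1e-3, identity >= 0.25) are reduced greedily to a set of
#' non-conflicting best hits (each protein used at most once, highest score
#' first); the distance is `1 - 2 * sum(identities) / (Na + Nb)` where `Na`
#' and `Nb` are the total proteome residue counts, clamped to `[0, 1]`.
#' Zero iff the proteomes align perfectly; symmetric.
#'
#' @param prot_a,prot_b named character vectors of the two proteomes
#'   (non-empty).
#' @param e_max,id_min,word_size hit thresholds, as [allVsAllProteins()].
#' @return Distance in `[0, 1]`.
#' @export
genomeDistance <- function(prot_a, prot_b, e_max = 1e-3, id_min = 0.25,
                           word_size = 4L) {
  if (length(prot_a) == 0L || length(prot_b) == 0L)
    stop("empty proteome")
  h <- allVsAllProteins(prot_a, prot_b, e_max = e_max, id_min = id_min,
                        word_size = word_size)
  Na <- sum(nchar(prot_a)); Nb <- sum(nchar(prot_b))
  if (nrow(h) == 0L) return(1)
  h <- h[order(-h$score, h$query_id, h$subject_id), , drop = FALSE]
  used_q <- character(0); used_s <- character(0)
  tot <- 0
  for (k in seq_len(nrow(h))) {
    if (h$query_id[k] %in% used_q || h$subject_id[k] %in% used_s) next
    used_q <- c(used_q, h$query_id[k])
    used_s <- c(used_s, h$subject_id[k])
    tot <- tot + h$identities[k]
  }
  min(max(1 - 2 * tot / (Na + Nb), 0), 1)
}

#' Pairwise whole-proteome distance matrix
#'
#' @param genes gene table from [callOrfs()] covering several genomes.
#' @param ... passed to [genomeDistance()].
#' @return Symmetric matrix over the genome IDs present in `genes`.
#' @export
genomeDistanceMatrix <- function(genes, ...) {
  prot <- split(stats::setNames(genes$protein, genes$protein_id),
                genes$genome_id)
  ids <- names(prot)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- genomeDistance(prot[[i]], prot[[j]], ...)
  d
}

#' Cut a distance matrix into rank-level clusters
#'
#' Single-linkage clusters over pairs with distance at or below the
#' threshold. Monotone in the threshold (clusters only merge as it
#' increases).
#'
#' @param d symmetric distance matrix.
#' @param threshold clustering threshold in `[0, 1]` (package defaults:
#'   0.6 for genus, 0.9 for subfamily on the whole-proteome distance).
#' @param rank label stored in the output (`"genus"` or `"subfamily"`).
#' @return data.frame: `label`, `rank`, `cluster_id` (clusters numbered by
#'   first appearance).
#' @export
rankPartition <- function(d, threshold, rank = c("genus", "subfamily")) {
  rank <- match.arg(rank)
  stopifnot(threshold >= 0, threshold <= 1)
  d <- as.matrix(d)
  labels <- rownames(d)
  linked <- d <= threshold + 1e-12
  diag(linked) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  comp <- igraph::components(g)$membership
  cluster_id <- match(comp, unique(comp))
  data.frame(label = labels, rank = rank, cluster_id = cluster_id,
             stringsAsFactors = FALSE)
}
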