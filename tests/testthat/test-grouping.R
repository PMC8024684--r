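# helper: hit table for an explicit undirected edge list (strong E-values)
edges_to_hits <- function(edges, evalue = 1e-50) {
  data.frame(query_id = edges[, 1], subject_id = edges[, 2],
             evalue = evalue, stringsAsFactors = FALSE)
}

test_that("Markov clustering of disconnected cliques equals components", {
  cliq <- function(ids) t(combn(ids, 2))
  edges <- rbind(cliq(c("a1", "a2", "a3")), cliq(c("b1", "b2", "b3")))
  ids <- c(paste0("a", 1:3), paste0("b", 1:3))
  groups <- buildOrthogroups(edges_to_hits(edges), ids)
  expect_equal(length(groups), 2L)
  expect_equal(unname(sort(lengths(groups))), c(3L, 3L))
  # independent oracle: graph components
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  oracle <- unname(lapply(split(names(comp), comp), sort))
  expect_setequal(lapply(groups, unname), oracle)

  # random clique graphs: MCL groups equal connected components
  set.seed(404)
  for (rep in 1:5) {
    sizes <- c(sample(2:5, sample(2:3, 1), replace = TRUE), 1L)
    ids <- unlist(lapply(seq_along(sizes), function(k)
      paste0("c", k, "_", seq_len(sizes[k]))))
    edges <- do.call(rbind, lapply(seq_along(sizes), function(k) {
      m <- paste0("c", k, "_", seq_len(sizes[k]))
      if (length(m) < 2) NULL else t(combn(m, 2))
    }))
    groups <- buildOrthogroups(edges_to_hits(edges), ids)
    gg <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gg <- gg + igraph::vertices(setdiff(ids, igraph::V(gg)$name))
    oracle <- unname(lapply(split(ids, igraph::components(gg)$membership[ids]),
                            sort))
    expect_setequal(lapply(groups, unname), oracle)
  }
})

test_that("orthogroups handle no-hit and single-edge graphs", {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric())
  groups <- buildOrthogroups(empty, c("p1", "p2", "p3"))
  expect_equal(length(groups), 3L)
  expect_true(all(lengths(groups) == 1L))

  one <- buildOrthogroups(edges_to_hits(cbind("p1", "p2")), c("p1", "p2"))
  expect_equal(length(one), 1L)
  expect_setequal(one[[1]], c("p1", "p2"))
})

test_that("orthogroups always partition the protein universe", {
  fx <- study_fixture()
  all_members <- unlist(fx$groups, use.names = FALSE)
  expect_equal(sort(all_members), sort(unique(fx$genes$protein_id)))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("shared gene fraction counts reference genes with orthologs", {
  # constructed grouping: 55 reference genes, contig matches 22 of them
  groups <- c(
    lapply(1:22, function(i) c(sprintf("R_%d", i), sprintf("C_%d", i))),
    lapply(23:55, function(i) sprintf("R_%d", i)),
    lapply(23:40, function(i) sprintf("C_%d", i)))
  names(groups) <- paste0("OG", seq_along(groups))
  gmap <- stats::setNames(rep(c("R", "C"), c(55, 40)),
                          c(sprintf("R_%d", 1:55), sprintf("C_%d", 1:40)))
  expect_equal(sharedGeneFraction("R", "C", groups, gmap), 22 / 55)
  expect_equal(sharedGeneFraction("R", "R", groups, gmap), 1.0)
  # contig with no shared groups
  expect_equal(sharedGeneFraction("R", "Z",
                                  c(groups, list(OGZ = "Z_1")),
                                  c(gmap, Z_1 = "Z")), 0.0)
  expect_error(sharedGeneFraction("missing", "C", groups, gmap), "no genes")
})

test_that("membership thresholds are inclusive and monotone", {
  expect_true(classifyMvg("c", 25000, 0.40)$is_member)
  expect_false(classifyMvg("c", 30000, 0.39)$is_member)
  expect_false(classifyMvg("c", 24999, 0.80)$is_member)
  expect_false(classifyMvg("c", 25000, 0.399)$is_member)
  # monotonicity: raising fraction or length never flips member -> not
  set.seed(9)
  for (i in 1:50) {
    fr <- runif(1); len <- sample(20000:40000, 1)
    m1 <- classifyMvg("c", len, fr)$is_member
    m2 <- classifyMvg("c", len + sample(0:5000, 1), min(1, fr + runif(1, 0, 0.3)))$is_member
    if (m1) expect_true(m2)
  }
})

test_that("fragment ANI recovers planted divergence", {
  ref <- makeReferenceGenome(61, length = 12000, n_genes = 10, id = "A")
  gs_same <- combineGenomes(ref$genome,
                            GenomeSet(stats::setNames(genomeSeqs(ref$genome, "A"), "B"),
                                      topology = "circular"))
  r <- computeANI(gs_same, "A", "B")
  expect_equal(r$ani, 1.0)
  expect_equal(r$aligned_fragments, r$total_fragments)
  expect_equal(r$total_fragments, 24L)  # 12 windows per direction

  ev <- evolveGenome(ref, 0.10, 1.0, seed = 62, id = "C")
  gs_div <- combineGenomes(ref$genome, ev$genome)
  r2 <- computeANI(gs_div, "A", "C")
  expect_gte(r2$ani, 0.88)
  expect_lte(r2$ani, 0.92)

  # independent random genomes share no qualifying fragment
  other <- makeReferenceGenome(63, length = 12000, n_genes = 10, id = "D")
  gs_un <- combineGenomes(ref$genome, other$genome)
  r3 <- computeANI(gs_un, "A", "D")
  expect_equal(r3$aligned_fragments, 0L)
  expect_true(is.na(r3$ani))

  expect_error(computeANI(gs_un, "A", "D", frag_len = 50000), "frag_len")
})

test_that("dereplication keeps the longest, links transitively, idempotent", {
  # one genome: itself
  g1 <- makeReferenceGenome(71, length = 6000, n_genes = 5, id = "solo")
  expect_equal(dereplicateGenomes(g1$genome), "solo")

  # identical sequences of different lengths: the longest wins
  set.seed(72)
  s <- random_dna(30000)
  pair <- GenomeSet(c(g_long = s, g_short = substr(s, 1, 26000)))
  expect_equal(dereplicateGenomes(pair), "g_long")

  # transitive chain a~b, b~c with a-c below threshold: one cluster
  base <- makeReferenceGenome(73, length = 15000, n_genes = 12, id = "b")
  a <- evolveGenome(base, 0.22, 1.0, seed = 74, id = "a")
  c_ <- evolveGenome(base, 0.22, 1.0, seed = 75, id = "c")
  trio <- combineGenomes(combineGenomes(a$genome, base$genome), c_$genome)
  ani <- aniMatrix(trio)
  expect_gte(ani["a", "b"], 0.70)
  expect_gte(ani["b", "c"], 0.70)
  expect_lt(ani["a", "c"], 0.70)
  reps <- dereplicateGenomes(trio, ani = ani)
  expect_equal(length(reps), 1L)

  # idempotence
  reps2 <- dereplicateGenomes(trio[reps])
  expect_equal(reps2, reps)
})
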