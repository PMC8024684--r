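test_that("marker distances follow the corrected-p formula and cap", {
  p <- random_protein(80)
  expect_equal(markerDistance(p, p), 0.0)

  set.seed(111)
  hom <- mutate_protein(p, 30)
  h <- alignProteinLocal(p, hom)
  p_obs <- 1 - h$identities / h$length
  expect_equal(markerDistance(p, hom), -log(1 - p_obs))

  # unalignable pair gets the cap
  expect_equal(markerDistance("AAAAAAAA", "TTTTTTTT"), 5.0)
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  expect_s3_class(tr, "phylo")
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighborJoining(d[1:2, 1:2]), "at least 3")

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tz <- neighborJoining(z)
  expect_true(all(tz$edge.length == 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(222)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    est <- neighborJoining(D)
    # topology identical (RF distance 0) and path lengths reproduced
    expect_equal(phangorn::RF.dist(est, true), 0)
    De <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(De, D, tolerance = 1e-6)
    # cross-check against an established NJ implementation
    ape_tree <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(est, ape_tree), 0)
  }
})

test_that("tree serializes to Newick and re-parses identically", {
  fx <- study_fixture()
  tr <- neighborJoining(fx$D)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(phangorn::RF.dist(back, tr), 0)
})

test_that("bootstrap supports a planted pairing with 100 and is seeded", {
  set.seed(333)
  a <- random_protein(60)
  b <- mutate_protein(a, 40)  # strongly divergent partner family
  prots <- c(x1 = a, x2 = a, y1 = b, y2 = b)
  tr <- bootstrapMarkerTree(prots, n_reps = 30, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup == 100, na.rm = TRUE))

  tr2 <- bootstrapMarkerTree(prots, n_reps = 30, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  tr0 <- bootstrapMarkerTree(prots, n_reps = 0, seed = 5)
  expect_null(tr0$node.label)

  expect_error(bootstrapMarkerTree(prots[1:3], n_reps = 10), "at least 4")
})

test_that("whole-proteome distance is a [0,1] metric-like quantity", {
  set.seed(444)
  prots <- stats::setNames(sapply(c(80, 120, 100), random_protein),
                           c("p1", "p2", "p3"))
  expect_equal(genomeDistance(prots, prots), 0.0)

  # unalignable proteomes sit at the maximum
  away <- c(q1 = strrep("K", 90), q2 = strrep("D", 70))
  expect_equal(genomeDistance(c(a1 = strrep("G", 80)), away), 1.0)
  expect_error(genomeDistance(character(0), prots), "empty")

  # distance increases with planted divergence
  ref <- makeReferenceGenome(91, length = 9000, n_genes = 8, id = "R0")
  lows <- lapply(c(0.03, 0.12, 0.30), function(d)
    evolveGenome(ref, d, 1.0, seed = 92, id = sprintf("E%02.0f", d * 100)))
  ref_prot <- stats::setNames(ref$genes$protein, ref$genes$protein_id)
  dists <- vapply(lows, function(e) {
    genes <- callOrfs(e$genome)
    genomeDistance(ref_prot,
                   stats::setNames(genes$protein, genes$protein_id))
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("rank partition cuts single-linkage clusters monotonically", {
  fx <- study_fixture()
  d <- fx$D
  all_one <- rankPartition(d, 1.0, "subfamily")
  expect_equal(length(unique(all_one$cluster_id)), 1L)
  singles <- rankPartition(d, 0.0, "genus")
  expect_equal(length(unique(singles$cluster_id)), nrow(d))

  # clusters only merge as the threshold grows
  prev <- nrow(d) + 1L
  for (th in c(0, 0.2, 0.4, 0.6, 0.8, 1.0)) {
    k <- length(unique(rankPartition(d, th, "genus")$cluster_id))
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("marker and genome trees isolate the planted far genome", {
  fx <- study_fixture()
  mt <- markerTree(fx$markers)
  gt <- neighborJoining(fx$D)
  isolated <- function(tree, far) {
    co <- ape::cophenetic.phylo(tree)
    others <- setdiff(rownames(co), far)
    min(co[far, others]) > max(co[others, others])
  }
  expect_true(isolated(mt, "MVG12"))
  expect_true(isolated(gt, "MVG12"))
})
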