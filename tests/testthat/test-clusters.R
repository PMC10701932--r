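test_that("a four-gene tandem arrangement forms one cluster", {
  ann <- trnaAnnotation("chr5", c(1, 421, 841, 1261), c(72, 492, 912, 1332),
                        "+", paste0("AT5G2085", c(8, 6, 4, 2)))
  cl <- findClusters(ann)
  expect_length(cl, 1)
  expect_length(clusterGenes(cl[[1]]), 4)
  expect_equal(classifyOrientation(cl[[1]]), "head_to_tail")
  expect_equal(spacerLengths(cl[[1]]), rep(348L, 3))
})

test_that("spacer lengths follow the between-gene base-count convention", {
  # genes occupying bases 1-70 and 205-274 are separated by 134 bp
  cl2 <- findClusters(trnaAnnotation("chr2", c(1, 205), c(70, 274),
                                     c("-", "+"), c("a", "b")))
  expect_equal(spacerLengths(cl2[[1]]), 134L)
  expect_equal(classifyOrientation(cl2[[1]]), "head_to_head")
  # immediately adjacent genes: spacer 0
  cl0 <- findClusters(trnaAnnotation("c", c(1, 71), c(70, 140), "+", c("a", "b")))
  expect_equal(spacerLengths(cl0[[1]]), 0L)
  expect_false(hasOverlap(cl0[[1]]))
  # overlapping genes: negative spacer, overlap flag
  clo <- findClusters(trnaAnnotation("c", c(1, 61), c(70, 130), "+", c("a", "b")))
  expect_equal(spacerLengths(clo[[1]]), -10L)
  expect_true(hasOverlap(clo[[1]]))
})

test_that("the gap rule splits runs and minGenes drops singletons", {
  # gaps 500 and 1500 around 70 bp genes
  s <- c(1, 571, 2141)
  ann <- trnaAnnotation("c", s, s + 69, "+", paste0("g", 1:3))
  cl <- findClusters(ann, maxGap = 1000)
  expect_length(cl, 1)
  expect_equal(clusterGenes(cl[[1]])$gene_id, c("g1", "g2"))
  expect_length(findClusters(ann[0]), 0)
})

test_that("cluster membership equals a brute-force gap partition", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    starts <- sort(sample(1:20000, n))
    ends <- starts + 71
    ann <- trnaAnnotation("c", starts, ends, "+", paste0("g", 1:n))
    max_gap <- sample(c(200, 500, 1000), 1)
    cl <- findClusters(ann, maxGap = max_gap, minGenes = 2)
    oracle <- cluster_oracle(starts, ends, max_gap, 2)
    expect_equal(length(cl), length(oracle))
    got <- lapply(cl, function(x) clusterGenes(x)$gene_id)
    want <- lapply(oracle, function(i) paste0("g", sort(i)))
    expect_equal(got, want)
    # order invariance and idempotence
    perm <- sample(n)
    cl2 <- findClusters(ann[perm], maxGap = max_gap, minGenes = 2)
    expect_equal(lapply(cl2, function(x) clusterGenes(x)$gene_id), got)
    # no gene lost or duplicated: clusters plus singletons = input
    in_clusters <- unlist(got)
    expect_equal(anyDuplicated(in_clusters), 0)
    expect_true(all(in_clusters %in% ann$gene_id))
    # every reported spacer respects the gap rule
    for (x in cl) expect_true(all(spacerLengths(x) <= max_gap))
  }
})

test_that("orientation patterns are classified from ascending-coordinate strands", {
  mk <- function(strands) {
    n <- length(strands)
    s <- seq(1, by = 200, length.out = n)
    cl <- findClusters(trnaAnnotation("c", s, s + 69, strands, paste0("g", 1:n)))
    classifyOrientation(cl[[1]])
  }
  expect_equal(mk(c("-", "+")), "head_to_head")
  expect_equal(mk(c("+", "-")), "tail_to_tail")
  expect_equal(mk(c("+", "+")), "head_to_tail")
  expect_equal(mk(c("-", "-")), "head_to_tail")
  expect_equal(mk(c("+", "+", "-", "+")), "mixed")
})

test_that("pseudogenes flank clusters without joining them", {
  ann <- c(
    trnaAnnotation("c", c(1000, 1420), c(1071, 1491), "+", c("g1", "g2")),
    trnaAnnotation("c", 200, 271, "+", "psi", category = "pseudogene",
                   high_confidence = FALSE)
  )
  cl <- findClusters(ann, maxGap = 1000)
  expect_length(cl, 1)
  expect_equal(clusterGenes(cl[[1]])$gene_id, c("g1", "g2"))
  expect_equal(cl[[1]]@flankingPseudogenes$gene_id, "psi")
  expect_error(findClusters(ann, maxGap = -1), "maxGap")
})
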