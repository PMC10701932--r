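test_that("exact tandem copies decompose into identical units", {
  set.seed(3)
  unit <- paste0(rand_dna(72), rand_dna(348))
  region <- strrep(unit, 4)
  genes <- trnaAnnotation("region", c(1, 421, 841, 1261), c(72, 492, 912, 1332),
                          "+", paste0("g", 1:4))
  us <- decomposeCluster(region, genes)
  expect_equal(length(us), 4)
  expect_equal(GenomicRanges::width(unitRanges(us)), rep(420L, 4))
  idm <- identityMatrix(unitSeqs(us))
  expect_true(all(idm == 100))
  # decomposition covers the span from first gene start to last unit end
  expect_equal(GenomicRanges::start(unitRanges(us))[1], 1)
  expect_equal(max(GenomicRanges::end(unitRanges(us))), 1680)
})

test_that("generator truth boundaries are recovered exactly", {
  panel <- makeClusterPanel(clusterSpec())
  for (acc in names(panel$accessions)) {
    tr <- panel$accessions[[acc]]$truth
    r <- extractClusterRegion(panel, acc)
    us <- decomposeCluster(r$region, r$genes, accession = acc)
    expect_equal(length(us), sum(tr$gene_present))
    want_starts <- tr$unit_starts[tr$gene_present] - tr$cluster_start + 1L
    expect_equal(GenomicRanges::start(unitRanges(us)), want_starts)
  }
})

test_that("unit counts are recovered across seeded panels up to 10% divergence", {
  set.seed(17)
  for (rep in 1:10) {
    counts <- sample(4:6, 3, replace = TRUE)
    sp <- clusterSpec(nUnits = setNames(counts, c("a1", "a2", "a3")),
                      divergence = runif(1, 0.02, 0.10),
                      partialDeletion = NULL, seed = 1000 + rep)
    panel <- makeClusterPanel(sp)
    got <- vapply(names(panel$accessions), function(acc) {
      r <- extractClusterRegion(panel, acc)
      length(decomposeCluster(r$region, r$genes, accession = acc))
    }, integer(1))
    expect_equal(unname(got), counts)
  }
})

test_that("minus-strand regions are reoriented before decomposition", {
  set.seed(4)
  unit <- paste0(rand_dna(72), rand_dna(348))
  region <- strrep(unit, 3)
  genes <- trnaAnnotation("r", c(1, 421, 841), c(72, 492, 912), "+",
                          paste0("g", 1:3))
  plus <- decomposeCluster(region, genes)
  # same cluster seen on the minus strand
  L <- nchar(region)
  rc_region <- cystra:::revcomp_chr(region)
  rc_genes <- trnaAnnotation("r", L - c(72, 492, 912) + 1, L - c(1, 421, 841) + 1,
                             "-", paste0("g", 1:3))
  minus <- decomposeCluster(rc_region, rc_genes)
  expect_equal(as.character(unitSeqs(minus)), as.character(unitSeqs(plus)),
               ignore_attr = TRUE)
  both <- trnaAnnotation("r", c(1, 421), c(72, 492), c("+", "-"), c("g1", "g2"))
  expect_error(decomposeCluster(region, both), "both strands")
  expect_error(decomposeCluster(region, genes[0]), "no genes")
})

test_that("identical panels yield no structural events", {
  sp <- clusterSpec(nUnits = c(a = 4, b = 4), accessionDivergence = 0,
                    partialDeletion = NULL, seed = 5)
  panel <- makeClusterPanel(sp)
  us <- lapply(names(panel$accessions), function(acc) {
    r <- extractClusterRegion(panel, acc)
    decomposeCluster(r$region, r$genes, accession = acc)
  })
  ev <- callStructuralEvents(buildUnitPanel(us))
  expect_equal(nrow(ev), 0)
})

test_that("an extra unit copy is called as a whole-unit insertion", {
  sp <- clusterSpec(nUnits = c(ref = 4), partialDeletion = NULL, seed = 6)
  panel <- makeClusterPanel(sp)
  r <- extractClusterRegion(panel, "ref")
  ref_us <- decomposeCluster(r$region, r$genes, accession = "ref")
  # accession with a duplicated third unit
  useqs <- as.character(unitSeqs(ref_us))
  ins_region <- paste0(useqs[1], useqs[2], useqs[3], useqs[3], useqs[4])
  s <- c(1, 421, 841, 1261, 1681)
  ins_genes <- trnaAnnotation("r", s, s + 71, "+", paste0("h", 1:5))
  ins_us <- decomposeCluster(ins_region, ins_genes, accession = "ins")
  ev <- callStructuralEvents(buildUnitPanel(list(ins_us, ref_us),
                                            reference = "ref"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "whole_unit_insertion")
  expect_equal(ev$size, 420)
})

test_that("the junction-spanning deletion is called with its exact size", {
  panel <- makeClusterPanel(clusterSpec())
  us <- lapply(names(panel$accessions), function(acc) {
    r <- extractClusterRegion(panel, acc)
    decomposeCluster(r$region, r$genes, accession = acc)
  })
  ev <- callStructuralEvents(buildUnitPanel(us))
  partial <- ev[ev$kind == "partial_deletion", ]
  expect_equal(nrow(partial), 1)
  expect_equal(partial$accession, "cviLike")
  expect_equal(partial$size, 167)
  # the remaining heterogeneity is whole-unit only
  expect_true(all(ev$kind[ev$accession != "cviLike"] %in%
                    c("whole_unit_deletion", "whole_unit_insertion")))
  expect_true(all(ev$size[ev$kind != "partial_deletion"] == 420))
})
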