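test_that("the template tRNA is cloverleaf-consistent with a GCA anticodon", {
  tpl <- makeTrnaTemplate(1)
  expect_equal(nchar(tpl$seq), 72)
  expect_equal(substring(tpl$seq, 34, 36), "GCA")
  r <- stemMispairCheck(tpl$seq, tpl$seq, tpl$pairing)
  expect_true(all(r$perStem$mispairs == 0))
  # different seeds give different, equally consistent templates
  tpl2 <- makeTrnaTemplate(2)
  expect_false(tpl$seq == tpl2$seq)
  chars <- strsplit(tpl2$seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (stem in tpl2$pairing$stems) {
    expect_true(all(comp[chars[stem[, 1]]] == chars[stem[, 2]]))
  }
})

test_that("panels are byte-reproducible per seed and respect divergence 0", {
  p1 <- makeClusterPanel(clusterSpec(seed = 7))
  p2 <- makeClusterPanel(clusterSpec(seed = 7))
  for (acc in names(p1$accessions)) {
    expect_identical(as.character(p1$accessions[[acc]]$genome),
                     as.character(p2$accessions[[acc]]$genome))
  }
  p3 <- makeClusterPanel(clusterSpec(seed = 8))
  expect_false(identical(as.character(p1$accessions[[1]]$genome),
                         as.character(p3$accessions[[1]]$genome)))
  # zero divergence: all units identical
  p0 <- makeClusterPanel(clusterSpec(divergence = 0, accessionDivergence = 0,
                                     partialDeletion = NULL, seed = 9))
  r <- extractClusterRegion(p0, "bigSix")
  us <- decomposeCluster(r$region, r$genes)
  expect_true(all(identityMatrix(unitSeqs(us)) == 100))
})

test_that("generator outputs satisfy their consumers' preconditions", {
  panel <- makeClusterPanel(clusterSpec())
  for (acc in names(panel$accessions)) {
    a <- panel$accessions[[acc]]
    # annotations inside the genome, unique ids, cluster detectable
    expect_true(all(GenomicRanges::end(a$annotations) <=
                      Biostrings::width(a$genome)[1]))
    expect_equal(anyDuplicated(a$annotations$gene_id), 0)
    cl <- findClusters(a$annotations)
    expect_length(cl, 1)
    # the pseudogene flanks the cluster rather than joining it
    expect_equal(length(cl[[1]]@flankingPseudogenes), 1)
    # truth covers every unit
    tr <- a$truth
    expect_equal(length(tr$unit_starts), tr$n_units)
    expect_equal(length(tr$groups), tr$n_units)
  }
})

test_that("panel files round-trip through FASTA and GFF3", {
  panel <- makeClusterPanel(clusterSpec(seed = 10))
  dir <- tempfile()
  files <- writePanel(panel, dir)
  acc <- names(panel$accessions)[1]
  g <- readFasta(files[[acc]][["fasta"]])
  expect_identical(as.character(g), as.character(panel$accessions[[acc]]$genome))
  ann <- readTrnaGff3(files[[acc]][["gff3"]])
  orig <- panel$accessions[[acc]]$annotations
  expect_equal(GenomicRanges::start(ann), GenomicRanges::start(orig))
  expect_equal(ann$category, orig$category)
  expect_setequal(ann$gene_id, orig$gene_id)
})

test_that("degenerate read simulation maps every read back perfectly", {
  ls <- makeLocusSet()
  e <- setNames(rep(0, length(ls$expression)), names(ls$expression))
  e[["tCys-05"]] <- 1
  rs <- readSimSpec(e, depth = 200, errorRate = 0, contaminantFraction = 0,
                    precursorFraction = 0.2, seed = 95)
  sim <- simulateReads(ls, rs)
  i <- match("tCys-05", ls$loci$gene_id)
  refs <- c(ls$loci$mature[i], ls$loci$precursor[i])
  for (rd in as.character(sim$reads$control)) {
    expect_true(grepl(rd, refs[1], fixed = TRUE) ||
                  grepl(rd, refs[2], fixed = TRUE))
  }
  expect_true(all(sim$truth$gene == "tCys-05"))
  expect_error(readSimSpec(setNames(0, "g"), depth = 10), "all-zero")
})

test_that("read simulation is reproducible and truth is complete", {
  ls <- makeLocusSet()
  rs <- readSimSpec(ls$expression, ls$charged, depth = 1000, seed = 96)
  s1 <- simulateReads(ls, rs)
  s2 <- simulateReads(ls, rs)
  expect_identical(as.character(s1$reads$control), as.character(s2$reads$control))
  expect_identical(s1$truth, s2$truth)
  for (lib in names(s1$reads)) {
    expect_equal(length(s1$reads[[lib]]),
                 sum(s1$truth$library == lib))
    expect_equal(unname(as.character(s1$reads[[lib]])),
                 s1$truth$read_seq[s1$truth$library == lib])
  }
})

test_that("charged genes are enriched in the deacylated library by the
          stated factor", {
  ls <- makeLocusSet()
  rs <- readSimSpec(ls$expression, ls$charged, depth = 50000, errorRate = 0,
                    contaminantFraction = 0, chargedFactor = 2, seed = 97)
  sim <- simulateReads(ls, rs)
  tt <- sim$truth[!is.na(sim$truth$gene), ]
  cnt <- table(tt$gene, tt$library)
  ch <- names(ls$charged)[ls$charged & ls$expression > 30]
  un <- names(ls$charged)[!ls$charged & ls$expression > 30]
  ratios_ch <- cnt[ch, "deacylated"] / cnt[ch, "control"]
  ratios_un <- cnt[un, "deacylated"] / cnt[un, "control"]
  expect_true(all(abs(ratios_ch - 2) / 2 < 0.1))
  expect_true(all(abs(ratios_un - 1) < 0.1))
})
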