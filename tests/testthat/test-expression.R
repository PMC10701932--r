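test_that("unique-read collapse preserves totals and merges libraries", {
  tab <- collapseUnique(list(lib1 = c("AAAA", "AAAA", "CCCC")))
  expect_equal(sort(tab$lib1), c(1, 2))
  expect_equal(tab$lib1[tab$read_seq == "AAAA"], 2)
  # a sequence shared between libraries lands on one row
  tab2 <- collapseUnique(list(a = c("AAAA", "GGGG"), b = c("AAAA")))
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$b[tab2$read_seq == "AAAA"], 1)
  expect_equal(tab2$b[tab2$read_seq == "GGGG"], 0)
  # replicate files are summed into their library column
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeFasta(c(r1 = "ACGTACGT"), f1)
  writeFasta(c(r2 = "ACGTACGT", r3 = "TTTTGGGG"), f2)
  tab3 <- collapseUnique(list(ctl = c(f1, f2)))
  expect_equal(sum(tab3$ctl), 3)
  expect_equal(tab3$ctl[tab3$read_seq == "ACGTACGT"], 2)
  expect_warning(collapseUnique(list(empty = character(0))), "zero reads")
})

test_that("collapse counts equal the simulation's draw exactly", {
  fx <- errorfree_sim()
  tab <- collapseUnique(fx$sim$reads)
  truth <- fx$sim$truth
  want <- table(truth$read_seq[truth$library == "control"])
  got <- setNames(tab$control, tab$read_seq)[names(want)]
  expect_equal(unname(got), as.vector(want))
  expect_equal(sum(tab$control), sum(truth$library == "control"))
})

test_that("length filter bounds are inclusive", {
  tab <- data.frame(read_seq = c(strrep("A", 54), strrep("C", 55),
                                 strrep("G", 110), strrep("T", 111)),
                    lib = 1:4, stringsAsFactors = FALSE)
  kept <- lengthFilter(tab)
  expect_equal(nchar(kept$read_seq), c(55, 110))
  expect_equal(nrow(lengthFilter(tab[0, ])), 0)
  expect_error(lengthFilter(tab, min = 0), "min")
  set.seed(81)
  big <- data.frame(read_seq = vapply(sample(20:150, 1000, TRUE), rand_dna, ""),
                    lib = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(lengthFilter(big)),
               sum(nchar(big$read_seq) >= 55 & nchar(big$read_seq) <= 110))
})

test_that("the contamination filter obeys its matcher and logs removals", {
  tab <- data.frame(read_seq = c("AAAA", "CCCC", "GGGG"), lib = c(1, 2, 3),
                    stringsAsFactors = FALSE)
  all_in <- contaminationFilter(tab, function(s) rep(TRUE, length(s)))
  expect_equal(nrow(all_in), 3)
  none <- contaminationFilter(tab, function(s) rep(FALSE, length(s)))
  expect_equal(nrow(none), 0)
  expect_equal(nrow(attr(none, "removed")), 3)
  expect_error(contaminationFilter(tab, function(s) c(TRUE, NA, TRUE)),
               "matcher failed")
  # labeled contaminants are removed exactly, via a truth-backed matcher
  ls <- makeLocusSet()
  rs <- readSimSpec(ls$expression, ls$charged, depth = 3000, errorRate = 0,
                    contaminantFraction = 0.1, seed = 82)
  sim <- simulateReads(ls, rs)
  tabs <- collapseUnique(sim$reads)
  contam_seqs <- unique(sim$truth$read_seq[sim$truth$class == "contaminant"])
  oracle <- function(s) !(s %in% contam_seqs)
  kept <- contaminationFilter(tabs, oracle)
  expect_false(any(kept$read_seq %in% contam_seqs))
  expect_equal(nrow(tabs) - nrow(kept), length(intersect(tabs$read_seq, contam_seqs)))
  # the scorer-backed matcher keeps every signal read and rejects nearly
  # all contaminants (a score threshold can let the odd chance hit through)
  m <- makeReferenceMatcher(ls$loci$precursor)
  keep2 <- m(tabs$read_seq)
  is_signal <- oracle(tabs$read_seq)
  expect_true(all(keep2[is_signal]))
  expect_lt(mean(keep2[!is_signal]), 0.01)
  expect_match(blastContaminationCommand("q.fa", "nt", "o.tsv"),
               "-word_size 6 -perc_identity 65 -dust no")
})

test_that("reference loci validate the CCA tail and body containment", {
  body <- rand_dna(72)
  expect_error(referenceLoci("g1", "v1", body, paste0("AA", body, "TT")),
               "CCA")
  expect_error(referenceLoci("g1", "v1", paste0(body, "CCA"),
                             paste0("AA", rand_dna(72), "TT")),
               "contain the gene body")
  ok <- referenceLoci("g1", "v1", paste0(body, "CCA"),
                      paste0("AAAAA", body, "TTTTT"))
  expect_s3_class(ok, "referenceLoci")
})

test_that("identical mature copies are separated only by precursor evidence", {
  set.seed(83)
  body <- rand_dna(72)
  loci <- referenceLoci(
    c("gA", "gB"), c("v1", "v1"),
    mature = rep(paste0(body, "CCA"), 2),
    precursor = c(paste0(rand_dna(30), body, rand_dna(30)),
                  paste0(rand_dna(30), body, rand_dna(30)))
  )
  mature_read <- paste0(body, "CCA")
  trailer_read <- paste0(body, substring(loci$precursor[1], 103, 110))
  tab <- data.frame(read_seq = c(mature_read, trailer_read), ctl = c(3, 2),
                    stringsAsFactors = FALSE)
  expr <- assignReads(tab, loci)
  # mature read: tie across loci sharing the variant -> variant-level only
  expect_equal(unname(geneCounts(expr)[, "ctl"]), c(0, 0) + c(2, 0))
  expect_equal(unname(variantCounts(expr)["v1", "ctl"]), 5)
  asn <- expr@assignments
  expect_equal(asn$level[asn$read_seq == mature_read], "variant")
  # 8 nt of gA's own trailer resolve the copy uniquely
  expect_equal(asn$target[asn$read_seq == trailer_read], "gA")
  expect_error(assignReads(tab, loci[0, ]), "empty locus")
})

test_that("simulated expression is recovered with silent loci staying silent", {
  fx <- errorfree_sim()
  ls <- fx$locusSet
  expr <- fx$expr
  ct <- compareLibraries(expr)
  silent <- c("var-12", "var-13")
  expect_setequal(ct$id[ct$status == "undetected"], silent)
  # zero-expression loci recover exactly zero assigned reads
  zero_genes <- names(ls$expression)[ls$expression == 0]
  expect_true(all(geneCounts(expr)[zero_genes, ] == 0))
  expect_true(all(variantCounts(expr)[silent, ] == 0))
  # recovered variant totals track the true expression vector
  vc <- variantCounts(expr)[, "control"]
  true_v <- tapply(ls$expression,
                   ls$loci$variant_id[match(names(ls$expression), ls$loci$gene_id)],
                   sum)
  rho <- cor(vc[names(true_v)], true_v, method = "spearman")
  expect_gte(rho, 0.95)
  # the duplicated-variant loci split exactly by read class
  asn <- expr@assignments
  tr <- unique(fx$sim$truth[, c("read_seq", "class", "gene")])
  key <- merge(asn, tr, by = "read_seq")
  pair <- key[!is.na(key$gene) & key$gene %in% c("tCys-01", "tCys-02"), ]
  expect_true(all(pair$level[pair$class == "precursor"] == "gene"))
  expect_true(all(pair$level[pair$class == "mature"] == "variant"))
})

test_that("read accounting is exactly conservative per library", {
  fx <- errorfree_sim()
  acct <- readAccounting(fx$expr)
  tab <- fx$tab
  for (lib in rownames(acct)) {
    expect_equal(sum(acct[lib, ]), sum(tab[[lib]]))
  }
  # and gene + variant-rescued counts reconcile with the accounting
  expect_equal(unname(colSums(geneCounts(fx$expr))),
               acct[colnames(geneCounts(fx$expr)), "gene_assigned"])
})

test_that("normalized counts are zero exactly when raw counts are, and
          library flags follow the contrast", {
  set.seed(85)
  body <- rand_dna(72)
  body2 <- cystra:::mutate_dna(body, 0.1)
  loci <- referenceLoci(c("g1", "g2"), c("v1", "v2"),
                        mature = c(paste0(body, "CCA"), paste0(body2, "CCA")),
                        precursor = c(paste0(rand_dna(30), body, rand_dna(30)),
                                      paste0(rand_dna(30), body2,
                                             rand_dna(30))))
  body3 <- cystra:::mutate_dna(body, 0.15)
  loci <- rbind(loci, referenceLoci("g3", "v3", paste0(body3, "CCA"),
                                    paste0(rand_dna(30), body3, rand_dna(30))))
  tab <- data.frame(
    read_seq = c(paste0(body, "CCA"), substring(body2, 1, 60)),
    control = c(10, 4), deacylated = c(20, 4), stringsAsFactors = FALSE)
  expr <- assignReads(tab, loci)
  expect_error(normalizedCounts(expr), "normalizeExpression")
  expr <- normalizeExpression(expr, factors = c(control = 1, deacylated = 1))
  nm <- normalizedCounts(expr, "variant")
  expect_equal(nm == 0, variantCounts(expr) == 0)
  ct <- compareLibraries(expr)
  # no read touches v3: undetected in both libraries
  expect_equal(ct$status[ct$id == "v3"], "undetected")
  # v1 doubles in the deacylated library relative to scaling -> charged;
  # v2 stays flat -> not charged
  expect_true(ct$charged[ct$id == "v1"])
  expect_false(ct$charged[ct$id == "v2"])
  expect_error(compareLibraries(expr, control = "missing"), "missing")
})

test_that("charged flags are perfectly accurate on a zero-noise simulation", {
  fx <- errorfree_sim()
  ls <- fx$locusSet
  ct <- compareLibraries(fx$expr)
  truth_charged <- tapply(ls$charged,
                          ls$loci$variant_id[match(names(ls$charged),
                                                   ls$loci$gene_id)], any)
  det <- ct[ct$status == "detected", ]
  expect_equal(det$charged, as.vector(truth_charged[det$id]))
})
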