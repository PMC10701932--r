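test_that("sixteen gene copies collapse to thirteen mature variants", {
  ls <- makeLocusSet()
  bodies <- setNames(substring(ls$loci$mature, 1, nchar(ls$loci$mature) - 3),
                     ls$loci$gene_id)
  v <- dedupeMature(bodies)
  expect_equal(nrow(v), 13)
  expect_equal(sum(v$n_members), 16)
  # duplicated variants carry exactly the generator's locus pairs
  by_truth <- split(ls$loci$gene_id, ls$loci$variant_id)
  for (k in seq_len(nrow(v))) {
    members <- strsplit(v$members[k], ",")[[1]]
    truth <- by_truth[[ls$loci$variant_id[match(members[1], ls$loci$gene_id)]]]
    expect_setequal(members, truth)
  }
  # trivial cases
  expect_equal(nrow(dedupeMature(setNames(rep("ACGTACGT", 5), paste0("g", 1:5)))), 1)
  expect_equal(nrow(dedupeMature(character(0))), 0)
})

test_that("greedy clustering respects the identity threshold arithmetic", {
  set.seed(61)
  base <- rand_dna(72)
  one_sub <- cystra:::mutate_dna(base, 1, protect = setdiff(1:72, 10))
  three_sub <- cystra:::mutate_dna(base, 1, protect = setdiff(1:72, c(10, 30, 50)))
  # identity 71/72 = 0.986 >= 0.97 -> one group
  g1 <- greedyCluster(c(a = base, b = one_sub), threshold = 0.97)
  expect_equal(length(unique(g1$centroid_id)), 1)
  # identity 69/72 = 0.958 < 0.97 -> two groups
  g2 <- greedyCluster(c(a = base, b = three_sub), threshold = 0.97)
  expect_equal(length(unique(g2$centroid_id)), 2)
  # identical sequences always join
  g3 <- greedyCluster(c(a = base, b = base))
  expect_equal(length(unique(g3$centroid_id)), 1)
  expect_error(greedyCluster(c(a = base), threshold = 0), "threshold")
})

test_that("six seeded families of near-identical members give six groups", {
  set.seed(62)
  templates <- replicate(6, rand_dna(72))
  # members differ from their template by one substitution each, so any two
  # family members are within 2 substitutions (identity 70/72 > 0.97) while
  # the templates themselves are mutually unrelated
  seqs <- unlist(lapply(1:6, function(f) {
    pos <- sample(1:72, 2)
    members <- c(templates[f],
                 cystra:::mutate_dna(templates[f], 1, protect = setdiff(1:72, pos[1])),
                 cystra:::mutate_dna(templates[f], 1, protect = setdiff(1:72, pos[2])))
    setNames(members, paste0("f", f, "_", 1:3))
  }))
  g <- greedyCluster(seqs, threshold = 0.97)
  expect_equal(length(unique(g$centroid_id)), 6)
  fam <- sub("_.*", "", g$member_id)
  # all members of one family share a centroid
  expect_true(all(tapply(g$centroid_id, fam, function(x) length(unique(x))) == 1))
})

test_that("at threshold 1 greedy clustering equals exact deduplication,
          and group counts fall as the threshold drops", {
  set.seed(63)
  base <- rand_dna(72)
  seqs <- setNames(c(base, base, cystra:::mutate_dna(base, 0.05),
                     cystra:::mutate_dna(base, 0.2), rand_dna(72)),
                   paste0("s", 1:5))
  g100 <- greedyCluster(seqs, threshold = 1)
  dd <- dedupeMature(seqs)
  expect_equal(length(unique(g100$centroid_id)), nrow(dd))
  counts <- vapply(c(1, 0.97, 0.9, 0.7, 0.5),
                   function(t) length(unique(greedyCluster(seqs, t)$centroid_id)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stem mispair assessment localizes substitutions and indels", {
  tpl <- makeTrnaTemplate(8)
  ref <- tpl$seq
  # reference vs itself: all stems canonical
  r0 <- stemMispairCheck(ref, ref, tpl$pairing)
  expect_true(all(r0$perStem$mispairs == 0))
  expect_false(any(r0$perStem$indel))
  expect_equal(r0$verdict, "canonical")

  # single substitution inside a T-stem pair (position 49 pairs with 65)
  chars <- strsplit(ref, "")[[1]]
  subs <- setdiff(c("A", "C", "G", "T"), c(chars[49],
    chartr("ACGT", "TGCA", chars[65])))[1]
  mutant <- paste0(substring(ref, 1, 48), subs, substring(ref, 50))
  r1 <- stemMispairCheck(mutant, ref, tpl$pairing)
  per <- setNames(r1$perStem$mispairs, r1$perStem$stem)
  expect_equal(per[["T"]], 1)
  expect_equal(sum(per), 1)
  expect_equal(r1$verdict, "deviant")

  # 11 nt deletion spanning the T-loop and two T-stem pairs (52..62)
  del <- paste0(substring(ref, 1, 51), substring(ref, 63))
  r2 <- stemMispairCheck(del, ref, tpl$pairing)
  expect_true(r2$perStem$indel[r2$perStem$stem == "T"])
  expect_equal(r2$verdict, "deviant")

  # alignment-neutral flank padding leaves the counts unchanged
  padded <- paste0("GGTTAAC", mutant, "TTGACAA")
  r3 <- stemMispairCheck(padded, ref, tpl$pairing)
  expect_equal(r3$perStem$mispairs, r1$perStem$mispairs)
})

test_that("the wobble pair is tolerated in stems", {
  tpl <- makeTrnaTemplate(9)
  chars <- strsplit(tpl$seq, "")[[1]]
  # find an acceptor-stem pair whose 5' base is G or can be made G:T wobble
  pm <- tpl$pairing$stems$acceptor
  i <- pm[1, 1]; j <- pm[1, 2]
  chars[i] <- "G"; chars[j] <- "C"
  ref <- paste(chars, collapse = "")
  chars[j] <- "T"                      # G:T wobble
  wob <- paste(chars, collapse = "")
  r <- stemMispairCheck(wob, ref, tpl$pairing)
  expect_equal(sum(r$perStem$mispairs), 0)
})
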