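# shared fixtures and independent oracles, built in code at test time

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small GFF3 fixture: one + tRNA, one - tRNA, one pseudogene, one mRNA
gff3_fixture <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "chr5\ttest\ttRNA\t11\t20\t.\t+\t.\tID=tA;isotype=Cys;anticodon=GCA",
    "chr5\ttest\ttRNA\t101\t172\t.\t-\t.\tID=tB;isotype=Cys;anticodon=GCA",
    "chr5\ttest\tpseudogene\t300\t371\t.\t+\t.\tID=psi1",
    "chr5\ttest\tmRNA\t500\t900\t.\t+\t.\tID=m1"
  ), ".gff3")
}

# tRNAscan-SE 2.0-style tabular fixture mimicking a 4-gene Cys cluster
trnascan_fixture <- function() {
  hdr <- c(
    "Sequence\t\ttRNA\tBounds\t\ttRNA\tAnti\tIntron Bounds\t\tInf\t",
    "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
    "--------\t------\t-----\t---\t----\t-----\t-----\t----\t-----\t----"
  )
  rows <- c(
    "chr5\t1\t1001\t1072\tCys\tGCA\t0\t0\t80.2\t",
    "chr5\t2\t1421\t1492\tCys\tGCA\t0\t0\t79.9\t",
    "chr5\t3\t1841\t1912\tCys\tGCA\t0\t0\t81.0\t",
    "chr5\t4\t2261\t2332\tCys\tGCA\t0\t0\t78.5\t"
  )
  write_lines_tmp(c(hdr, rows), ".txt")
}

# brute-force cluster membership oracle: partition sorted genes wherever the
# gap between neighbours exceeds max_gap, then drop short runs
cluster_oracle <- function(starts, ends, max_gap, min_genes) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  runs <- list(1L)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - ends[i - 1] - 1 <= max_gap) {
      runs[[length(runs)]] <- c(runs[[length(runs)]], i)
    } else {
      runs[[length(runs) + 1L]] <- i
    }
  }
  lapply(Filter(function(r) length(r) >= min_genes, runs),
         function(r) o[r])
}

# independent hairpin enumerator based on string reverse-complementation
hairpin_oracle <- function(seq, window, min_stem, max_loop, min_loop,
                           max_mm) {
  L <- nchar(seq)
  w <- substring(seq, L - window + 1, L)
  res <- list()
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (s in seq_len(nchar(w))) {
    for (stem in min_stem:floor((nchar(w) - min_loop) / 2)) {
      for (loop in min_loop:max_loop) {
        e <- s + 2 * stem + loop - 1
        if (e > nchar(w)) next
        left <- substring(w, s, s + stem - 1)
        right <- substring(w, s + stem + loop, e)
        mm <- sum(strsplit(left, "")[[1]] != strsplit(rc(right), "")[[1]])
        if (mm <= max_mm) {
          res[[length(res) + 1L]] <- c(start = L - window + s, stem = stem,
                                       loop = loop, mm = mm)
        }
      }
    }
  }
  res
}

# default-condition locus set + error-free simulated reads, shared by the
# assignment tests (computed once per test run)
fixture_cache <- new.env()

errorfree_sim <- function() {
  if (!is.null(fixture_cache$sim)) return(fixture_cache$sim)
  ls <- makeLocusSet()
  rs <- readSimSpec(ls$expression, ls$charged, depth = 20000, errorRate = 0,
                    contaminantFraction = 0, seed = 11)
  sim <- simulateReads(ls, rs)
  tab <- lengthFilter(collapseUnique(sim$reads))
  expr <- normalizeExpression(assignReads(tab, ls$loci), table = tab)
  fixture_cache$sim <- list(locusSet = ls, sim = sim, tab = tab, expr = expr)
  fixture_cache$sim
}
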