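# Helitron terminal-signal scan, 3'-hairpin scan, and in-silico PCR

#' Scan for Helitron terminal signals
#'
#' Reports all exact occurrences, on both strands, of the 5'-terminal
#' `TC`, the 3'-terminal `CTRR` (R = A/G), and the `CTAG` motif followed
#' by T or C (`CTAGY`) that marks candidate termination signals within
#' repeating units. IUPAC codes are honoured in the patterns.
#'
#' @param seq a DNA sequence (character or `DNAString`).
#' @param motifs named character vector of IUPAC patterns; the defaults
#'   are the rolling-circle transposon terminal signals.
#' @return data.frame with columns `motif`, `pattern`, `strand`, `start`,
#'   `end` (1-based on the input sequence) and `context` (10 nt window on
#'   the plus strand).
#' @export
scanHelitronSignals <- function(seq, motifs = c(five_prime_TC = "TC",
                                                three_prime_CTRR = "CTRR",
                                                CTAG_TC = "CTAGY")) {
  seq <- as_dna_character(seq)
  subject <- Biostrings::DNAString(seq)
  L <- nchar(seq)
  rows <- list()
  for (m in names(motifs)) {
    pat <- Biostrings::DNAString(motifs[[m]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      hits <- Biostrings::matchPattern(p, subject, fixed = FALSE)
      if (length(hits) == 0) next
      st <- Biostrings::start(hits)
      en <- Biostrings::end(hits)
      ctx_lo <- pmax(1, st - 3)
      ctx_hi <- pmin(L, en + 3)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = m, pattern = motifs[[m]], strand = strand, start = st,
        end = en, context = substring(seq, ctx_lo, ctx_hi),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(0), pattern = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$motif, out$strand), , drop = FALSE]
}

#' Scan the 3' window of a sequence for hairpin-forming inverted repeats
#'
#' Exhaustive search of the last `windowFrom3prime` bases for inverted
#' repeats with stem length >= `minStem`, loop length in
#' `[minLoop, maxLoop]`, and at most `maxMismatch` stem mismatches --
#' the subterminal palindrome expected near a rolling-circle transposon's
#' 3' end. Brute force is exact at this window size.
#'
#' @param seq a DNA sequence.
#' @param windowFrom3prime window size from the 3' end (default 60).
#' @param minStem minimum stem length (default 6).
#' @param maxLoop maximum loop length (default 10).
#' @param minLoop minimum loop length (default 3).
#' @param maxMismatch maximum mismatched stem pairs (default 1).
#' @return data.frame with `start`, `end` (1-based on the full sequence),
#'   `stem`, `loop`, `mismatches` and `dist_from_3prime` (bases between
#'   hairpin end and the 3' end).
#' @export
hairpinScan <- function(seq, windowFrom3prime = 60, minStem = 6,
                        maxLoop = 10, minLoop = 3, maxMismatch = 1) {
  seq <- as_dna_character(seq)
  L <- nchar(seq)
  if (L < windowFrom3prime) {
    stop("sequence shorter than the scan window", call. = FALSE)
  }
  off <- L - windowFrom3prime   # window = positions off+1 .. L
  w <- substring(seq, off + 1, L)
  wl <- nchar(w)
  chars <- strsplit(w, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  rows <- list()
  maxStem <- floor((wl - minLoop) / 2)
  stems <- if (minStem <= maxStem) seq(minStem, maxStem) else integer(0)
  for (stem in stems) {
    for (loop in seq(minLoop, min(maxLoop, wl - 2 * stem))) {
      span <- 2 * stem + loop
      for (s in seq_len(wl - span + 1)) {
        left <- chars[s:(s + stem - 1)]
        right <- chars[(s + stem + loop):(s + span - 1)]
        mm <- sum(comp[left] != rev(right))
        if (mm <= maxMismatch) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = off + s, end = off + s + span - 1, stem = stem,
            loop = loop, mismatches = mm,
            dist_from_3prime = wl - (s + span - 1),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0), stem = integer(0),
                      loop = integer(0), mismatches = integer(0),
                      dist_from_3prime = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' In-silico PCR
#'
#' Finds binding sites of the forward primer on the plus strand and of the
#' reverse primer (as its reverse complement) downstream, and reports every
#' pairing within `maxProduct`; the symmetric orientation (product on the
#' minus strand) is also searched. Product size is measured from the 5'
#' end of the forward site to the 5' end of the reverse site inclusive,
#' i.e. the product includes both primer footprints, matching what a gel
#' would show.
#'
#' @param genome named `DNAStringSet` (or single sequence).
#' @param fwdPrimer,revPrimer primer sequences, 15-35 nt, plain ACGT.
#' @param maxProduct maximum product size in bp (default 5000).
#' @param maxMismatch allowed mismatches per primer site (default 0;
#'   the PCR this models used primers fully conserved across accessions).
#' @return data.frame with `seqid`, `start`, `end`, `size`, `fwd_site`,
#'   `rev_site`, `strand`.
#' @export
inSilicoPcr <- function(genome, fwdPrimer, revPrimer, maxProduct = 5000,
                        maxMismatch = 0) {
  if (methods::is(genome, "DNAString") || is.character(genome) && length(genome) == 1 && is.null(names(genome))) {
    genome <- Biostrings::DNAStringSet(as_dna_character(genome))
    names(genome) <- "seq1"
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(as_dna_character(genome))
  fwdPrimer <- as_dna_character(fwdPrimer)
  revPrimer <- as_dna_character(revPrimer)
  for (p in c(fwdPrimer, revPrimer)) {
    if (grepl("[^ACGT]", p)) stop("primer contains non-ACGT symbol", call. = FALSE)
    if (nchar(p) < 15 || nchar(p) > 35) {
      stop("primer length must be 15-35 nt", call. = FALSE)
    }
  }
  rows <- list()
  scan_orientation <- function(sq, name, fp, rp, strand) {
    subject <- genome[[sq]]
    f_hits <- Biostrings::matchPattern(Biostrings::DNAString(fp), subject,
                                       max.mismatch = maxMismatch)
    r_hits <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(rp)), subject,
      max.mismatch = maxMismatch)
    if (length(f_hits) == 0 || length(r_hits) == 0) return()
    for (i in seq_along(f_hits)) {
      fs <- Biostrings::start(f_hits)[i]
      for (j in seq_along(r_hits)) {
        re <- Biostrings::end(r_hits)[j]
        if (re <= fs) next
        size <- re - fs + 1
        if (size > maxProduct) next
        rows[[length(rows) + 1L]] <<- data.frame(
          seqid = name, start = fs, end = re, size = size, fwd_site = fs,
          rev_site = Biostrings::start(r_hits)[j], strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  for (sq in names(genome)) {
    scan_orientation(sq, sq, fwdPrimer, revPrimer, "+")
    scan_orientation(sq, sq, revPrimer, fwdPrimer, "-")
  }
  if (!length(rows)) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      fwd_site = integer(0), rev_site = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}
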