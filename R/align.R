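#' Scoring scheme for pairwise DNA alignment
#'
#' Defaults reproduce the constants of the EMBOSS `needle` aligner that the
#' identity statistics of this package are calibrated to: match +5,
#' mismatch -4, gap open 10, gap extend 0.5, end gaps free. A gap of length
#' L costs `gapOpen + L * gapExtend`. Positions involving `N` never score
#' as matches (N vs base -2, N vs N -1).
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score.
#' @param gapOpen gap opening penalty (>= 0).
#' @param gapExtend gap extension penalty (>= 0, `<= gapOpen`).
#' @param endGapsFree when `TRUE` (default) terminal gaps are not
#'   penalized.
#' @return a list of class `"alignScoring"`.
#' @export
alignScoring <- function(match = 5, mismatch = -4, gapOpen = 10,
                         gapExtend = 0.5, endGapsFree = TRUE) {
  stopifnot(gapOpen >= 0, gapExtend >= 0)
  if (gapExtend > gapOpen) stop("gapExtend must not exceed gapOpen", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend, endGapsFree = isTRUE(endGapsFree)),
            class = "alignScoring")
}

#' Optimal global pairwise alignment (affine gaps)
#'
#' Needleman-Wunsch alignment under the Gotoh three-state affine-gap
#' recursion. Traceback ties are broken deterministically: diagonal first,
#' then gap in `b`, then gap in `a`.
#'
#' @param a,b DNA strings (character or `DNAString`) over \{A,C,G,T,N\}.
#' @param scoring an [alignScoring()] scheme.
#' @return list of class `"pairAlignment"` with elements `alignedA`,
#'   `alignedB` (equal-length gapped strings), `score`, `identities` and
#'   `length` (alignment columns).
#' @examples
#' aln <- alignGlobal("ACGT", "AGT")
#' percentIdentity(aln)
#' @export
alignGlobal <- function(a, b, scoring = alignScoring()) {
  a <- as_dna_character(a); b <- as_dna_character(b)
  check_dna(a); check_dna(b)
  res <- .gotohAlign(a, b, scoring$match, scoring$mismatch, scoring$gapOpen,
                     scoring$gapExtend, scoring$endGapsFree)
  structure(res, class = "pairAlignment")
}

#' @export
print.pairAlignment <- function(x, ...) {
  cat("pairAlignment: score", format(x$score), "identities",
      x$identities, "/", x$length,
      sprintf("(%.1f%%)\n", 100 * x$identities / x$length))
  cat(" ", x$alignedA, "\n ", x$alignedB, "\n")
  invisible(x)
}

#' Best local alignment score (affine gaps)
#'
#' Smith-Waterman local alignment, score only, with the end coordinates of
#' the best-scoring alignment in query and reference.
#'
#' @param query,ref DNA strings.
#' @param scoring an [alignScoring()] scheme (`endGapsFree` is irrelevant
#'   for local alignment).
#' @return list with `score`, `endQuery`, `endRef`.
#' @export
alignLocal <- function(query, ref, scoring = alignScoring()) {
  query <- as_dna_character(query); ref <- as_dna_character(ref)
  check_dna(query); check_dna(ref)
  .swAlignScore(query, ref, scoring$match, scoring$mismatch,
                scoring$gapOpen, scoring$gapExtend)
}

# batch local alignment scores: queries x refs matrix
local_score_matrix <- function(queries, refs, scoring = alignScoring()) {
  queries <- as_dna_character(queries); refs <- as_dna_character(refs)
  .swScoreMatrix(queries, refs, scoring$match, scoring$mismatch,
                 scoring$gapOpen, scoring$gapExtend)
}

#' Percent identity of a global alignment
#'
#' `100 * identities / alignment length`; gap columns (terminal ones
#' included) count in the denominator, the convention under which the
#' identity of two sequences of different length is penalized for the
#' overhang.
#'
#' @param alignment result of [alignGlobal()].
#' @param digits decimals to round to (default 1; use `Inf` for no
#'   rounding).
#' @return percent identity in `[0, 100]`.
#' @export
percentIdentity <- function(alignment, digits = 1) {
  if (alignment$length == 0) stop("alignment of length 0", call. = FALSE)
  p <- 100 * alignment$identities / alignment$length
  if (is.finite(digits)) round(p, digits) else p
}

#' Pairwise percent-identity matrix
#'
#' Global alignment identity for every sequence pair; each pair is computed
#' once, the diagonal is 100 by definition.
#'
#' @param seqs named character vector or `DNAStringSet` (>= 2 sequences).
#' @param scoring an [alignScoring()] scheme.
#' @param digits rounding passed to [percentIdentity()].
#' @return symmetric numeric matrix with row/column names.
#' @export
identityMatrix <- function(seqs, scoring = alignScoring(), digits = 1) {
  seqs <- as_dna_character(seqs)
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  empty <- which(nchar(seqs) == 0)
  if (length(empty)) stop("empty sequence at index ", empty[1], call. = FALSE)
  check_dna(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      p <- percentIdentity(alignGlobal(seqs[i], seqs[j], scoring), digits)
      m[i, j] <- p
      m[j, i] <- p
    }
  }
  m
}
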