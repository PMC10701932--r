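# Trimmed-mean-of-M-values between-library normalization

# 75th-percentile of counts over library size, per column
tmm_quantile_ratio <- function(x, lib.size, p = 0.75) {
  apply(x, 2, function(col) quantile(col, probs = p)) / lib.size
}

# one pairwise TMM factor, column obs against column ref
tmm_pair_factor <- function(obs, ref, logratioTrim, sumTrim, doWeighting) {
  obs <- as.numeric(obs)
  ref <- as.numeric(ref)
  nO <- sum(obs)
  nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))       # M values
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2  # A values
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref  # asymptotic variance
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  if (!any(fin)) {
    stop("no read sequence is positive in both libraries", call. = FALSE)
  }
  logR <- logR[fin]
  absE <- absE[fin]
  v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sumTrim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (doWeighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per-library scaling factors that correct for
#' library composition so that counts are comparable between libraries.
#' The reference library is the one whose 75th-percentile-count to
#' library-size ratio is closest to the mean of those ratios. For every
#' library, rows with a zero in either the library or the reference are
#' removed, M (log2 ratio of proportions) and A (mean log2 proportion)
#' values are doubly trimmed (30% of the M tails, 5% of the A tails by
#' default), and the factor is 2 to the inverse-asymptotic-variance
#' weighted mean of the surviving M values. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts numeric matrix, rows = (unique read) sequences, columns =
#'   libraries (>= 2).
#' @param logratioTrim fraction trimmed from each M tail (default 0.30).
#' @param sumTrim fraction trimmed from each A tail (default 0.05).
#' @param doWeighting use inverse-variance weights (default `TRUE`).
#' @param refColumn optional explicit reference library (index or name).
#' @return named numeric vector of factors (geometric mean 1), with the
#'   chosen reference in `attr(, "refColumn")`.
#' @export
tmmFactors <- function(counts, logratioTrim = 0.30, sumTrim = 0.05,
                       doWeighting = TRUE, refColumn = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 libraries", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  lib.size <- colSums(counts)
  if (any(lib.size == 0)) stop("a library has zero total count", call. = FALSE)
  if (is.null(refColumn)) {
    f75 <- tmm_quantile_ratio(counts, lib.size)
    refColumn <- if (median(f75) < 1e-20) {
      which.max(colSums(sqrt(counts)))
    } else {
      which.min(abs(f75 - mean(f75)))
    }
  }
  if (is.character(refColumn)) refColumn <- match(refColumn, colnames(counts))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    tmm_pair_factor(counts[, i], counts[, refColumn], logratioTrim, sumTrim,
                    doWeighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "refColumn") <- refColumn
  f
}
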