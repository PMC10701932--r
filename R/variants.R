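# mature tRNA variant handling: deduplication, greedy identity clustering,
# and cloverleaf stem-mispair assessment

#' Deduplicate mature tRNA sequences
#'
#' Exact-string deduplication of mature tRNA bodies. Each distinct sequence
#' becomes one variant, named deterministically after the first gene id
#' carrying it (in input order).
#'
#' @param seqs named character vector or `DNAStringSet` of mature tRNA
#'   bodies (5' to 3', no CCA, no introns); names are gene ids.
#' @return data.frame with columns `variant_id`, `seq`, `n_members`,
#'   `members` (comma-separated gene ids), in order of first appearance.
#' @export
dedupeMature <- function(seqs) {
  seqs <- as_dna_character(seqs)
  if (length(seqs) == 0) {
    return(data.frame(variant_id = character(0), seq = character(0),
                      n_members = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("gene", seq_along(seqs))
  uniq <- unique(seqs)
  idx <- lapply(uniq, function(s) which(seqs == s))
  data.frame(
    variant_id = vapply(idx, function(i) names(seqs)[i[1]], character(1)),
    seq = unname(uniq),
    n_members = vapply(idx, length, integer(1)),
    members = vapply(idx, function(i) paste(names(seqs)[i], collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

#' Greedy centroid clustering by global-alignment identity
#'
#' USEARCH-style greedy clustering: sequences are visited sorted by length
#' (decreasing), ties broken lexicographically; the first unassigned
#' sequence seeds a centroid, and every sequence joins the best centroid
#' whose identity (matches / alignment columns of the global alignment)
#' reaches `threshold`, otherwise it seeds a new centroid. The visit order
#' is fixed, so the clustering is deterministic. Identity is computed with
#' the package's global aligner, not a k-mer heuristic.
#'
#' @param seqs named sequences.
#' @param threshold identity fraction in (0, 1] (default 0.97).
#' @param scoring an [alignScoring()] scheme.
#' @return data.frame with columns `centroid_id`, `member_id`, `identity`
#'   (fraction to centroid, 1 for the centroid itself).
#' @export
greedyCluster <- function(seqs, threshold = 0.97, scoring = alignScoring()) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  seqs <- as_dna_character(seqs)
  if (length(seqs) == 0) {
    return(data.frame(centroid_id = character(0), member_id = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), seqs, names(seqs))
  seqs <- seqs[ord]
  centroids <- character(0)
  rows <- list()
  for (i in seq_along(seqs)) {
    best_c <- NA_character_
    best_id <- -1
    for (cid in centroids) {
      aln <- alignGlobal(seqs[i], seqs[cid], scoring)
      idf <- aln$identities / aln$length
      if (idf >= threshold && idf > best_id) {
        best_id <- idf
        best_c <- cid
      }
    }
    if (is.na(best_c)) {
      centroids <- c(centroids, names(seqs)[i])
      rows[[i]] <- data.frame(centroid_id = names(seqs)[i],
                              member_id = names(seqs)[i], identity = 1,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(centroid_id = best_c,
                              member_id = names(seqs)[i], identity = best_id,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cloverleaf pairing map of a reference tRNA
#'
#' Positions (1-based, on a 72 nt tRNA body without CCA) of the paired
#' stems of the standard cloverleaf: acceptor stem 7 pairs, D-stem 4,
#' anticodon stem 5, T-stem 5, plus the anticodon positions. The default
#' corresponds to the canonical tRNA layout used by the synthetic template
#' generator; any reference with a self-consistent map is acceptable.
#'
#' @param refLength length of the reference body the map refers to.
#' @return list of class `"pairingMap"` with elements `stems` (named list
#'   of two-column matrices of paired positions) and `anticodon`
#'   (positions).
#' @export
defaultPairingMap <- function(refLength = 72) {
  pairs <- function(from, to) cbind(from, to)
  map <- list(
    stems = list(
      acceptor = pairs(1:7, 72:66),
      D = pairs(10:13, 25:22),
      anticodon = pairs(27:31, 43:39),
      T = pairs(49:53, 65:61)
    ),
    anticodon = 34:36
  )
  validatePairingMap(map, refLength)
  structure(map, class = "pairingMap")
}

validatePairingMap <- function(map, refLength) {
  all_pos <- unlist(lapply(map$stems, as.vector))
  if (any(all_pos < 1) || any(all_pos > refLength)) {
    stop("pairing index outside reference (length ", refLength, ")",
         call. = FALSE)
  }
  if (anyDuplicated(all_pos)) {
    stop("a position appears in two stem pairs", call. = FALSE)
  }
  invisible(map)
}

VALID_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")  # G:T = wobble G.U

#' Assess stem mispairing of a tRNA variant
#'
#' The variant is globally aligned to the reference and the stem pairing
#' positions are transferred through the alignment. A transferred pair is
#' counted as a mispair unless it is Watson-Crick or a G.U wobble (G:T in
#' DNA space). A stem position falling in an alignment gap sets the indel
#' flag for that stem: the structure is not evaluable there, the situation
#' of an 11 nt deletion removing a T-loop and part of the T-stem.
#'
#' @param variantSeq variant sequence (mature body, 5' to 3').
#' @param referenceSeq reference body the pairing map refers to.
#' @param pairing a [defaultPairingMap()]-style map.
#' @param scoring an [alignScoring()] scheme.
#' @return list with `perStem` (data.frame: stem, n_pairs, mispairs,
#'   indel) and `verdict` (`"canonical"` if no stem has a mispair or
#'   indel, else `"deviant"`).
#' @export
stemMispairCheck <- function(variantSeq, referenceSeq,
                             pairing = defaultPairingMap(nchar(referenceSeq)),
                             scoring = alignScoring()) {
  variantSeq <- as_dna_character(variantSeq)
  referenceSeq <- as_dna_character(referenceSeq)
  validatePairingMap(pairing, nchar(referenceSeq))
  aln <- alignGlobal(variantSeq, referenceSeq, scoring)
  va <- strsplit(aln$alignedA, "")[[1]]
  ra <- strsplit(aln$alignedB, "")[[1]]
  # reference position -> variant character ('-' when deleted)
  ref_to_var <- character(nchar(referenceSeq))
  rp <- 0L
  for (k in seq_along(ra)) {
    if (ra[k] != "-") {
      rp <- rp + 1L
      ref_to_var[rp] <- va[k]
    }
  }
  per <- lapply(names(pairing$stems), function(stem) {
    pm <- pairing$stems[[stem]]
    a <- ref_to_var[pm[, 1]]
    b <- ref_to_var[pm[, 2]]
    indel <- any(a == "-") || any(b == "-")
    ok <- paste0(a, b) %in% VALID_PAIRS
    ok[a == "-" | b == "-"] <- NA
    data.frame(stem = stem, n_pairs = nrow(pm),
               mispairs = sum(!ok, na.rm = TRUE), indel = indel,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  verdict <- if (any(per$mispairs > 0) || any(per$indel)) "deviant" else "canonical"
  list(perStem = per, verdict = verdict)
}
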