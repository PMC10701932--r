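# cluster detection from tRNA annotations

# gap in bases between consecutive sorted genes (negative = overlap)
diff_spacers <- function(gr) {
  n <- length(gr)
  if (n < 2) return(integer(0))
  GenomicRanges::start(gr)[-1] - GenomicRanges::end(gr)[-n] - 1L
}

#' Find tRNA gene clusters
#'
#' A cluster is a maximal run of tRNA genes on one sequence in which every
#' adjacent pair is separated by at most `maxGap` bases (strand is ignored
#' for membership, so divergently transcribed pairs cluster too). The
#' commonly used gap criterion for eukaryotic tRNA gene clusters is 1 kbp,
#' the default here. Pseudogenes never become members but are reported as
#' flanking features when they lie within `maxGap` of a cluster edge, the
#' situation of the conserved pseudogene upstream of the chromosome 5
#' tRNA-Cys cluster.
#'
#' @param annotations standardized annotation `GRanges` (see
#'   [readTrnaGff3()]); pseudogenes are recognized by
#'   `category == "pseudogene"`.
#' @param maxGap maximum intergenic distance in bp (default 1000).
#' @param minGenes minimum number of genes per reported cluster (default
#'   2; singletons are dropped).
#' @param sameIsotype additionally break runs where the isotype changes.
#' @param exclude optional `GRanges` of non-tRNA features (e.g.
#'   protein-coding genes); overlaps with reported clusters are attached as
#'   an attribute `"overlaps"` and messaged, not fatal -- tRNA clusters
#'   overlapping introns of coding genes are real and are kept.
#' @return list of [ClusterRegion-class] objects.
#' @examples
#' ann <- trnaAnnotation("chr5", c(1, 421, 841, 1261),
#'   c(72, 492, 912, 1332), "+", paste0("g", 1:4))
#' findClusters(ann)
#' @export
findClusters <- function(annotations, maxGap = 1000, minGenes = 2,
                         sameIsotype = FALSE, exclude = NULL) {
  if (maxGap < 0) stop("maxGap must be >= 0", call. = FALSE)
  if (length(annotations) == 0) return(list())
  annotations <- GenomicRanges::sort(annotations, ignore.strand = TRUE)
  has_cat <- "category" %in% colnames(S4Vectors::mcols(annotations))
  pseudo <- if (has_cat) annotations[annotations$category == "pseudogene"]
            else annotations[0]
  genes <- if (has_cat) annotations[annotations$category != "pseudogene"]
           else annotations
  if (length(genes) == 0) return(list())

  out <- list()
  for (sq in unique(as.character(GenomicRanges::seqnames(genes)))) {
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == sq]
    gaps <- diff_spacers(g)
    breaks <- gaps > maxGap
    if (sameIsotype && length(g) > 1) {
      iso <- g$isotype
      breaks <- breaks | (iso[-1] != iso[-length(iso)])
    }
    run <- cumsum(c(0L, as.integer(breaks)))
    for (r in unique(run)) {
      members <- g[run == r]
      if (length(members) < minGenes) next
      span_lo <- min(GenomicRanges::start(members)) - maxGap
      span_hi <- max(GenomicRanges::end(members)) + maxGap
      ps <- pseudo[as.character(GenomicRanges::seqnames(pseudo)) == sq &
                     GenomicRanges::end(pseudo) >= span_lo &
                     GenomicRanges::start(pseudo) <= span_hi]
      out[[length(out) + 1L]] <- methods::new(
        "ClusterRegion", seqid = sq, genes = members,
        maxGap = as.numeric(maxGap), flankingPseudogenes = ps
      )
    }
  }
  if (!is.null(exclude) && length(out)) {
    for (k in seq_along(out)) {
      span <- GenomicRanges::GRanges(out[[k]]@seqid, IRanges::IRanges(
        min(GenomicRanges::start(out[[k]]@genes)),
        max(GenomicRanges::end(out[[k]]@genes))))
      ov <- IRanges::subsetByOverlaps(exclude, span, ignore.strand = TRUE)
      if (length(ov)) {
        message("cluster on ", out[[k]]@seqid, " overlaps ", length(ov),
                " excluded feature(s); kept and flagged")
        attr(out[[k]], "overlaps") <- ov
      }
    }
  }
  out
}

#' @rdname classifyOrientation
#' @export
setMethod("classifyOrientation", "ClusterRegion", function(x) {
  s <- as.character(GenomicRanges::strand(x@genes))
  if (all(s == s[1])) return("head_to_tail")
  if (length(s) == 2) {
    if (identical(s, c("-", "+"))) return("head_to_head")
    if (identical(s, c("+", "-"))) return("tail_to_tail")
  }
  "mixed"
})

#' @rdname spacerLengths
#' @export
setMethod("spacerLengths", "ClusterRegion", function(x) diff_spacers(x@genes))

#' @rdname spacerLengths
#' @export
setMethod("hasOverlap", "ClusterRegion", function(x) any(diff_spacers(x@genes) < 0))

#' @rdname clusterGenes
#' @export
setMethod("clusterGenes", "ClusterRegion", function(x) x@genes)

setMethod("show", "ClusterRegion", function(object) {
  g <- object@genes
  cat("ClusterRegion on ", object@seqid, ": ", length(g), " genes [",
      min(GenomicRanges::start(g)), "-", max(GenomicRanges::end(g)), "], ",
      classifyOrientation(object), "\n", sep = "")
  sp <- spacerLengths(object)
  cat("  spacers (bp): ", paste(sp, collapse = ", "), "\n", sep = "")
  if (length(object@flankingPseudogenes)) {
    cat("  flanking pseudogenes: ",
        paste(object@flankingPseudogenes$gene_id, collapse = ", "), "\n",
        sep = "")
  }
  invisible(NULL)
})
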