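#' ClusterRegion: an ordered run of tRNA genes forming a cluster
#'
#' A maximal run of tRNA genes on one sequence in which every adjacent pair
#' is separated by at most the gap used at construction time. Genes are held
#' as a [GenomicRanges::GRanges] sorted by start, with metadata columns
#' `gene_id`, `isotype`, `anticodon`, `category` and `high_confidence`.
#' Pseudogenes found within `maxGap` of either cluster edge are kept in the
#' `flankingPseudogenes` slot rather than as members, reflecting the
#' convention that clusters are runs of genes while conserved upstream
#' pseudogene relics are flanking features.
#'
#' @slot seqid sequence (chromosome) name the cluster lies on.
#' @slot genes `GRanges` of member genes, sorted by start.
#' @slot maxGap maximum intergenic distance (bp) used at construction.
#' @slot flankingPseudogenes `GRanges` of pseudogenes within `maxGap` of an
#'   edge (possibly empty).
#'
#' @seealso [findClusters()], [classifyOrientation()], [spacerLengths()]
#' @export
setClass("ClusterRegion",
  representation(
    seqid = "character",
    genes = "GRanges",
    maxGap = "numeric",
    flankingPseudogenes = "GRanges"
  )
)

setValidity("ClusterRegion", function(object) {
  msgs <- character(0)
  if (length(object@genes) < 2) {
    msgs <- c(msgs, "a cluster needs at least 2 genes")
  }
  if (length(object@genes) &&
      is.unsorted(GenomicRanges::start(object@genes))) {
    msgs <- c(msgs, "genes must be sorted by start")
  }
  sp <- diff_spacers(object@genes)
  if (length(sp) && any(sp > object@maxGap)) {
    msgs <- c(msgs, "a spacer exceeds maxGap")
  }
  if (length(msgs)) msgs else TRUE
})

#' RepeatUnitSet: tandem repeat-unit decomposition of one cluster region
#'
#' The units of one accession's cluster, indexed 5' to 3' in the tRNA
#' transcription direction. Unit i spans from the start of gene i to the
#' start of gene i+1; the last unit extends by the median unit length,
#' clipped at the region end. Units are contiguous and non-overlapping.
#'
#' @slot accession accession (ecotype) label.
#' @slot clusterId cluster identifier.
#' @slot units `GRanges` in region-local coordinates with metadata columns
#'   `index` and `gene_id`.
#' @slot seqs `DNAStringSet` of unit sequences, one per unit.
#' @slot regionLength length (bp) of the region that was decomposed.
#' @slot clipped `TRUE` when the last unit was clipped at the region end.
#'
#' @seealso [decomposeCluster()], [buildUnitPanel()]
#' @export
setClass("RepeatUnitSet",
  representation(
    accession = "character",
    clusterId = "character",
    units = "GRanges",
    seqs = "DNAStringSet",
    regionLength = "integer",
    clipped = "logical"
  )
)

setValidity("RepeatUnitSet", function(object) {
  msgs <- character(0)
  n <- length(object@units)
  if (n == 0) msgs <- c(msgs, "at least one unit required")
  if (n != length(object@seqs)) {
    msgs <- c(msgs, "units and seqs lengths differ")
  }
  if (n > 1) {
    s <- GenomicRanges::start(object@units)
    e <- GenomicRanges::end(object@units)
    if (any(s[-1] != e[-n] + 1L)) {
      msgs <- c(msgs, "units must be contiguous and non-overlapping")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' UnitPanel: repeat units of several accessions with group correspondence
#'
#' Pools the repeat units of two or more accessions, the matrix of pairwise
#' global-alignment identities, the neighbor-joining tree built from the
#' corresponding p-distances, and the unit-to-group correspondence obtained
#' by cutting long branches of that tree (97% identity convention by
#' default).
#'
#' @slot unitSets named list of [RepeatUnitSet-class] objects.
#' @slot identity symmetric matrix of pairwise percent identities between
#'   all units.
#' @slot groups named integer vector: group label per unit.
#' @slot tree the `ape::phylo` neighbor-joining tree of the units.
#' @slot reference accession used as reference for structural-event calls.
#'
#' @seealso [buildUnitPanel()], [callStructuralEvents()]
#' @export
setClass("UnitPanel",
  representation(
    unitSets = "list",
    identity = "matrix",
    groups = "integer",
    tree = "ANY",
    reference = "character"
  )
)

#' TrnaExpression: gene- and variant-level tRNA read counts
#'
#' Result of assigning unique reads to reference loci. Gene-level counts
#' hold reads whose best local alignment is attained by exactly one locus;
#' variant-level counts additionally include reads tied between loci that
#' share one mature sequence variant. Accounting records, per library, how
#' every input read was spent (gene-assigned, variant-only, discarded as
#' multi-mapped across variants, or below the score floor), so that read
#' totals are conserved exactly.
#'
#' @slot geneCounts matrix loci x libraries of uniquely assigned raw counts.
#' @slot variantCounts matrix variants x libraries of raw counts (unique
#'   assignments rolled up plus variant-level rescues).
#' @slot loci data.frame describing the reference loci (gene_id,
#'   variant_id, mature/precursor references).
#' @slot normFactors per-library TMM scaling factors (NA until set).
#' @slot libSizes per-library totals used for normalization.
#' @slot normalized list with gene/variant normalized matrices (empty until
#'   [normalizeExpression()] is called).
#' @slot accounting per-library read accounting (data.frame).
#' @slot assignments per-unique-read assignment table.
#'
#' @seealso [assignReads()], [normalizeExpression()], [compareLibraries()]
#' @export
setClass("TrnaExpression",
  representation(
    geneCounts = "matrix",
    variantCounts = "matrix",
    loci = "data.frame",
    normFactors = "numeric",
    libSizes = "numeric",
    normalized = "list",
    accounting = "data.frame",
    assignments = "data.frame"
  )
)
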