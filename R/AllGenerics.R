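#' Classify the transcriptional orientation pattern of a cluster
#'
#' `head_to_tail` when all genes share one strand; for two-gene clusters,
#' `head_to_head` when the genes are transcribed divergently (ascending
#' coordinate strands `-`,`+`, transcription starts facing each other) and
#' `tail_to_tail` for `+`,`-`; anything else is `mixed`.
#'
#' @param x a [ClusterRegion-class].
#' @return one of `"head_to_tail"`, `"head_to_head"`, `"tail_to_tail"`,
#'   `"mixed"`.
#' @export
setGeneric("classifyOrientation", function(x) standardGeneric("classifyOrientation"))

#' Intergenic spacer lengths of a cluster
#'
#' Spacer i is the number of bases strictly between gene i and gene i+1.
#' Overlapping genes give negative values (flagged by [hasOverlap()]).
#'
#' @param x a [ClusterRegion-class].
#' @return integer vector of length `n_genes - 1`.
#' @export
setGeneric("spacerLengths", function(x) standardGeneric("spacerLengths"))

#' @rdname spacerLengths
#' @export
setGeneric("hasOverlap", function(x) standardGeneric("hasOverlap"))

#' @describeIn ClusterRegion member genes as a `GRanges`
#' @param x a `ClusterRegion`
#' @export
setGeneric("clusterGenes", function(x) standardGeneric("clusterGenes"))

#' Accessors for repeat-unit sets and panels
#'
#' @param x a [RepeatUnitSet-class] or [UnitPanel-class].
#' @return `unitRanges` the unit `GRanges`; `unitSeqs` the unit
#'   `DNAStringSet`; `unitGroups` the unit-to-group labels of a panel.
#' @export
setGeneric("unitRanges", function(x) standardGeneric("unitRanges"))

#' @rdname unitRanges
#' @export
setGeneric("unitSeqs", function(x) standardGeneric("unitSeqs"))

#' @rdname unitRanges
#' @export
setGeneric("unitGroups", function(x) standardGeneric("unitGroups"))

#' Accessors for expression results
#'
#' @param x a [TrnaExpression-class].
#' @param level `"gene"` or `"variant"`.
#' @return `geneCounts`/`variantCounts`: raw count matrices;
#'   `normalizedCounts`: TMM-normalized matrix at the requested level;
#'   `readAccounting`: the per-library read accounting table.
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname geneCounts
#' @export
setGeneric("variantCounts", function(x) standardGeneric("variantCounts"))

#' @rdname geneCounts
#' @export
setGeneric("normalizedCounts", function(x, level = "variant") standardGeneric("normalizedCounts"))

#' @rdname geneCounts
#' @export
setGeneric("readAccounting", function(x) standardGeneric("readAccounting"))
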