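# tandem repeat-unit decomposition and cross-accession structural events

#' Decompose a cluster region into tandem repeat units
#'
#' Unit boundaries are anchored at gene starts: unit i spans from the start
#' of gene i to the base before the start of gene i+1, so each unit is one
#' tRNA gene followed by its downstream spacer (~420 bp in the chromosome 5
#' tRNA-Cys cluster). The last unit extends by the rounded median of the
#' earlier unit lengths and is clipped at the region end. If most genes lie
#' on the minus strand the region is reverse-complemented first, so units
#' are always indexed 5' to 3' in the transcription direction.
#'
#' @param region the region sequence (character, `DNAString`, or
#'   length-one `DNAStringSet`).
#' @param genes `GRanges` of the tRNA genes in region-local 1-based
#'   coordinates.
#' @param accession accession label recorded in the result.
#' @param clusterId cluster label recorded in the result.
#' @return a [RepeatUnitSet-class].
#' @export
decomposeCluster <- function(region, genes, accession = "acc",
                             clusterId = "cluster") {
  if (methods::is(region, "DNAStringSet")) region <- region[[1]]
  region <- as_dna_character(region)
  L <- nchar(region)
  if (length(genes) == 0) stop("no genes in region", call. = FALSE)
  strands <- as.character(GenomicRanges::strand(genes))
  n_minus <- sum(strands == "-")
  n_plus <- sum(strands == "+")
  if (n_minus == n_plus && n_minus > 0) {
    stop("genes on both strands in equal number; orient the region explicitly",
         call. = FALSE)
  }
  if (n_minus > n_plus) {
    region <- revcomp_chr(region)
    new_start <- L - GenomicRanges::end(genes) + 1L
    new_end <- L - GenomicRanges::start(genes) + 1L
    genes <- make_trna_granges(
      as.character(GenomicRanges::seqnames(genes)), new_start, new_end,
      chartr("+-", "-+", strands), genes$gene_id, genes$isotype,
      genes$anticodon, genes$category, genes$high_confidence
    )
  }
  if (any(GenomicRanges::end(genes) > L)) {
    stop("gene outside region bounds", call. = FALSE)
  }
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  starts <- GenomicRanges::start(genes)
  n <- length(starts)
  if (n == 1) {
    ends <- L
  } else {
    med <- as.integer(round(median(diff(starts))))
    ends <- c(starts[-1] - 1L, min(starts[n] + med - 1L, L))
  }
  clipped <- n > 1 && (starts[n] + as.integer(round(median(diff(starts)))) - 1L) > L
  units <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(genes))[1],
    ranges = IRanges::IRanges(start = starts, end = ends), strand = "+"
  )
  S4Vectors::mcols(units) <- S4Vectors::DataFrame(
    index = seq_len(n), gene_id = genes$gene_id
  )
  seqs <- Biostrings::DNAStringSet(substring(region, starts, ends))
  names(seqs) <- paste0(accession, ".u", seq_len(n))
  methods::new("RepeatUnitSet", accession = accession, clusterId = clusterId,
               units = units, seqs = seqs, regionLength = as.integer(L),
               clipped = clipped)
}

#' @rdname unitRanges
#' @export
setMethod("unitRanges", "RepeatUnitSet", function(x) x@units)

#' @rdname unitRanges
#' @export
setMethod("unitSeqs", "RepeatUnitSet", function(x) x@seqs)

setMethod("length", "RepeatUnitSet", function(x) length(x@units))

setMethod("show", "RepeatUnitSet", function(object) {
  w <- GenomicRanges::width(object@units)
  cat("RepeatUnitSet '", object@accession, "': ", length(object@units),
      " units (", paste(w, collapse = ", "), " bp), region ",
      object@regionLength, " bp\n", sep = "")
  invisible(NULL)
})

#' Build a cross-accession repeat-unit panel
#'
#' Pools the units of several accessions, computes all pairwise
#' global-alignment identities, builds the NJ tree of the corresponding
#' p-distances, and assigns units to groups with [groupUnits()]. The
#' reference accession for structural-event calling defaults to the one
#' with the most units, since only the longest clusters exhibit all unit
#' groups.
#'
#' @param unitSets list of [RepeatUnitSet-class] objects (>= 2).
#' @param cut branch-length cut passed to [groupUnits()] (default 0.03,
#'   the 97% identity convention).
#' @param scoring an [alignScoring()] scheme.
#' @param reference accession name to use as reference; default the
#'   accession with the most units (earliest wins ties).
#' @return a [UnitPanel-class].
#' @export
buildUnitPanel <- function(unitSets, cut = 0.03, scoring = alignScoring(),
                           reference = NULL) {
  if (length(unitSets) < 2) stop("need at least 2 accessions", call. = FALSE)
  accs <- vapply(unitSets, function(u) u@accession, character(1))
  names(unitSets) <- accs
  if (is.null(reference)) {
    reference <- accs[which.max(vapply(unitSets, length, integer(1)))]
  }
  if (!reference %in% accs) {
    stop("reference accession '", reference, "' absent from panel", call. = FALSE)
  }
  seqs <- do.call(c, lapply(unitSets, function(u) as.character(u@seqs)))
  names(seqs) <- unlist(lapply(unitSets, function(u) names(u@seqs)))
  idm <- identityMatrix(seqs, scoring, digits = Inf)
  groups <- groupUnits(identity = idm, cut = cut)
  dm <- (100 - idm) / 100
  diag(dm) <- 0
  tree <- if (length(seqs) >= 3) njTree(dm) else NULL
  methods::new("UnitPanel", unitSets = unitSets, identity = idm,
               groups = groups, tree = tree, reference = reference)
}

#' @rdname unitRanges
#' @export
setMethod("unitGroups", "UnitPanel", function(x) x@groups)

setMethod("show", "UnitPanel", function(object) {
  cat("UnitPanel: ", length(object@unitSets), " accessions, ",
      length(object@groups), " units in ", max(object@groups),
      " groups; reference '", object@reference, "'\n", sep = "")
  for (acc in names(object@unitSets)) {
    u <- object@unitSets[[acc]]
    g <- object@groups[names(u@seqs)]
    cat("  ", acc, ": groups [", paste(g, collapse = " "), "]\n", sep = "")
  }
  invisible(NULL)
})

#' Call structural events between accessions of a unit panel
#'
#' Each non-reference accession's units are matched one-to-one to the
#' reference units (greedy, by decreasing global-alignment identity, with a
#' floor of `partialIdentity` below which a unit is considered unrelated).
#' Unmatched reference units are whole-unit deletions; surplus accession
#' units are whole-unit insertions. A length residual between the observed
#' region length and the total expected from matched whole units signals a
#' partial event: a positive residual smaller than a missing unit means
#' that unit is partially present, and the event size is the number of
#' bases missing from it; a negative residual is a deletion within a
#' matched unit. Residuals within `tol` of a unit length (fraction,
#' default 0.2) are ignored, so ordinary length jitter never becomes an
#' event.
#'
#' @param panel a [UnitPanel-class].
#' @param tol fraction of the median unit length below which a residual is
#'   noise (default 0.2).
#' @param partialIdentity minimum percent-identity fraction for a unit to
#'   be matched to a reference unit at all (default 0.5).
#' @return data.frame with columns `accession`, `kind`
#'   (`whole_unit_insertion`, `whole_unit_deletion`, `partial_deletion`),
#'   `affected_units` (reference group indices, comma separated) and
#'   `size` (bp).
#' @export
callStructuralEvents <- function(panel, tol = 0.2, partialIdentity = 0.5) {
  ref <- panel@unitSets[[panel@reference]]
  if (is.null(ref)) stop("reference accession absent", call. = FALSE)
  ref_names <- names(ref@seqs)
  ref_groups <- panel@groups[ref_names]
  ref_w <- GenomicRanges::width(ref@units)
  medL <- median(ref_w)
  tolbp <- tol * medL
  events <- list()
  add <- function(acc, kind, affected, size) {
    events[[length(events) + 1L]] <<- data.frame(
      accession = acc, kind = kind,
      affected_units = paste(affected, collapse = ","),
      size = as.numeric(size), stringsAsFactors = FALSE
    )
  }
  for (acc in names(panel@unitSets)) {
    if (acc == panel@reference) next
    uset <- panel@unitSets[[acc]]
    unames <- names(uset@seqs)
    idm <- panel@identity[unames, ref_names, drop = FALSE]
    # greedy one-to-one matching by decreasing identity
    match_ref <- rep(NA_integer_, length(unames))   # index into ref units
    match_id <- rep(NA_real_, length(unames))
    free_u <- seq_along(unames)
    free_r <- seq_along(ref_names)
    while (length(free_u) && length(free_r)) {
      sub <- idm[free_u, free_r, drop = FALSE]
      k <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      if (sub[k[1], k[2]] < 100 * partialIdentity) break
      ui <- free_u[k[1]]; ri <- free_r[k[2]]
      match_ref[ui] <- ri
      match_id[ui] <- idm[ui, ri]
      free_u <- setdiff(free_u, ui)
      free_r <- setdiff(free_r, ri)
    }
    matched <- which(!is.na(match_ref))
    inserted <- which(is.na(match_ref))
    missing <- setdiff(seq_along(ref_names), match_ref[matched])
    expected <- sum(ref_w[match_ref[matched]]) +
      sum(GenomicRanges::width(uset@units)[inserted])
    resid <- uset@regionLength - expected
    if (resid > tolbp && length(missing)) {
      # part of a missing unit is still present: prefer the missing unit
      # that follows the last matched one, the junction situation
      cand <- missing[ref_w[missing] > resid]
      if (length(cand)) {
        after <- cand[cand > max(match_ref[matched])]
        gstar <- if (length(after)) min(after) else min(cand)
        worst <- matched[which.min(match_id[matched])]
        add(acc, "partial_deletion",
            sort(unique(c(ref_groups[match_ref[worst]], ref_groups[gstar]))),
            ref_w[gstar] - resid)
        missing <- setdiff(missing, gstar)
      }
    } else if (resid < -tolbp && length(matched)) {
      worst <- matched[which.min(match_id[matched])]
      add(acc, "partial_deletion", ref_groups[match_ref[worst]], -resid)
    }
    for (g in missing) {
      add(acc, "whole_unit_deletion", ref_groups[g], ref_w[g])
    }
    for (u in inserted) {
      # label by the group of the inserted unit itself
      add(acc, "whole_unit_insertion", panel@groups[unames[u]],
          GenomicRanges::width(uset@units)[u])
    }
  }
  if (length(events) == 0) {
    return(data.frame(accession = character(0), kind = character(0),
                      affected_units = character(0), size = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, events)
}
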