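# tRNA-seq expression quantification: unique-read collapse, filters,
# precursor-aware best-hit assignment, normalization and library contrast

#' Collapse read libraries to unique sequences
#'
#' Exact-sequence collapse per library, merged into one table keyed by
#' sequence. Each library may be given as one file/set or several
#' (replicates), which are summed; totals are preserved exactly.
#'
#' @param libraries named list; each element a `DNAStringSet`, a character
#'   vector of read sequences, or paths to FASTA/FASTQ files.
#' @return data.frame with column `read_seq` and one count column per
#'   library; totals per library equal the input read numbers.
#' @export
collapseUnique <- function(libraries) {
  if (is.null(names(libraries)) || any(names(libraries) == "")) {
    stop("libraries must be a named list", call. = FALSE)
  }
  get_seqs <- function(x) {
    if (methods::is(x, "XStringSet")) return(as.character(x))
    if (is.character(x) && length(x) && all(file.exists(x))) {
      return(unlist(lapply(x, function(p) as.character(read_reads_file(p)))))
    }
    as_dna_character(x)
  }
  tabs <- lapply(libraries, function(x) {
    s <- unname(get_seqs(x))
    if (length(s) == 0) {
      warning("a library has zero reads", call. = FALSE)
      return(integer(0))
    }
    table(s)
  })
  all_seqs <- sort(unique(unlist(lapply(tabs, names))))
  out <- data.frame(read_seq = all_seqs, stringsAsFactors = FALSE)
  for (lib in names(tabs)) {
    cnt <- integer(length(all_seqs))
    t <- tabs[[lib]]
    if (length(t)) cnt[match(names(t), all_seqs)] <- as.integer(t)
    out[[lib]] <- cnt
  }
  out
}

#' Filter unique reads by length
#'
#' Keeps reads whose length is within `[min, max]` (bounds inclusive); the
#' default 55-110 nt window retains mature tRNAs and their precursors
#' while removing short degradation fragments and long contaminants.
#'
#' @param table a unique-read table from [collapseUnique()].
#' @param min,max inclusive length bounds.
#' @return the filtered table.
#' @export
lengthFilter <- function(table, min = 55, max = 110) {
  if (min <= 0 || min > max) stop("need 0 < min <= max", call. = FALSE)
  len <- nchar(table$read_seq)
  table[len >= min & len <= max, , drop = FALSE]
}

#' Remove reads not matched by a reference matcher
#'
#' The matcher embodies the contamination-cleaning contract: reads that do
#' not match any sequence of the expected taxon set are removed. Rows
#' removed are recorded in the `"removed"` attribute of the result; a
#' matcher failure is an error, never a silent keep.
#'
#' @param table a unique-read table.
#' @param matcher function mapping a character vector of read sequences to
#'   a logical vector (`TRUE` = match, keep). See
#'   [makeReferenceMatcher()] for the packaged scorer-backed matcher and
#'   [blastContaminationCommand()] for the external-tool adapter.
#' @return the filtered table with attribute `"removed"`.
#' @export
contaminationFilter <- function(table, matcher) {
  keep <- matcher(table$read_seq)
  if (!is.logical(keep) || length(keep) != nrow(table) || anyNA(keep)) {
    stop("matcher failed: must return one non-NA logical per read",
         call. = FALSE)
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- table[!keep, , drop = FALSE]
  out
}

#' Scorer-backed reference matcher
#'
#' A packaged matcher for [contaminationFilter()] using the package's
#' local aligner: a read matches when its best local alignment against any
#' reference sequence reaches the score a `minIdentity`-identity alignment
#' covering `minCoverage` of the read would attain. Reads here are whole
#' small-RNA molecules, so a genuine taxon match is expected to span the
#' read; the default identity of 0.72 at full coverage sits high enough
#' that chance local alignments of random 55-110 nt sequences essentially
#' never reach it, while true relatives of the reference set always do.
#' The external-tool adapter ([blastContaminationCommand()]) carries the
#' original 65% search sensitivity.
#'
#' @param refSeqs reference sequences of the expected taxon set.
#' @param minIdentity identity fraction a matching alignment corresponds
#'   to (default 0.72).
#' @param minCoverage fraction of the read the alignment must cover
#'   (default 1).
#' @param scoring an [alignScoring()] scheme.
#' @return a matcher function for [contaminationFilter()].
#' @export
makeReferenceMatcher <- function(refSeqs, minIdentity = 0.72,
                                 minCoverage = 1,
                                 scoring = alignScoring()) {
  refSeqs <- as_dna_character(refSeqs)
  force(minIdentity); force(minCoverage); force(scoring)
  per_base <- scoring$match * minIdentity + scoring$mismatch * (1 - minIdentity)
  function(seqs) {
    if (length(seqs) == 0) return(logical(0))
    sc <- local_score_matrix(seqs, refSeqs, scoring)
    best <- apply(sc, 1, max)
    best >= per_base * minCoverage * nchar(seqs)
  }
}

#' External-search adapter for the contamination filter
#'
#' Returns the command line for running the contamination search with an
#' external BLAST-style tool at the sensitivity settings this pipeline
#' assumes (`-word_size 6 -perc_identity 65 -dust no`). The command is
#' composed, not executed; its tabular output can be turned into a matcher
#' with `function(seqs) seqs %in% hits`.
#'
#' @param queryFasta path to the query FASTA of unique reads.
#' @param db BLAST database name.
#' @param out output path for the tabular result.
#' @return the command string.
#' @export
blastContaminationCommand <- function(queryFasta, db, out) {
  sprintf(paste("blastn -query %s -db %s -word_size 6 -perc_identity 65",
                "-dust no -soft_masking false -outfmt 6 -out %s"),
          queryFasta, db, out)
}

#' Construct a reference locus table for read assignment
#'
#' Each locus carries a mature reference (gene body plus the
#' post-transcriptional 3'-CCA) and a precursor reference (genomic
#' sequence with 5' leader and 3' trailer, no CCA). The mature reference
#' must end in CCA and the precursor must contain the gene body, which is
#' what lets flank-containing precursor reads discriminate loci whose
#' mature tRNAs are identical.
#'
#' @param gene_id,variant_id locus and mature-variant identifiers.
#' @param mature mature reference sequences (body + CCA).
#' @param precursor precursor reference sequences (leader + body +
#'   trailer).
#' @return data.frame of class `"referenceLoci"`.
#' @export
referenceLoci <- function(gene_id, variant_id, mature, precursor) {
  mature <- as_dna_character(mature)
  precursor <- as_dna_character(precursor)
  if (any(substring(mature, nchar(mature) - 2) != "CCA")) {
    stop("every mature reference must end in CCA", call. = FALSE)
  }
  body <- substring(mature, 1, nchar(mature) - 3)
  ok <- mapply(function(b, p) grepl(b, p, fixed = TRUE), body, precursor)
  if (!all(ok)) {
    stop("precursor reference must contain the gene body: ",
         gene_id[!ok][1], call. = FALSE)
  }
  if (anyDuplicated(gene_id)) stop("duplicate gene_id", call. = FALSE)
  structure(
    data.frame(gene_id = gene_id, variant_id = variant_id, mature = mature,
               precursor = precursor, stringsAsFactors = FALSE),
    class = c("referenceLoci", "data.frame")
  )
}

#' Assign unique reads to tRNA loci by best local alignment
#'
#' Every read is scored against each locus's mature and precursor
#' references with the affine local aligner; a locus's score is the better
#' of the two. A read is assigned at gene level iff exactly one locus
#' attains the maximum score; when several loci tie, the read is discarded
#' at gene level, but if all tied loci share one mature variant it still
#' counts at variant level -- the rule that lets identical gene copies be
#' quantified jointly while their precursor reads separate them. Reads
#' whose best score is below `minScoreFrac` of a perfect full-length match
#' are left unassigned.
#'
#' @param table a unique-read table (collapsed, filtered).
#' @param loci a [referenceLoci()] table.
#' @param scoring an [alignScoring()] scheme (match +5, mismatch -4, gap
#'   open 10, extend 0.5 by default).
#' @param minScoreFrac score floor as a fraction of `match * read length`
#'   (default 0.5).
#' @return a [TrnaExpression-class].
#' @export
assignReads <- function(table, loci, scoring = alignScoring(),
                        minScoreFrac = 0.5) {
  if (!nrow(loci)) stop("empty locus table", call. = FALSE)
  libs <- setdiff(colnames(table), "read_seq")
  if (!length(libs)) stop("table has no library columns", call. = FALSE)
  reads <- table$read_seq
  counts <- as.matrix(table[, libs, drop = FALSE])
  nl <- nrow(loci)
  if (nrow(table)) {
    sm <- local_score_matrix(reads, loci$mature, scoring)
    sp <- local_score_matrix(reads, loci$precursor, scoring)
    sc <- pmax(sm, sp)
  } else {
    sc <- matrix(0, 0, nl)
  }
  geneCounts <- matrix(0, nl, length(libs),
                       dimnames = list(loci$gene_id, libs))
  variants <- unique(loci$variant_id)
  variantCounts <- matrix(0, length(variants), length(libs),
                          dimnames = list(variants, libs))
  acct <- matrix(0, 4, length(libs),
                 dimnames = list(c("gene_assigned", "variant_only",
                                   "multi_discarded", "unassigned"), libs))
  assign_to <- character(nrow(table))
  level <- character(nrow(table))
  eps <- 1e-6
  for (r in seq_len(nrow(table))) {
    best <- max(sc[r, ])
    floor_score <- minScoreFrac * scoring$match * nchar(reads[r])
    if (best < floor_score) {
      level[r] <- "unassigned"
      assign_to[r] <- NA_character_
      acct["unassigned", ] <- acct["unassigned", ] + counts[r, ]
      next
    }
    tied <- which(sc[r, ] >= best - eps)
    if (length(tied) == 1) {
      gid <- loci$gene_id[tied]
      vid <- loci$variant_id[tied]
      geneCounts[gid, ] <- geneCounts[gid, ] + counts[r, ]
      variantCounts[vid, ] <- variantCounts[vid, ] + counts[r, ]
      acct["gene_assigned", ] <- acct["gene_assigned", ] + counts[r, ]
      assign_to[r] <- gid
      level[r] <- "gene"
    } else {
      vids <- unique(loci$variant_id[tied])
      if (length(vids) == 1) {
        variantCounts[vids, ] <- variantCounts[vids, ] + counts[r, ]
        acct["variant_only", ] <- acct["variant_only", ] + counts[r, ]
        assign_to[r] <- vids
        level[r] <- "variant"
      } else {
        acct["multi_discarded", ] <- acct["multi_discarded", ] + counts[r, ]
        assign_to[r] <- NA_character_
        level[r] <- "multi"
      }
    }
  }
  methods::new("TrnaExpression",
    geneCounts = geneCounts, variantCounts = variantCounts,
    loci = as.data.frame(loci), normFactors = setNames(rep(NA_real_, length(libs)), libs),
    libSizes = colSums(counts)[libs],
    normalized = list(),
    accounting = as.data.frame(t(acct)),
    assignments = data.frame(read_seq = reads, target = assign_to,
                             level = level, stringsAsFactors = FALSE)
  )
}

#' @rdname geneCounts
#' @export
setMethod("geneCounts", "TrnaExpression", function(x) x@geneCounts)

#' @rdname geneCounts
#' @export
setMethod("variantCounts", "TrnaExpression", function(x) x@variantCounts)

#' @rdname geneCounts
#' @export
setMethod("readAccounting", "TrnaExpression", function(x) x@accounting)

#' @rdname geneCounts
#' @export
setMethod("normalizedCounts", "TrnaExpression", function(x, level = "variant") {
  level <- match.arg(level, c("variant", "gene"))
  if (!length(x@normalized)) {
    stop("call normalizeExpression() first", call. = FALSE)
  }
  x@normalized[[level]]
})

setMethod("show", "TrnaExpression", function(object) {
  cat("TrnaExpression: ", nrow(object@geneCounts), " loci, ",
      nrow(object@variantCounts), " variants, libraries: ",
      paste(colnames(object@geneCounts), collapse = ", "), "\n", sep = "")
  print(object@accounting)
  invisible(NULL)
})

#' Apply TMM scaling to assigned counts
#'
#' Normalized counts are raw counts divided by the effective library size
#' (library total times TMM factor) and rescaled by the geometric mean of
#' the effective sizes, so values stay on a counts-like scale and a
#' normalized count is zero exactly when the raw count is.
#'
#' @param expr a [TrnaExpression-class].
#' @param factors per-library TMM factors; when `NULL` they are computed
#'   with [tmmFactors()] from `libSizes`-bearing unique-read counts in
#'   `table` (or, failing that, from the variant count matrix).
#' @param table optional unique-read table to compute factors from (the
#'   stage the normalization is defined on).
#' @return the updated `TrnaExpression`.
#' @export
normalizeExpression <- function(expr, factors = NULL, table = NULL) {
  libs <- colnames(expr@geneCounts)
  if (is.null(factors)) {
    m <- if (!is.null(table)) {
      as.matrix(table[, libs, drop = FALSE])
    } else {
      expr@variantCounts
    }
    factors <- tmmFactors(m)
  }
  if (is.null(names(factors))) names(factors) <- libs
  eff <- expr@libSizes[libs] * factors[libs]
  scale <- exp(mean(log(eff)))
  norm <- function(m) sweep(m, 2, eff, "/") * scale
  expr@normFactors <- factors[libs]
  expr@normalized <- list(gene = norm(expr@geneCounts),
                          variant = norm(expr@variantCounts))
  expr
}

#' Contrast control and deacylated libraries
#'
#' Per variant: `undetected` when both normalized counts are zero,
#' `ambiguous` when zero in exactly one library, otherwise `detected`.
#' Detected variants with a higher deacylated than control signal are
#' flagged `charged` (the tRNA pool carries amino acids, so deacylation
#' before ligation increases its representation); detected variants whose
#' mean normalized count falls below the `lowQuantile` quantile of the
#' positive variants are flagged `low`.
#'
#' @param expr a normalized [TrnaExpression-class].
#' @param control,treated library names (default `"control"`,
#'   `"deacylated"`).
#' @param lowQuantile quantile of positive variants under which expression
#'   is called low (default 0.1).
#' @param level `"variant"` (default) or `"gene"`.
#' @return data.frame with normalized counts, `status`, and logical
#'   `charged` / `low` flags.
#' @export
compareLibraries <- function(expr, control = "control",
                             treated = "deacylated", lowQuantile = 0.1,
                             level = "variant") {
  m <- normalizedCounts(expr, level)
  if (!all(c(control, treated) %in% colnames(m))) {
    stop("missing library: need '", control, "' and '", treated, "'",
         call. = FALSE)
  }
  ctl <- m[, control]
  trt <- m[, treated]
  status <- ifelse(ctl == 0 & trt == 0, "undetected",
                   ifelse(ctl == 0 | trt == 0, "ambiguous", "detected"))
  mean_expr <- (ctl + trt) / 2
  pos <- mean_expr[mean_expr > 0]
  low_thr <- if (length(pos)) quantile(pos, lowQuantile) else 0
  data.frame(
    id = rownames(m), control = ctl, deacylated = trt, status = status,
    charged = status == "detected" & trt > ctl,
    low = status != "undetected" & mean_expr > 0 & mean_expr < low_thr,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
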