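# end-to-end demo pipeline on synthetic data with a reproducibility manifest

default_pipeline_config <- function() {
  list(
    maxGap = 1000,        # cluster gap rule, bp
    minGenes = 2,
    cut = 0.03,           # unit grouping branch cut (97% identity)
    threshold = 0.97,     # greedy variant clustering identity
    depth = 4000,         # reads per simulated library
    errorRate = 0.01,
    contaminantFraction = 0.1,
    precursorFraction = 0.1,
    chargedFactor = 2,
    minScoreFrac = 0.5,
    lowQuantile = 0.1
  )
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates simulate -> detect -> decompose -> panel -> variants ->
#' expression -> report on generated data: a cluster panel is written to
#' and re-read from disk (exercising the format round trips), clusters are
#' detected and decomposed, units grouped and structural events called,
#' mature variants deduplicated and clustered, reads simulated and pushed
#' through collapse, length filter, contamination filter, assignment, TMM
#' normalization and the control/deacylated contrast, and cluster sizes
#' cross-checked by in-silico PCR. All stage outputs land under `outDir`
#' together with a JSON report whose manifest (seed and parameters)
#' suffices to reproduce the run bit-identically.
#'
#' @param outDir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param config named list overriding entries of the default
#'   configuration; unknown keys are rejected.
#' @return the report, invisibly.
#' @export
runPipeline <- function(outDir, seed = 1, config = list()) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # --- stage 1: synthetic panel, written to and re-read from disk
  panel <- makeClusterPanel(clusterSpec(seed = derive_seed(seed, 1)))
  panel_dir <- file.path(outDir, "panel")
  files <- writePanel(panel, panel_dir)
  clusters <- list()
  unit_sets <- list()
  for (acc in names(panel$accessions)) {
    ann <- readTrnaGff3(files[[acc]][["gff3"]])
    cl <- findClusters(ann, maxGap = cfg$maxGap, minGenes = cfg$minGenes)
    clusters[[acc]] <- cl
    reg <- extractClusterRegion(panel, acc)
    unit_sets[[acc]] <- decomposeCluster(reg$region, reg$genes,
                                         accession = acc)
  }

  # --- stage 2: unit panel, grouping, tree, structural events
  upanel <- buildUnitPanel(unit_sets, cut = cfg$cut)
  events <- callStructuralEvents(upanel)
  writeFasta(setNames(as.character(do.call(c, lapply(unit_sets, function(u)
    as.character(unitSeqs(u))))), names(unitGroups(upanel))),
    file.path(outDir, "units.fa"))
  ape::write.tree(upanel@tree, file.path(outDir, "units.nwk"))
  write.table(data.frame(unit = names(unitGroups(upanel)),
                         group = unitGroups(upanel)),
              file.path(outDir, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(events, file.path(outDir, "events.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  # --- stage 3: mature variants across the panel genomes
  gene_seqs <- unlist(lapply(names(panel$accessions), function(acc) {
    a <- panel$accessions[[acc]]
    g <- a$annotations[a$annotations$category == "gene"]
    as.character(geneSequences(a$genome, g))
  }))
  variants <- dedupeMature(gene_seqs)
  vgroups <- greedyCluster(setNames(variants$seq, variants$variant_id),
                           threshold = cfg$threshold)
  write.table(vgroups, file.path(outDir, "variant_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- stage 4: expression on a genome-wide locus set
  locus_set <- makeLocusSet(seed = derive_seed(seed, 2))
  rs <- readSimSpec(locus_set$expression, locus_set$charged,
                    depth = cfg$depth, errorRate = cfg$errorRate,
                    contaminantFraction = cfg$contaminantFraction,
                    precursorFraction = cfg$precursorFraction,
                    chargedFactor = cfg$chargedFactor,
                    seed = derive_seed(seed, 3))
  sim <- simulateReads(locus_set, rs)
  tab <- collapseUnique(sim$reads)
  n_in <- vapply(sim$reads, length, integer(1))
  tab <- lengthFilter(tab)
  matcher <- makeReferenceMatcher(locus_set$loci$precursor)
  tab <- contaminationFilter(tab, matcher)
  expr <- assignReads(tab, locus_set$loci, minScoreFrac = cfg$minScoreFrac)
  expr <- normalizeExpression(expr, table = tab)
  contrast <- compareLibraries(expr, lowQuantile = cfg$lowQuantile)
  write.table(contrast, file.path(outDir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- stage 5: in-silico PCR size confirmation
  pcr <- do.call(rbind, lapply(names(panel$accessions), function(acc) {
    p <- inSilicoPcr(panel$accessions[[acc]]$genome, CHR5_PRIMERS[["fwd"]],
                     CHR5_PRIMERS[["rev"]])
    if (nrow(p)) p$accession <- acc
    p
  }))
  write.table(pcr, file.path(outDir, "pcr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  acct <- readAccounting(expr)
  report <- list(
    manifest = list(seed = seed, config = cfg,
                    package_version = as.character(utils::packageVersion("cystra"))),
    accessions = lapply(names(panel$accessions), function(acc) list(
      accession = acc,
      n_clusters = length(clusters[[acc]]),
      n_units = length(unit_sets[[acc]]),
      orientation = if (length(clusters[[acc]]))
        classifyOrientation(clusters[[acc]][[1]]) else NA
    )),
    unit_groups = max(unitGroups(upanel)),
    structural_events = events,
    n_mature_variants = nrow(variants),
    n_variant_groups = length(unique(vgroups$centroid_id)),
    expression = list(
      libraries = rownames(acct),
      reads_in = as.list(setNames(n_in, names(n_in))),
      accounting = acct,
      tmm_factors = as.list(expr@normFactors),
      undetected = contrast$id[contrast$status == "undetected"],
      charged = contrast$id[contrast$charged]
    ),
    pcr_product_sizes = if (!is.null(pcr) && nrow(pcr))
      setNames(as.list(pcr$size), pcr$accession) else list()
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_lines <- c(
    sprintf("accessions: %s", paste(names(panel$accessions), collapse = ", ")),
    sprintf("unit counts: %s", paste(vapply(unit_sets, length, integer(1)),
                                     collapse = ", ")),
    sprintf("unit groups: %d", max(unitGroups(upanel))),
    sprintf("structural events: %d", nrow(events)),
    sprintf("mature variants: %d", nrow(variants)),
    sprintf("undetected variants: %s",
            paste(contrast$id[contrast$status == "undetected"], collapse = ", "))
  )
  writeLines(summary_lines, file.path(outDir, "summary.txt"))
  invisible(report)
}
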