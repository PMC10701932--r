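# Seeded synthetic-data generators: genomes carrying a tandem tRNA-Cys-like
# cluster across accessions, genome-wide locus sets, and read libraries,
# all with recorded ground truth so every pipeline stage is testable
# without external downloads.

# the chromosome 5 cluster primer pair used for in-silico PCR size checks
CHR5_PRIMERS <- c(fwd = "CTGATCGTTTGACTTGACACG", rev = "ATGGTACCTAGGTGTTTGACC")

# draw a cloverleaf-consistent 72 nt tRNA body from the current RNG stream
template_rng <- function() {
  map <- defaultPairingMap(72)
  chars <- sample(DNA_BASES, 72, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (stem in map$stems) {
    for (r in seq_len(nrow(stem))) {
      chars[stem[r, 2]] <- comp[[chars[stem[r, 1]]]]
    }
  }
  chars[map$anticodon] <- c("G", "C", "A")
  list(seq = paste(chars, collapse = ""), pairing = map,
       anticodon = map$anticodon)
}

#' Generate a cloverleaf-consistent tRNA-Cys-GCA-like template
#'
#' A 72 nt tRNA body in which every stem pair of the standard cloverleaf
#' map is Watson-Crick complementary and the anticodon positions read GCA.
#' Deterministic per seed.
#'
#' @param seed integer seed.
#' @return list with `seq` (72 nt), `pairing` (a [defaultPairingMap()])
#'   and `anticodon` (positions).
#' @export
makeTrnaTemplate <- function(seed = 1) {
  with_seed(seed, template_rng())
}

#' Specification of a synthetic cluster panel
#'
#' Defaults encode the study conditions the generator emulates: ~420 bp
#' units, accessions with four to six units plus one accession carrying a
#' 167 bp deletion spanning a unit junction (95 bp of one unit plus the
#' whole 72 bp tRNA gene of the next), a conserved upstream pseudogene,
#' identical 500 bp flanks and the cluster-flanking primer sites.
#'
#' @param unitLength unit length in bp (default 420).
#' @param nUnits named integer vector of unit counts per accession, values
#'   in 2..6 (default `c(colLike=4, lerLike=5, bigSix=6, cviLike=4)`).
#' @param divergence substitution probability between unit-group
#'   prototypes (default 0.05; yields within-cluster unit identities in
#'   the mid-80s to mid-90s percent band).
#' @param accessionDivergence substitution probability of an accession's
#'   unit relative to its group prototype (default 0.01, well inside the
#'   97% grouping convention).
#' @param partialDeletion `NULL`, or list with `accession`, `junction`
#'   (unit whose tail is removed) and `upstreamBp` (bases removed upstream
#'   of the junction); the deletion also removes the following unit's
#'   gene, so its total size is `upstreamBp + 72`.
#' @param pseudogene plant the conserved upstream pseudogene (default
#'   `TRUE`).
#' @param flankLength flank length in bp (default 500).
#' @param seed integer seed.
#' @return list of class `"clusterSpec"`.
#' @export
clusterSpec <- function(unitLength = 420,
                        nUnits = c(colLike = 4, lerLike = 5, bigSix = 6,
                                   cviLike = 4),
                        divergence = 0.05, accessionDivergence = 0.01,
                        partialDeletion = list(accession = "cviLike",
                                               junction = 3, upstreamBp = 95),
                        pseudogene = TRUE, flankLength = 500, seed = 101) {
  if (divergence < 0 || divergence >= 1 || accessionDivergence < 0 ||
      accessionDivergence >= 1) {
    stop("divergence probabilities must be in [0, 1)", call. = FALSE)
  }
  if (is.null(names(nUnits)) || any(names(nUnits) == "")) {
    stop("nUnits must be named by accession", call. = FALSE)
  }
  if (any(nUnits < 2) || any(nUnits > 6)) {
    stop("nUnits values must be in 2..6", call. = FALSE)
  }
  if (unitLength < 150) stop("unitLength must exceed the 72 nt gene plus spacer", call. = FALSE)
  if (!is.null(partialDeletion)) {
    if (!partialDeletion$accession %in% names(nUnits)) {
      stop("partialDeletion accession not in nUnits", call. = FALSE)
    }
    if (partialDeletion$junction >= nUnits[[partialDeletion$accession]]) {
      stop("partialDeletion junction must precede the last unit", call. = FALSE)
    }
    if (partialDeletion$upstreamBp + 72 >= 2 * unitLength) {
      stop("deletion size must be below twice the unit length", call. = FALSE)
    }
  }
  structure(list(unitLength = unitLength, nUnits = nUnits,
                 divergence = divergence,
                 accessionDivergence = accessionDivergence,
                 partialDeletion = partialDeletion, pseudogene = pseudogene,
                 flankLength = flankLength, seed = seed),
            class = "clusterSpec")
}

#' Generate a synthetic multi-accession cluster panel
#'
#' Builds, per accession, a genome sequence (single "chr5"-like record)
#' carrying identical flanks, an upstream tRNA-derived pseudogene, the
#' cluster-flanking primer sites, and a tandem cluster of units derived
#' from six group prototypes (accession with n units carries groups 1..n).
#' Each unit is one 72 nt tRNA gene plus spacer, with one CTAGY motif
#' planted per unit and the anticodon kept intact. Whole-unit differences
#' between accessions and the optional junction-spanning deletion are
#' recorded in a per-accession truth table.
#'
#' @param spec a [clusterSpec()].
#' @return list of class `"clusterPanel"`: per-accession `genome`
#'   (`DNAStringSet`), `annotations` (standardized `GRanges`, pseudogene
#'   included), and `truth` (cluster span, unit boundaries, group labels,
#'   deletion record); plus the `template` and the `spec`.
#' @export
makeClusterPanel <- function(spec = clusterSpec()) {
  stopifnot(inherits(spec, "clusterSpec"))
  with_seed(spec$seed, {
    template <- template_rng()
    geneLen <- 72L
    uL <- spec$unitLength
    spacerLen <- uL - geneLen
    ctag_off <- geneLen + 100L            # CTAGT planted at unit positions 173-177
    protect <- c(template$anticodon, ctag_off + 1:5)
    plant <- function(seq, motif, at) {
      paste0(substring(seq, 1, at - 1), motif,
             substring(seq, at + nchar(motif)))
    }
    ancestral <- plant(paste0(template$seq, random_dna(spacerLen)),
                       "CTAGT", ctag_off + 1L)
    prototypes <- vapply(1:6, function(g) {
      plant(mutate_dna(ancestral, spec$divergence, protect), "CTAGT",
            ctag_off + 1L)
    }, character(1))

    fL <- spec$flankLength
    flank5 <- random_dna(fL)
    flank5 <- plant(flank5, CHR5_PRIMERS[["fwd"]], 51L)
    pseudo_at <- 201L
    pseudo_seq <- NULL
    if (spec$pseudogene) {
      subs <- sample(setdiff(seq_len(geneLen), template$anticodon), 3)
      pseudo_seq <- mutate_dna(template$seq, 1, protect = setdiff(seq_len(geneLen), subs))
      flank5 <- plant(flank5, pseudo_seq, pseudo_at)
    }
    flank3 <- plant(random_dna(fL), revcomp_chr(CHR5_PRIMERS[["rev"]]),
                    fL - 120L)

    accessions <- list()
    for (acc in names(spec$nUnits)) {
      n <- spec$nUnits[[acc]]
      groups <- seq_len(n)
      unit_seqs <- vapply(groups, function(g) {
        plant(mutate_dna(prototypes[g], spec$accessionDivergence, protect),
              "CTAGT", ctag_off + 1L)
      }, character(1))
      cluster <- paste(unit_seqs, collapse = "")
      genome_seq <- paste0(flank5, cluster, flank3)
      cluster_start <- fL + 1L
      unit_starts <- cluster_start + (groups - 1L) * uL
      unit_ends <- unit_starts + uL - 1L
      gene_starts <- unit_starts
      gene_present <- rep(TRUE, n)
      deletion <- NULL

      pd <- spec$partialDeletion
      if (!is.null(pd) && pd$accession == acc) {
        size <- pd$upstreamBp + geneLen
        del_start <- cluster_start + pd$junction * uL - pd$upstreamBp
        genome_seq <- paste0(substring(genome_seq, 1, del_start - 1),
                             substring(genome_seq, del_start + size))
        gene_present[pd$junction + 1L] <- FALSE
        shift <- function(x) ifelse(x >= del_start, x - size, x)
        gene_starts <- shift(gene_starts)
        unit_starts <- shift(unit_starts)
        unit_ends <- ifelse(unit_ends >= del_start, unit_ends - size,
                            unit_ends)
        deletion <- list(start = del_start, size = size,
                         junction = pd$junction)
      }

      ann_start <- gene_starts[gene_present]
      ann <- trnaAnnotation(
        "chr5", ann_start, ann_start + geneLen - 1L, "+",
        gene_id = sprintf("%s.trnaCys%d", acc, groups[gene_present])
      )
      if (spec$pseudogene) {
        ps <- trnaAnnotation("chr5", pseudo_at, pseudo_at + geneLen - 1L,
                             "+", gene_id = paste0(acc, ".pseudoCys"),
                             category = "pseudogene",
                             high_confidence = FALSE)
        ann <- GenomicRanges::sort(c(ann, ps), ignore.strand = TRUE)
      }
      genome <- Biostrings::DNAStringSet(genome_seq)
      names(genome) <- "chr5"
      accessions[[acc]] <- list(
        genome = genome, annotations = ann,
        truth = list(
          accession = acc, n_units = n, groups = groups,
          cluster_start = cluster_start, cluster_end = max(unit_ends),
          unit_starts = unit_starts, unit_ends = unit_ends,
          gene_present = gene_present, deletion = deletion,
          pseudogene_start = if (spec$pseudogene) pseudo_at else NA
        )
      )
    }
    structure(list(accessions = accessions, template = template,
                   pseudogene = pseudo_seq, spec = spec),
              class = "clusterPanel")
  })
}

#' Extract an accession's cluster region and region-local gene annotations
#'
#' Uses the panel truth to delimit the syntenic cluster span (with real
#' assemblies this delimitation comes from flank homology); coordinates of
#' the tRNA genes are shifted to be 1-based within the region, ready for
#' [decomposeCluster()].
#'
#' @param panel a [makeClusterPanel()] result.
#' @param accession accession name.
#' @return list with `region` (character) and `genes` (`GRanges`).
#' @export
extractClusterRegion <- function(panel, accession) {
  acc <- panel$accessions[[accession]]
  if (is.null(acc)) stop("unknown accession: ", accession, call. = FALSE)
  tr <- acc$truth
  region <- substring(as.character(acc$genome[[1]]), tr$cluster_start,
                      tr$cluster_end)
  ann <- acc$annotations
  ann <- ann[ann$category == "gene"]
  genes <- make_trna_granges(
    "region", GenomicRanges::start(ann) - tr$cluster_start + 1L,
    GenomicRanges::end(ann) - tr$cluster_start + 1L,
    as.character(GenomicRanges::strand(ann)), ann$gene_id, ann$isotype,
    ann$anticodon, ann$category, ann$high_confidence
  )
  list(region = region, genes = genes)
}

#' Write a cluster panel to FASTA + GFF3 files
#'
#' @param panel a [makeClusterPanel()] result.
#' @param dir output directory (created if needed).
#' @return named list of written file pairs, invisibly.
#' @export
writePanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (acc in names(panel$accessions)) {
    fa <- file.path(dir, paste0(acc, ".fa"))
    gff <- file.path(dir, paste0(acc, ".gff3"))
    writeFasta(panel$accessions[[acc]]$genome, fa)
    writeTrnaGff3(panel$accessions[[acc]]$annotations, gff)
    out[[acc]] <- c(fasta = fa, gff3 = gff)
  }
  invisible(out)
}

#' Generate a genome-wide tRNA-Cys locus set
#'
#' Sixteen loci carrying thirteen unique mature variants by default: three
#' variants are each present at two loci with distinct genomic flanks
#' (the situation in which only precursor reads can discriminate the
#' copies), the remaining ten variants at one locus each. Variant bodies
#' differ from the template by one to three substitutions outside the
#' anticodon, placed within the first 50 nt of the body so that every read
#' passing the 55 nt length filter covers all variant-distinguishing
#' positions (3'-truncated mature reads therefore never blur variants,
#' only gene copies of the same variant). The default expression vector
#' leaves the loci of the last two variants silent.
#'
#' @param seed integer seed.
#' @param nLoci number of loci (default 16).
#' @param nVariants number of unique mature variants (default 13; the
#'   first `nLoci - nVariants` variants are duplicated at two loci).
#' @param flankLength leader/trailer length of the precursor references
#'   (default 30).
#' @param nSilent number of trailing single-copy variants with zero
#'   default expression (default 2).
#' @return list with `loci` (a [referenceLoci()] table), `expression`
#'   (named by gene_id), `charged` (named logical), `template`.
#' @export
makeLocusSet <- function(seed = 202, nLoci = 16, nVariants = 13,
                         flankLength = 30, nSilent = 2) {
  stopifnot(nVariants <= nLoci, nLoci - nVariants < nVariants,
            nSilent < nVariants - (nLoci - nVariants))
  with_seed(seed, {
    template <- template_rng()
    geneLen <- nchar(template$seq)
    bodies <- character(nVariants)
    bodies[1] <- template$seq
    pool <- setdiff(seq_len(50), template$anticodon)
    for (v in 2:nVariants) {
      repeat {
        k <- sample(1:3, 1)
        pos <- sample(pool, k)
        cand <- mutate_dna(template$seq, 1,
                           protect = setdiff(seq_len(geneLen), pos))
        if (!cand %in% bodies[seq_len(v - 1)]) {
          bodies[v] <- cand
          break
        }
      }
    }
    nDup <- nLoci - nVariants
    variant_of <- c(rep(seq_len(nDup), each = 2),
                    seq(nDup + 1, nVariants))
    gene_id <- sprintf("tCys-%02d", seq_len(nLoci))
    variant_id <- sprintf("var-%02d", variant_of)
    leader <- vapply(seq_len(nLoci), function(i) random_dna(flankLength),
                     character(1))
    trailer <- vapply(seq_len(nLoci), function(i) random_dna(flankLength),
                      character(1))
    loci <- referenceLoci(
      gene_id, variant_id,
      mature = paste0(bodies[variant_of], "CCA"),
      precursor = paste0(leader, bodies[variant_of], trailer)
    )
    expression <- setNames(round(exp(rnorm(nLoci, log(50), 1))), gene_id)
    silent_variants <- sprintf("var-%02d", seq(nVariants - nSilent + 1, nVariants))
    expression[variant_id %in% silent_variants] <- 0
    # charged status is a property of the variant (odd-numbered expressed
    # variants charged), so gene copies of one variant always agree
    charged <- setNames(expression > 0 & variant_of %% 2 == 1, gene_id)
    list(loci = loci, expression = expression, charged = charged,
         template = template)
  })
}

#' Specification for read simulation
#'
#' @param expression named non-negative expression vector per gene.
#' @param charged named logical: genes whose tRNA pool is aminoacylated;
#'   their representation is multiplied by `chargedFactor` in the
#'   deacylated library.
#' @param depth reads per library (default 20000).
#' @param precursorFraction fraction of signal reads carrying genomic
#'   flank (default 0.1).
#' @param errorRate per-base substitution error (default 0.01).
#' @param contaminantFraction fraction of non-tRNA contaminant reads
#'   (default 0.1).
#' @param chargedFactor deacylated/control enrichment of charged genes
#'   (default 2).
#' @param readLengthRange mature-read length window (default 55-110 nt).
#' @param flankMin minimum flank bases a precursor read carries (default
#'   5).
#' @param seed integer seed.
#' @return list of class `"readSimSpec"`.
#' @export
readSimSpec <- function(expression, charged = NULL, depth = 20000,
                        precursorFraction = 0.1, errorRate = 0.01,
                        contaminantFraction = 0.1, chargedFactor = 2,
                        readLengthRange = c(55, 110), flankMin = 5,
                        seed = 303) {
  if (any(expression < 0)) stop("expression must be non-negative", call. = FALSE)
  if (depth >= 1 && all(expression == 0)) {
    stop("all-zero expression vector with positive depth", call. = FALSE)
  }
  for (f in c(precursorFraction, errorRate, contaminantFraction)) {
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]", call. = FALSE)
  }
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (is.null(charged)) charged <- setNames(expression > 0, names(expression))
  structure(list(expression = expression, charged = charged, depth = depth,
                 precursorFraction = precursorFraction,
                 errorRate = errorRate,
                 contaminantFraction = contaminantFraction,
                 chargedFactor = chargedFactor,
                 readLengthRange = readLengthRange, flankMin = flankMin,
                 seed = seed),
            class = "readSimSpec")
}

#' Simulate control and deacylated tRNA-seq read libraries
#'
#' Signal reads are drawn per gene proportionally to the expression
#' vector; mature reads are the mature reference (CCA included) truncated
#' from the 3' end into the length window, precursor reads carry at least
#' `flankMin` genomic flank bases on one side; substitution errors are
#' applied at `errorRate`; contaminants come from an unrelated random
#' pool. Deacylation renders aminoacylated (charged) tRNAs ligatable, so
#' in the deacylated library charged genes contribute `chargedFactor`
#' times more molecules and the library yield grows accordingly: the
#' expected deacylated/control count ratio is `chargedFactor` for charged
#' genes and 1 for uncharged ones. Every read has a truth entry (source
#' gene, class).
#'
#' @param locusSet a [makeLocusSet()] result (or list with `loci`).
#' @param spec a [readSimSpec()].
#' @return list with `reads` (named list of `DNAStringSet`: control,
#'   deacylated) and `truth` (data.frame: read id, library, class, gene,
#'   variant).
#' @export
simulateReads <- function(locusSet, spec) {
  stopifnot(inherits(spec, "readSimSpec"))
  loci <- locusSet$loci
  expr <- spec$expression[loci$gene_id]
  body <- substring(loci$mature, 1, nchar(loci$mature) - 3)
  bodyLen <- nchar(body)
  leadLen <- trailLen <- (nchar(loci$precursor) - bodyLen) / 2
  with_seed(spec$seed, {
    out_reads <- list()
    out_truth <- list()
    w_control <- expr
    for (lib in c("control", "deacylated")) {
      w <- expr
      if (lib == "deacylated") {
        ch <- spec$charged[loci$gene_id]
        w <- w * ifelse(ch, spec$chargedFactor, 1)
      }
      # library yield scales with the ligatable molecule pool
      lib_depth <- round(spec$depth * sum(w) / sum(w_control))
      nContam <- round(lib_depth * spec$contaminantFraction)
      nSignal <- lib_depth - nContam
      gi <- sample(seq_len(nrow(loci)), nSignal, replace = TRUE,
                   prob = w)
      is_prec <- runif(nSignal) < spec$precursorFraction
      reads <- character(nSignal)
      lmin <- spec$readLengthRange[1]
      for (k in seq_len(nSignal)) {
        i <- gi[k]
        if (is_prec[k]) {
          take <- sample(spec$flankMin:trailLen[i], 1)
          if (runif(1) < 0.5) {
            reads[k] <- paste0(body[i],
                               substring(loci$precursor[i],
                                         leadLen[i] + bodyLen[i] + 1,
                                         leadLen[i] + bodyLen[i] + take))
          } else {
            reads[k] <- paste0(substring(loci$precursor[i],
                                         leadLen[i] - take + 1, leadLen[i]),
                               body[i])
          }
        } else {
          len <- sample(lmin:min(spec$readLengthRange[2],
                                 nchar(loci$mature[i])), 1)
          reads[k] <- substring(loci$mature[i], 1, len)
        }
      }
      if (spec$errorRate > 0) {
        reads <- vapply(reads, mutate_dna, character(1),
                        rate = spec$errorRate, USE.NAMES = FALSE)
      }
      contam <- vapply(seq_len(nContam), function(k) {
        random_dna(sample(spec$readLengthRange[1]:spec$readLengthRange[2], 1),
                   gc = 0.4)
      }, character(1))
      all_reads <- c(reads, contam)
      ids <- sprintf("%s_r%06d", lib, seq_along(all_reads))
      rs <- Biostrings::DNAStringSet(all_reads)
      names(rs) <- ids
      out_reads[[lib]] <- rs
      out_truth[[lib]] <- data.frame(
        read_id = ids, library = lib, read_seq = all_reads,
        class = c(ifelse(is_prec, "precursor", "mature"),
                  rep("contaminant", nContam)),
        gene = c(loci$gene_id[gi], rep(NA_character_, nContam)),
        variant = c(loci$variant_id[gi], rep(NA_character_, nContam)),
        stringsAsFactors = FALSE
      )
    }
    list(reads = out_reads, truth = do.call(rbind, out_truth))
  })
}
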