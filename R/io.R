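#' Read a DNA FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`, so downstream code
#' always sees DNA over \{A,C,G,T,N\}. Record ids are the first whitespace
#' token of each header; duplicated ids and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by record id.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgu"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(chartr("Uu", "Tt", as.character(x)))
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(ids == "")) stop("FASTA record with empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  check_dna(seqs, "FASTA sequence")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

# read a FASTA or FASTQ read file based on its first non-empty character
read_reads_file <- function(path) {
  first <- substr(trimws(readLines(path, n = 1L)), 1, 1)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  names(x) <- vapply(strsplit(names(x), "[ \t]+"), `[`, character(1), 1L)
  x
}

# standardized tRNA annotation GRanges used throughout the package
make_trna_granges <- function(seqid, start, end, strand, gene_id, isotype,
                              anticodon, category, high_confidence) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = gene_id, isotype = isotype, anticodon = anticodon,
    category = category, high_confidence = high_confidence
  )
  gr
}

#' Read tRNA gene annotations from a GFF3 file
#'
#' Keeps features whose type is in `types` (tRNA genes and tRNA
#' pseudogenes). GFF3 1-based inclusive coordinates are carried unchanged
#' into the returned `GRanges` (the R convention); the strand is preserved.
#' Attributes `ID`/`Name`, `isotype`, `anticodon` and `high_confidence` are
#' read when present.
#'
#' @param path path to a GFF3 file.
#' @param types feature types treated as tRNA genes (default `"tRNA"`) --
#'   types listed in `pseudoTypes` become `category = "pseudogene"`.
#' @param pseudoTypes feature types treated as tRNA pseudogenes.
#' @return `GRanges` with metadata columns `gene_id`, `isotype`,
#'   `anticodon`, `category`, `high_confidence`.
#' @export
readTrnaGff3 <- function(path, types = "tRNA",
                         pseudoTypes = c("pseudogene", "tRNA_pseudogene")) {
  # light pre-validation so coordinate errors carry a line number
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) next
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (!is.na(s) && !is.na(e) && s > e) {
      stop("GFF3 line ", i, ": start > end", call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c(types, pseudoTypes)
  gr <- gr[keep]
  if (length(gr) == 0) {
    return(make_trna_granges(character(0), integer(0), integer(0),
                             character(0), character(0), character(0),
                             character(0), character(0), logical(0)))
  }
  meta <- S4Vectors::mcols(gr)
  get_attr <- function(name, default) {
    if (name %in% colnames(meta)) {
      v <- as.character(meta[[name]])
      ifelse(is.na(v), default, v)
    } else rep(default, length(gr))
  }
  ids <- get_attr("ID", NA_character_)
  nm <- get_attr("Name", NA_character_)
  ids <- ifelse(is.na(ids), nm, ids)
  ids[is.na(ids)] <- paste0("trna_", seq_len(sum(is.na(ids))))
  hc <- get_attr("high_confidence", "NA")
  out <- make_trna_granges(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = ids,
    isotype = get_attr("isotype", NA_character_),
    anticodon = get_attr("anticodon", NA_character_),
    category = ifelse(as.character(gr$type) %in% pseudoTypes,
                      "pseudogene", "gene"),
    high_confidence = hc %in% c("TRUE", "true", "1", "yes")
  )
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         out$gene_id[duplicated(out$gene_id)][1], call. = FALSE)
  }
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Read a tRNAscan-SE 2.0 tabular output file
#'
#' Parses the tab-separated output (columns: sequence name, tRNA number,
#' begin, end, isotype, anticodon, intron bounds, score and an optional
#' note). Rows with `begin > end` are reverse-strand genes: coordinates are
#' swapped and the strand set to `-`. Rows whose note matches an entry of
#' `noteMap` are flagged as pseudogenes. High confidence is taken from
#' `highConfidenceIds` (a companion high-confidence filter output) when
#' supplied, otherwise from the absence of "pseudo"/"not high confidence"
#' notes.
#'
#' @param path path to the tabular output.
#' @param highConfidenceIds optional character vector of gene ids (in the
#'   `seqname.trnaN` form) that passed the high-confidence filter.
#' @param noteMap named character vector mapping note substrings to
#'   categories; the tRNAscan-SE note vocabulary varies between versions so
#'   the mapping is configurable.
#' @return `GRanges` in the same standardized form as [readTrnaGff3()].
#' @export
readTrnascanTable <- function(path, highConfidenceIds = NULL,
                              noteMap = c(pseudo = "pseudogene")) {
  lines <- readLines(path)
  lines <- lines[lines != ""]
  # drop the up-to-three header lines (column names + dashes)
  is_header <- grepl("^(Sequence|Name|chr)?\\s*\\t?(Name|tRNA)", lines) |
    grepl("^-{2,}", lines)
  body <- lines[!is_header]
  if (length(body) == 0) {
    return(make_trna_granges(character(0), integer(0), integer(0),
                             character(0), character(0), character(0),
                             character(0), character(0), logical(0)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  fields <- lapply(fields, trimws)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6) stop("tRNAscan row ", i, ": too few columns", call. = FALSE)
    num <- suppressWarnings(as.integer(f[c(2, 3, 4)]))
    if (anyNA(num)) stop("tRNAscan row ", i, ": malformed numeric field", call. = FALSE)
    begin <- num[2]; end <- num[3]
    strand <- if (begin > end) "-" else "+"
    note <- if (length(f) >= 10) f[10] else ""
    category <- "gene"
    for (k in seq_along(noteMap)) {
      if (grepl(names(noteMap)[k], note, ignore.case = TRUE)) {
        category <- unname(noteMap[k])
      }
    }
    gene_id <- paste0(f[1], ".trna", num[1])
    hc <- if (!is.null(highConfidenceIds)) {
      gene_id %in% highConfidenceIds
    } else {
      !grepl("pseudo|not high confidence", note, ignore.case = TRUE)
    }
    out[[i]] <- data.frame(
      seqid = f[1], start = min(begin, end), end = max(begin, end),
      strand = strand, gene_id = gene_id, isotype = f[5],
      anticodon = f[6], category = category, high_confidence = hc,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  GenomicRanges::sort(
    make_trna_granges(df$seqid, df$start, df$end, df$strand, df$gene_id,
                      df$isotype, df$anticodon, df$category,
                      df$high_confidence),
    ignore.strand = TRUE)
}

#' Write annotations as BED6
#'
#' Standard BED 0-based half-open convention; one line per annotation with
#' the gene id as the name field and score 0.
#'
#' @param annotations a `GRanges` with a `gene_id` metadata column (or
#'   unnamed, in which case running ids are used).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(annotations, path) {
  if (length(annotations) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if ("gene_id" %in% colnames(S4Vectors::mcols(annotations))) {
    annotations$gene_id
  } else {
    paste0("feature_", seq_along(annotations))
  }
  strand <- as.character(GenomicRanges::strand(annotations))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   as.character(GenomicRanges::seqnames(annotations)),
                   GenomicRanges::start(annotations) - 1L,
                   GenomicRanges::end(annotations),
                   nm, 0L, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file into the standardized annotation form
#'
#' @param path path to a BED file.
#' @return `GRanges` with a `gene_id` column (BED name field).
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    return(make_trna_granges(character(0), integer(0), integer(0),
                             character(0), character(0), character(0),
                             character(0), character(0), logical(0)))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  make_trna_granges(
    seqid = f[, 1], start = as.integer(f[, 2]) + 1L,
    end = as.integer(f[, 3]), strand = ifelse(f[, 6] == ".", "*", f[, 6]),
    gene_id = f[, 4], isotype = NA_character_, anticodon = NA_character_,
    category = "gene", high_confidence = NA
  )
}

#' Write tRNA annotations as GFF3
#'
#' @param annotations standardized annotation `GRanges`.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
writeTrnaGff3 <- function(annotations, path, source = "cystra") {
  header <- "##gff-version 3"
  if (length(annotations) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  type <- ifelse(annotations$category == "pseudogene", "pseudogene", "tRNA")
  attrs <- sprintf(
    "ID=%s;isotype=%s;anticodon=%s;high_confidence=%s",
    annotations$gene_id, annotations$isotype, annotations$anticodon,
    ifelse(annotations$high_confidence, "true", "false")
  )
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(GenomicRanges::seqnames(annotations)),
                   source, type,
                   GenomicRanges::start(annotations),
                   GenomicRanges::end(annotations),
                   as.character(GenomicRanges::strand(annotations)),
                   attrs)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Extract gene sequences in transcription orientation
#'
#' Minus-strand genes are reverse-complemented so every returned sequence
#' reads 5' to 3' of the tRNA. Genes whose sequence contains `N` are
#' dropped with a message (ambiguous sequences are excluded from identity
#' statistics).
#'
#' @param genome a `DNAStringSet` (or single `DNAString`) holding the
#'   chromosome sequences.
#' @param annotations standardized annotation `GRanges`.
#' @param dropAmbiguous drop sequences containing `N` (default `TRUE`).
#' @return named `DNAStringSet` (names = gene ids).
#' @export
geneSequences <- function(genome, annotations, dropAmbiguous = TRUE) {
  if (methods::is(genome, "DNAString")) {
    genome <- Biostrings::DNAStringSet(list(genome))
    names(genome) <- as.character(GenomicRanges::seqnames(annotations))[1]
  }
  seqid <- as.character(GenomicRanges::seqnames(annotations))
  if (!all(seqid %in% names(genome))) {
    stop("annotation seqid absent from genome: ",
         setdiff(seqid, names(genome))[1], call. = FALSE)
  }
  ends <- GenomicRanges::end(annotations)
  lens <- Biostrings::width(genome)[match(seqid, names(genome))]
  if (any(ends > lens) || any(GenomicRanges::start(annotations) < 1)) {
    stop("annotation outside sequence bounds", call. = FALSE)
  }
  out <- character(length(annotations))
  for (i in seq_along(annotations)) {
    s <- Biostrings::subseq(genome[[seqid[i]]],
                            GenomicRanges::start(annotations)[i],
                            GenomicRanges::end(annotations)[i])
    if (as.character(GenomicRanges::strand(annotations))[i] == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    out[i] <- as.character(s)
  }
  names(out) <- annotations$gene_id
  if (dropAmbiguous) {
    amb <- grepl("N", out, fixed = TRUE)
    if (any(amb)) {
      message("dropping ", sum(amb), " gene(s) with ambiguous bases: ",
              paste(names(out)[amb], collapse = ", "))
      out <- out[!amb]
    }
  }
  Biostrings::DNAStringSet(out)
}

#' Construct a standardized tRNA annotation GRanges
#'
#' Convenience constructor producing the annotation form all cluster
#' functions consume (vectors are recycled).
#'
#' @param seqid,start,end,strand locus coordinates (1-based inclusive).
#' @param gene_id unique gene identifiers.
#' @param isotype,anticodon tRNA isotype (e.g. "Cys") and anticodon
#'   (e.g. "GCA").
#' @param category `"gene"` or `"pseudogene"`.
#' @param high_confidence logical confidence flag.
#' @return `GRanges` with the standard metadata columns.
#' @examples
#' trnaAnnotation("chr5", c(1, 421), c(72, 492), "+", c("g1", "g2"))
#' @export
trnaAnnotation <- function(seqid, start, end, strand = "+", gene_id,
                           isotype = "Cys", anticodon = "GCA",
                           category = "gene", high_confidence = TRUE) {
  n <- max(length(seqid), length(start), length(end), length(gene_id))
  stopifnot(all(end >= start))
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1], call. = FALSE)
  }
  make_trna_granges(rep_len(seqid, n), rep_len(start, n), rep_len(end, n),
                    rep_len(strand, n), rep_len(gene_id, n),
                    rep_len(isotype, n), rep_len(anticodon, n),
                    rep_len(category, n), rep_len(high_confidence, n))
}
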