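# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

DNA_BASES <- c("A", "C", "G", "T")

# random DNA with A. thaliana-like GC content
random_dna <- function(n, gc = 0.36) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# per-position substitution at `rate`, never touching `protect` positions
mutate_dna <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(x, what = "sequence") {
  if (any(nchar(x) == 0)) stop(what, " must be non-empty", call. = FALSE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(x)
}

as_dna_character <- function(x) {
  if (methods::is(x, "XStringSet") || methods::is(x, "XString")) {
    x <- as.character(x)
  }
  toupper(x)
}
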