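# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Seed-scoped evaluation: runs `expr` under `seed` without disturbing the
# caller's RNG stream. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# GC fraction of a DNA string vector (ambiguous bases ignored in numerator,
# counted in the denominator).
gc_content <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0L, gc / n, NA_real_)
}

# Validate an A/C/G/T-only sequence vector.
assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf(
      "%s contains non-ACGT characters (first offender: '%s')",
      what, x[which(bad)[1L]]
    ), call. = FALSE)
  }
  invisible(x)
}

# Coerce a reference argument to a named character vector of sequences.
# Accepts a named character vector, a Biostrings::DNAStringSet, or a FASTA
# file path.
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      nchar(reference) < 1000L && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    # FASTA headers: keep only the sequence id, drop the description
    ids <- sub("\\s.*$", "", names(reference))
    reference <- setNames(as.character(reference), ids)
  }
  if (!is.character(reference)) {
    stop("`reference` must be a named character vector, DNAStringSet, or FASTA path",
         call. = FALSE)
  }
  if (is.null(names(reference)) && length(reference) == 1L) {
    names(reference) <- "chr"
  }
  toupper(reference)
}

# Split a wide count table into its barcode ids and numeric matrix.
count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "barcode_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "barcode_id")])
  rownames(m) <- counts$barcode_id
  storage.mode(m) <- "double"
  m
}
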