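#' Read a variant manifest
#'
#' Reads a tab-separated variant manifest with columns `variant_id`,
#' `chrom`, `pos` (1-based), `ref_allele`, `alt_allele`, and optionally
#' `cohort`, validating the required columns and allele alphabet
#' (`"-"` marks the empty allele of a pure insertion/deletion).
#'
#' @param path TSV file path.
#' @returns Tibble of variants, ready for [build_library()].
#' @export
read_variants <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  required <- c("variant_id", "chrom", "pos", "ref_allele", "alt_allele")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("variant manifest lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1L)) {
    stop("variant positions must be 1-based positive integers", call. = FALSE)
  }
  for (col in c("ref_allele", "alt_allele")) {
    df[[col]] <- toupper(df[[col]])
    bad <- !grepl("^([ACGT]+|-)$", df[[col]])
    if (any(bad)) {
      stop(sprintf("%s of %s is not ACGT or '-'", col,
                   df$variant_id[which(bad)[1L]]), call. = FALSE)
    }
  }
  df
}

#' Read a barcode count table with its sample sheet
#'
#' Reads a counts TSV (first column `barcode_id`, one integer column per
#' sample) and a sample sheet TSV (`sample_id`, `fraction`, `replicate`),
#' checking that they agree on the sample set.
#'
#' @param counts_path,samples_path TSV file paths.
#' @returns List with `counts` and `samples` tibbles, as produced by
#'   [simulate_counts()] and consumed by the quantification functions.
#' @export
read_count_table <- function(counts_path, samples_path) {
  counts <- tibble::as_tibble(
    utils::read.delim(counts_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
  )
  if (names(counts)[1L] != "barcode_id") {
    stop("counts table must start with a 'barcode_id' column", call. = FALSE)
  }
  samples <- tibble::as_tibble(
    utils::read.delim(samples_path, stringsAsFactors = FALSE)
  )
  required <- c("sample_id", "fraction", "replicate")
  if (!all(required %in% names(samples))) {
    stop("sample sheet needs sample_id, fraction, replicate", call. = FALSE)
  }
  off <- setdiff(samples$sample_id, names(counts)[-1L])
  if (length(off)) {
    stop(sprintf("sample sheet entries missing from counts: %s",
                 paste(off, collapse = ", ")), call. = FALSE)
  }
  list(counts = counts, samples = samples)
}

#' Write a count table and sample sheet to TSV
#'
#' @param sim A list with `counts` and `samples` (e.g. an `mpra_sim`).
#' @param counts_path,samples_path Output TSV paths.
#' @returns Invisibly, the paths written.
#' @export
write_count_table <- function(sim, counts_path, samples_path) {
  utils::write.table(sim$counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, samples = samples_path))
}
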