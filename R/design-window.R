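#' Extract the variant-centered sequence window for both alleles
#'
#' Builds the reference- and alternative-allele element sequences for one
#' variant by slicing a window (default 120 nt) out of the reference,
#' centered on the variant. For single-nucleotide variants the variant base
#' sits at 0-based offset `window/2`, i.e. with a 60-nt left flank and a
#' 59-nt right flank at the default window. For indels the shared flanks are
#' sized so that the longer allele's context still fits within `window`
#' nucleotides; the shorter allele's context is then shorter than `window`
#' (padding to a constant oligo length happens at assembly time, see
#' [assemble_oligo()]). Windows are clipped, without erroring, where the
#' variant lies near a sequence end.
#'
#' A pure insertion or deletion is represented with `"-"` as the empty
#' allele, in which case `pos` is the base immediately left of the event.
#'
#' @param reference Named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param variant One-row data frame (or list) with `variant_id`, `chrom`,
#'   `pos` (1-based), `ref_allele`, `alt_allele`.
#' @param window Even window size in nucleotides (default 120).
#' @returns A list with `ref_context`, `alt_context`, and `variant_offset`
#'   (0-based offset of the allele within `ref_context`).
#' @export
extract_window <- function(reference, variant, window = 120L) {
  stopifnot(window >= 2L, window %% 2L == 0L)
  reference <- as_reference(reference)
  v <- as.list(variant)
  chrom <- as.character(v$chrom)
  if (!chrom %in% names(reference)) {
    stop(sprintf("chromosome '%s' not found in reference", chrom), call. = FALSE)
  }
  chrom_seq <- reference[[chrom]]
  pos <- as.integer(v$pos)
  ref_allele <- toupper(as.character(v$ref_allele))
  alt_allele <- toupper(as.character(v$alt_allele))
  if (pos < 1L || pos > nchar(chrom_seq)) {
    stop(sprintf("variant %s: pos %d outside reference", v$variant_id, pos),
         call. = FALSE)
  }

  ref_len <- if (identical(ref_allele, "-")) 0L else nchar(ref_allele)
  alt_len <- if (identical(alt_allele, "-")) 0L else nchar(alt_allele)
  if (ref_len > 0L) {
    observed <- substr(chrom_seq, pos, pos + ref_len - 1L)
    if (!identical(observed, ref_allele)) {
      stop(sprintf(
        "variant %s: ref allele '%s' does not match reference '%s' at %s:%d",
        v$variant_id, ref_allele, observed, chrom, pos
      ), call. = FALSE)
    }
  }

  # Flank budget: the longer allele plus both flanks must fit in `window`.
  long_len <- max(ref_len, alt_len, 1L)
  flank_total <- max(window - long_len, 0L)
  left_want <- as.integer(ceiling(flank_total / 2))
  right_want <- flank_total - left_want

  # The reference-genome footprint of the event. For a pure insertion the
  # footprint is the single anchor base at `pos`.
  foot_start <- pos
  foot_end <- if (ref_len > 0L) pos + ref_len - 1L else pos
  left_avail <- foot_start - 1L
  right_avail <- nchar(chrom_seq) - foot_end
  left <- min(left_want, left_avail)
  right <- min(right_want, right_avail)

  left_flank <- substr(chrom_seq, foot_start - left, foot_start - 1L)
  right_flank <- substr(chrom_seq, foot_end + 1L, foot_end + right)

  if (ref_len == 0L) {
    # pure insertion: anchor base belongs to both contexts
    anchor <- substr(chrom_seq, pos, pos)
    ref_context <- paste0(left_flank, anchor, right_flank)
    alt_context <- paste0(left_flank, anchor, alt_allele, right_flank)
  } else {
    ref_context <- paste0(left_flank, ref_allele, right_flank)
    alt_inner <- if (alt_len == 0L) "" else alt_allele
    alt_context <- paste0(left_flank, alt_inner, right_flank)
  }

  list(
    ref_context = ref_context,
    alt_context = alt_context,
    variant_offset = left
  )
}

#' Composition-preserving shuffle of an element sequence
#'
#' Returns a uniformly random permutation of the letters of `sequence`, so
#' that the shuffled control retains the exact nucleotide composition (and
#' hence GC content and length) of its source element. Deterministic for a
#' given `seed`.
#'
#' @param sequence DNA string to shuffle.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @returns Shuffled DNA string.
#' @export
shuffle_sequence <- function(sequence, seed = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  with_seed(seed, paste(sample(letters), collapse = ""))
}
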