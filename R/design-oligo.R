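#' Oligo layout configuration
#'
#' Fixed flanking segments that turn a (up to) 120-nt element plus 9-nt
#' barcode into a constant-length synthesis oligo:
#' `primer5 | cutsite5 | element | linker | barcode | cutsite3 | primer3`.
#' With the defaults (24-nt 5' primer, NheI site `GCTAGC`, 120-nt element
#' slot, 20-nt linker, 9-nt barcode, KpnI site `GGTACC`, 25-nt 3' primer)
#' the total is 210 nt. Elements shorter than `utr_length` (truncated indel
#' contexts) are padded with a neutral `AT`-repeat spacer placed between the
#' 5' primer and the NheI site, i.e. outside the cloned insert, so every
#' oligo still reaches the constant total length.
#'
#' The primer sequences are synthetic placeholders of the conventional
#' lengths and can be overridden.
#'
#' @param primer5,primer3 Amplification primer landing sites.
#' @param cutsite5,cutsite3 Restriction sites flanking the insert.
#' @param linker Constant linker between element and barcode.
#' @param utr_length Element slot size in nt (default 120).
#' @param barcode_length Barcode size in nt (default 9).
#' @returns A list of class `oligo_layout`.
#' @export
oligo_layout <- function(primer5 = "ACTGGCCGCTTGACGTCATAGGCT",
                         primer3 = "AGATCGGAAGAGCGTCGTGTAGGGA",
                         cutsite5 = "GCTAGC",
                         cutsite3 = "GGTACC",
                         linker = "CTTCGGTAACGGACTTCAGG",
                         utr_length = 120L,
                         barcode_length = 9L) {
  layout <- list(
    primer5 = toupper(primer5), primer3 = toupper(primer3),
    cutsite5 = toupper(cutsite5), cutsite3 = toupper(cutsite3),
    linker = toupper(linker),
    utr_length = as.integer(utr_length),
    barcode_length = as.integer(barcode_length)
  )
  layout$total_length <- nchar(layout$primer5) + nchar(layout$cutsite5) +
    layout$utr_length + nchar(layout$linker) + layout$barcode_length +
    nchar(layout$cutsite3) + nchar(layout$primer3)
  structure(layout, class = "oligo_layout")
}

# Padding spacer of `n` nt built from AT repeats.
at_spacer <- function(n) {
  if (n <= 0L) return("")
  substr(strrep("AT", ceiling(n / 2)), 1L, n)
}

#' Assemble barcoded oligos
#'
#' Concatenates each element sequence with its barcode and the constant
#' flanks of an [oligo_layout()] into a full synthesis oligo, and records
#' the 0-based half-open coordinates of every segment so that element and
#' barcode can be sliced back out of the full sequence exactly.
#'
#' @param elements Data frame with `element_id` and `sequence` (each at most
#'   `layout$utr_length` nt).
#' @param barcodes Data frame with `element_id`, `barcode_id`, `sequence`
#'   (one row per oligo: the barcode assigned to that element copy).
#' @param layout An [oligo_layout()].
#' @returns Tibble with `oligo_id`, `element_id`, `barcode_id`,
#'   `full_sequence`, and a `layout` list-column of per-segment
#'   `(segment, start, end)` tibbles.
#' @export
assemble_oligo <- function(elements, barcodes, layout = oligo_layout()) {
  stopifnot(inherits(layout, "oligo_layout"))
  df <- dplyr::inner_join(
    dplyr::select(barcodes, "element_id", "barcode_id", barcode_seq = "sequence"),
    dplyr::select(elements, "element_id", element_seq = "sequence"),
    by = "element_id"
  )
  if (nrow(df) == 0L) stop("no element/barcode pairs to assemble", call. = FALSE)
  elen <- nchar(df$element_seq)
  if (any(elen > layout$utr_length)) {
    bad <- df$element_id[which(elen > layout$utr_length)[1L]]
    stop(sprintf("element %s longer than the %d-nt slot", bad, layout$utr_length),
         call. = FALSE)
  }
  if (any(nchar(df$barcode_seq) != layout$barcode_length)) {
    stop(sprintf("all barcodes must be %d nt", layout$barcode_length), call. = FALSE)
  }

  pad <- vapply(layout$utr_length - elen, at_spacer, character(1))
  full <- paste0(layout$primer5, pad, layout$cutsite5, df$element_seq,
                 layout$linker, df$barcode_seq, layout$cutsite3, layout$primer3)

  seg_layout <- function(pad_len, element_len) {
    segs <- c(primer5 = nchar(layout$primer5), pad5 = pad_len,
              cutsite5 = nchar(layout$cutsite5), utr_context = element_len,
              linker = nchar(layout$linker), barcode = layout$barcode_length,
              cutsite3 = nchar(layout$cutsite3), primer3 = nchar(layout$primer3))
    segs <- segs[segs > 0L | names(segs) != "pad5"]
    ends <- cumsum(segs)
    tibble::tibble(segment = names(segs),
                   start = as.integer(unname(ends - segs)),
                   end = as.integer(unname(ends)))
  }

  tibble::tibble(
    oligo_id = paste0(df$element_id, "_", df$barcode_id),
    element_id = df$element_id,
    barcode_id = df$barcode_id,
    full_sequence = full,
    layout = purrr::map2(layout$utr_length - elen, elen, seg_layout)
  )
}

#' Slice an oligo segment back out by its recorded layout
#'
#' @param oligos Output of [assemble_oligo()].
#' @param segment Segment name, e.g. `"barcode"` or `"utr_context"`.
#' @returns Character vector of segment sequences (empty string where the
#'   segment is absent).
#' @export
oligo_segment <- function(oligos, segment) {
  purrr::map2_chr(oligos$full_sequence, oligos$layout, function(seq, lay) {
    row <- lay[lay$segment == segment, ]
    if (nrow(row) == 0L) return("")
    substr(seq, row$start + 1L, row$end)
  })
}
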