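#' Build a shuffled control element from a reference element
#'
#' Produces the composition-matched (hence GC-matched) control for one
#' reference element: a uniformly random permutation of its letters, linked
#' back to the source via `paired_element_id`.
#'
#' @param element One-row data frame with at least `element_id`,
#'   `element_class` (must be `"ref"`), and `sequence`.
#' @param seed Integer seed.
#' @returns One-row element tibble of class `shuf`.
#' @export
shuffle_control <- function(element, seed = NULL) {
  el <- as.list(element)
  if (!identical(as.character(el$element_class), "ref")) {
    stop("shuffled controls are derived from 'ref' elements", call. = FALSE)
  }
  shuffled <- shuffle_sequence(as.character(el$sequence), seed = seed)
  tibble::tibble(
    element_id = paste0(el$element_id, "_shuf"),
    element_class = "shuf",
    variant_id = NA_character_,
    paired_element_id = as.character(el$element_id),
    sequence = shuffled,
    gc_content = gc_content(shuffled)
  )
}

#' Build the full barcoded oligo library design
#'
#' From a variant manifest and a reference sequence, constructs the complete
#' design: a ref/alt element pair per variant (variant-centered windows),
#' composition-preserving shuffled controls for a seeded random subset of
#' the reference elements, user-supplied control elements, a
#' Hamming-separated barcode whitelist, and the assembled synthesis oligos
#' (`barcodes_per_element` barcoded copies of every element).
#'
#' @param variants Data frame with `variant_id`, `chrom`, `pos` (1-based),
#'   `ref_allele`, `alt_allele`, and optionally `cohort`.
#' @param reference Named character vector / `DNAStringSet` / FASTA path.
#' @param n_shuffle Number of reference elements to shuffle into controls.
#' @param controls Optional data frame of extra control elements with
#'   `element_id` and `sequence`.
#' @param barcodes_per_element Barcoded copies per element (default 6).
#' @param window Element window size (default 120).
#' @param layout An [oligo_layout()].
#' @param seed Integer seed governing shuffle-target choice, shuffles, and
#'   barcode generation.
#' @returns An object of class `mpra_design`: a list with tibbles
#'   `variants`, `elements`, `barcodes`, `oligos`, and the `layout`.
#' @export
build_library <- function(variants, reference, n_shuffle = 0L,
                          controls = NULL, barcodes_per_element = 6L,
                          window = 120L, layout = oligo_layout(),
                          seed = NULL) {
  variants <- tibble::as_tibble(variants)
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant_ids in the variant manifest", call. = FALSE)
  }
  n_ref <- nrow(variants)
  if (n_shuffle > n_ref) {
    stop("n_shuffle exceeds the number of reference elements", call. = FALSE)
  }

  windows <- purrr::pmap(variants, function(...) {
    extract_window(reference, list(...), window = window)
  })

  ref_elements <- tibble::tibble(
    element_id = paste0(variants$variant_id, "_ref"),
    element_class = "ref",
    variant_id = variants$variant_id,
    paired_element_id = paste0(variants$variant_id, "_alt"),
    sequence = purrr::map_chr(windows, "ref_context")
  )
  alt_elements <- tibble::tibble(
    element_id = paste0(variants$variant_id, "_alt"),
    element_class = "alt",
    variant_id = variants$variant_id,
    paired_element_id = paste0(variants$variant_id, "_ref"),
    sequence = purrr::map_chr(windows, "alt_context")
  )

  with_seed(seed, {
    shuf_elements <- NULL
    if (n_shuffle > 0L) {
      targets <- sort(sample.int(n_ref, n_shuffle))
      shuf_elements <- purrr::map_dfr(targets, function(i) {
        shuffle_control(ref_elements[i, ], seed = NULL)
      })
    }

    control_elements <- NULL
    if (!is.null(controls) && nrow(controls) > 0L) {
      control_elements <- tibble::tibble(
        element_id = as.character(controls$element_id),
        element_class = "control",
        variant_id = NA_character_,
        paired_element_id = NA_character_,
        sequence = toupper(as.character(controls$sequence))
      )
    }

    elements <- dplyr::bind_rows(
      ref_elements, alt_elements, shuf_elements, control_elements
    )
    elements$gc_content <- gc_content(elements$sequence)
    if (anyDuplicated(elements$element_id)) {
      stop("duplicate element_ids in the assembled design", call. = FALSE)
    }

    whitelist <- generate_barcodes(
      n = nrow(elements) * barcodes_per_element,
      length = layout$barcode_length, seed = NULL
    )
    assignment <- whitelist
    assignment$element_id <- rep(elements$element_id, each = barcodes_per_element)

    oligos <- assemble_oligo(elements, assignment, layout = layout)

    structure(
      list(
        variants = variants,
        elements = elements,
        barcodes = dplyr::select(
          assignment, "barcode_id", "element_id", "sequence"
        ),
        oligos = oligos,
        barcodes_per_element = as.integer(barcodes_per_element),
        layout = layout
      ),
      class = "mpra_design"
    )
  })
}

#' @export
print.mpra_design <- function(x, ...) {
  cls <- table(x$elements$element_class)
  cat(sprintf(
    "<mpra_design> %d variants; %d elements (%s); %d oligos (%d barcodes/element, %d nt)\n",
    nrow(x$variants), nrow(x$elements),
    paste(sprintf("%s: %d", names(cls), cls), collapse = ", "),
    nrow(x$oligos), x$barcodes_per_element, x$layout$total_length
  ))
  invisible(x)
}

#' Expected design coverage from a colony count
#'
#' Poisson-approximate expected fraction of design members captured when
#' `colonies` clones are picked from a `design_size`-member library of which
#' a fraction `error_rate` is synthesis-corrupted:
#' `1 - (1 - 1/design_size)^(colonies * (1 - error_rate))`.
#'
#' @param design_size Number of distinct oligos in the design.
#' @param colonies Number of colonies recovered.
#' @param error_rate Fraction of colonies carrying corrupted inserts.
#' @returns Expected covered fraction in `[0, 1]`.
#' @export
#' @examples
#' colony_coverage(9744, 71000, error_rate = 0.5)
colony_coverage <- function(design_size, colonies, error_rate = 0) {
  stopifnot(design_size >= 1, colonies >= 0)
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  1 - (1 - 1 / design_size)^(colonies * (1 - error_rate))
}

#' Write the design to plain-text files
#'
#' Writes the element manifest (TSV), the oligo FASTA, and the barcode
#' whitelist (TSV) into a directory.
#'
#' @param design An `mpra_design`.
#' @param dir Output directory (created if missing).
#' @returns Invisibly, the paths written.
#' @export
write_design <- function(design, dir) {
  stopifnot(inherits(design, "mpra_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- dplyr::left_join(
    dplyr::select(design$barcodes, "barcode_id", "element_id",
                  barcode_sequence = "sequence"),
    design$elements,
    by = "element_id"
  )
  paths <- c(
    manifest = file.path(dir, "design_manifest.tsv"),
    oligos = file.path(dir, "oligos.fa"),
    whitelist = file.path(dir, "barcode_whitelist.tsv")
  )
  utils::write.table(manifest, paths[["manifest"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  oligo_set <- Biostrings::DNAStringSet(
    setNames(design$oligos$full_sequence, design$oligos$oligo_id)
  )
  Biostrings::writeXStringSet(oligo_set, paths[["oligos"]])
  utils::write.table(
    dplyr::select(design$barcodes, "barcode_id", "sequence", "element_id"),
    paths[["whitelist"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
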