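# Programmatic fixtures shared across the suite.

# Random reference genome as a named character vector.
make_reference <- function(n_chrom = 1L, len = 5000L, seed = 101L) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0("chr", seq_len(n_chrom)))
  })
}

# SNV manifest drawn from a reference, positions clear of the edges.
make_variants <- function(reference, n, seed = 202L) {
  chrom <- names(reference)[1L]
  len <- nchar(reference[[1L]])
  withr::with_seed(seed, {
    pos <- sort(sample(seq(150L, len - 150L), n))
    ref <- substring(reference[[1L]], pos, pos)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1), USE.NAMES = FALSE)
    tibble::tibble(
      variant_id = sprintf("var%03d", seq_len(n)),
      chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
      cohort = rep_len(c("proband", "sibling"), n)
    )
  })
}

# Small end-to-end design.
make_design <- function(n_variants = 4L, n_shuffle = 2L,
                        barcodes_per_element = 3L, seed = 303L) {
  ref <- make_reference(len = 4000L, seed = seed)
  build_library(
    make_variants(ref, n_variants, seed = seed + 1L), ref,
    n_shuffle = n_shuffle, barcodes_per_element = barcodes_per_element,
    seed = seed + 2L
  )
}

# Barcode-to-element map without sequences, for count simulations that do
# not need a synthesized design.
make_bc_map <- function(n_variants = 0L, n_controls = 0L,
                        barcodes_per_element = 6L) {
  el <- tibble::tibble(element_id = character(), element_class = character(),
                       variant_id = character())
  if (n_variants > 0L) {
    vid <- sprintf("v%03d", seq_len(n_variants))
    el <- dplyr::bind_rows(
      tibble::tibble(element_id = paste0(vid, "_ref"), element_class = "ref",
                     variant_id = vid),
      tibble::tibble(element_id = paste0(vid, "_alt"), element_class = "alt",
                     variant_id = vid)
    )
  }
  if (n_controls > 0L) {
    el <- dplyr::bind_rows(el, tibble::tibble(
      element_id = sprintf("ctrl%03d", seq_len(n_controls)),
      element_class = "control", variant_id = NA_character_
    ))
  }
  tidyr::expand_grid(element_id = el$element_id,
                     copy = seq_len(barcodes_per_element)) |>
    dplyr::left_join(el, by = "element_id") |>
    dplyr::mutate(barcode_id = sprintf("%s_bc%d", element_id, copy)) |>
    dplyr::select("barcode_id", "element_id", "element_class", "variant_id")
}

# Balanced two-sided Gaussian measurements for LRT tests.
make_pair_measurements <- function(k = 6L, n_rep = 6L, beta = 0,
                                   sigma_b = 0, sigma_e = 0.1, seed = NULL) {
  gen <- function() {
    purrr::map_dfr(c("a", "b"), function(s) {
      b <- stats::rnorm(k, 0, sigma_b)
      tidyr::expand_grid(bc = seq_len(k), replicate = seq_len(n_rep)) |>
        dplyr::mutate(
          barcode_id = sprintf("%s_bc%d", s, bc),
          side = s,
          value = (s == "b") * beta + b[bc] + stats::rnorm(k * n_rep, 0, sigma_e)
        ) |>
        dplyr::select("barcode_id", "side", "replicate", "value")
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
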