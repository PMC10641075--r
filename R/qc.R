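#' Replicate-to-replicate Pearson correlations
#'
#' Pairwise Pearson correlation between sample columns of a value table
#' (raw counts, CPM, or a wide activity table), restricted to the barcodes
#' finite in both members of each pair. Pairs with fewer than two
#' overlapping observations get `NA` with `n_overlap` recorded.
#'
#' @param values Wide tibble: `barcode_id` plus one numeric column per
#'   sample.
#' @param samples Optional sample sheet; when given, only pairs within the
#'   same `fraction` are reported.
#' @returns Long tibble: `sample_a`, `sample_b`, (`fraction`,) `pcc`,
#'   `n_overlap`, for all unordered pairs.
#' @export
replicate_correlation <- function(values, samples = NULL) {
  m <- count_matrix(values)
  ids <- colnames(m)
  pairs <- utils::combn(ids, 2L)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    ok <- is.finite(m[, a]) & is.finite(m[, b])
    tibble::tibble(
      sample_a = a, sample_b = b,
      pcc = if (sum(ok) >= 2L) cor(m[ok, a], m[ok, b]) else NA_real_,
      n_overlap = sum(ok)
    )
  })
  if (!is.null(samples)) {
    fr <- setNames(samples$fraction, samples$sample_id)
    out$fraction_a <- as.character(fr[out$sample_a])
    out$fraction_b <- as.character(fr[out$sample_b])
    out <- out[!is.na(out$fraction_a) & out$fraction_a == out$fraction_b, ]
    out$fraction <- out$fraction_a
    out <- dplyr::select(out, "sample_a", "sample_b", "fraction", "pcc",
                         "n_overlap")
  }
  out
}

#' Barcode dropout report
#'
#' Flags design barcodes with zero counts across the DNA libraries,
#' tallies surviving barcodes per element, and reports the fraction of
#' elements retaining at least `min_barcodes` barcodes.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet (used to locate the DNA columns; if no
#'   DNA fraction is present, all columns are used).
#' @param design An `mpra_design` or barcode-to-element map.
#' @param min_barcodes Survival threshold per element (default 3).
#' @returns List: `dropout_fraction` (fraction of design barcodes with
#'   zero DNA counts), `per_element` (tibble `element_id`,
#'   `n_barcodes_detected`), `frac_elements_covered` (elements with >=
#'   `min_barcodes` surviving barcodes).
#' @export
dropout_report <- function(counts, samples, design, min_barcodes = 3L) {
  map <- if (inherits(design, "mpra_design")) design$barcodes else design
  m <- count_matrix(counts)
  dna_cols <- samples$sample_id[samples$fraction == "DNA"]
  if (length(dna_cols) == 0L) dna_cols <- colnames(m)
  dna <- rowSums(m[, dna_cols, drop = FALSE])
  detected <- rownames(m)[dna > 0]

  per_element <- map |>
    dplyr::group_by(.data$element_id) |>
    dplyr::summarise(
      n_barcodes_detected = sum(.data$barcode_id %in% detected),
      .groups = "drop"
    )
  list(
    dropout_fraction = mean(!map$barcode_id %in% detected),
    per_element = per_element,
    frac_elements_covered = mean(per_element$n_barcodes_detected >= min_barcodes)
  )
}

#' Jackpotting index of a count column
#'
#' Share of a sample's total counts held by its top decile of barcodes
#' (`method = "top_share"`), or the Gini coefficient of the counts. Both
#' are scale-invariant; a uniform library scores 0.1 (top-share) or 0
#' (Gini), and a library dominated by a few barcodes approaches 1.
#'
#' @param x Non-empty numeric vector of counts for one sample.
#' @param top Top fraction of barcodes for the share metric (default 0.1).
#' @param method `"top_share"` or `"gini"`.
#' @returns Fraction in `[0, 1]`.
#' @export
jackpot_index <- function(x, top = 0.1, method = c("top_share", "gini")) {
  method <- match.arg(method)
  stopifnot(length(x) > 0L, all(x >= 0))
  if (sum(x) == 0) return(0)
  if (method == "top_share") {
    n_top <- max(1L, ceiling(top * length(x)))
    sum(sort(x, decreasing = TRUE)[seq_len(n_top)]) / sum(x)
  } else {
    x <- sort(x)
    n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
}

#' DNA recovery by element GC content
#'
#' Bins elements by GC fraction and reports the mean DNA CPM (averaged
#' over each element's barcodes, then over the elements in the bin),
#' exposing GC-dependent cloning/synthesis dropout.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet (DNA columns are used).
#' @param design An `mpra_design`, or a data frame with `barcode_id`,
#'   `element_id`, `gc_content`.
#' @param bins Bin edges covering `[0, 1]` (default width 0.1).
#' @returns Tibble: `gc_lo`, `gc_hi`, `n_elements`, `mean_dna_cpm` (`NA`
#'   for empty bins).
#' @export
gc_recovery <- function(counts, samples, design, bins = seq(0, 1, by = 0.1)) {
  if (inherits(design, "mpra_design")) {
    map <- dplyr::left_join(
      dplyr::select(design$barcodes, "barcode_id", "element_id"),
      dplyr::select(design$elements, "element_id", "gc_content"),
      by = "element_id"
    )
  } else {
    map <- tibble::as_tibble(design)
  }
  stopifnot(all(c("barcode_id", "element_id", "gc_content") %in% names(map)))
  cpm <- count_matrix(cpm_normalize(counts))
  dna_cols <- samples$sample_id[samples$fraction == "DNA"]
  if (length(dna_cols) == 0L) dna_cols <- colnames(cpm)
  dna <- rowMeans(cpm[, dna_cols, drop = FALSE])

  per_element <- map |>
    dplyr::mutate(dna_cpm = dna[match(.data$barcode_id, rownames(cpm))]) |>
    dplyr::group_by(.data$element_id, .data$gc_content) |>
    dplyr::summarise(dna_cpm = mean(.data$dna_cpm, na.rm = TRUE),
                     .groups = "drop")

  idx <- cut(per_element$gc_content, breaks = bins, include.lowest = TRUE,
             right = FALSE, labels = FALSE)
  # right-open bins except the last, so every GC value lands exactly once
  idx[per_element$gc_content == bins[length(bins)]] <- length(bins) - 1L
  purrr::map_dfr(seq_len(length(bins) - 1L), function(i) {
    members <- which(idx == i)
    tibble::tibble(
      gc_lo = bins[i], gc_hi = bins[i + 1L],
      n_elements = length(members),
      mean_dna_cpm = if (length(members)) mean(per_element$dna_cpm[members])
                     else NA_real_
    )
  })
}

#' Compile a library QC report
#'
#' Bundles the QC diagnostics into one object: replicate correlations at
#' the raw-count and CPM level, dropout, per-sample jackpotting indices,
#' and GC-binned DNA recovery.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet.
#' @param design An `mpra_design`.
#' @returns List of class `mpra_qc`.
#' @export
qc_report <- function(counts, samples, design) {
  cpm <- cpm_normalize(counts)
  m <- count_matrix(counts)
  structure(
    list(
      replicate_correlation = replicate_correlation(cpm, samples),
      dropout = dropout_report(counts, samples, design),
      jackpot = tibble::tibble(
        sample_id = colnames(m),
        jackpot_index = apply(m, 2L, jackpot_index)
      ),
      gc_recovery = gc_recovery(counts, samples, design)
    ),
    class = "mpra_qc"
  )
}

#' @export
print.mpra_qc <- function(x, ...) {
  cat(sprintf(
    "<mpra_qc> mean within-fraction PCC %.3f; dropout %.1f%%; %.1f%% of elements with >= 3 barcodes; mean jackpot index %.2f\n",
    mean(x$replicate_correlation$pcc, na.rm = TRUE),
    100 * x$dropout$dropout_fraction,
    100 * x$dropout$frac_elements_covered,
    mean(x$jackpot$jackpot_index)
  ))
  invisible(x)
}
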