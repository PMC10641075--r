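#' Count whitelisted barcodes in reads by anchored matching
#'
#' Locates the constant linker (`anchor`) in each read by exact string
#' match and reads off the barcode immediately downstream; a read counts
#' toward a barcode only on an exact whitelist hit. Reads without the
#' anchor, truncated before the barcode ends, or carrying an off-whitelist
#' barcode are tallied as discarded. Exact matching is safe because the
#' whitelist is designed at pairwise Hamming distance >= 2.
#'
#' @param reads Character vector of read sequences, or a FASTA/FASTQ path.
#' @param whitelist Data frame with `barcode_id` and `sequence`, or a named
#'   character vector (names = barcode ids).
#' @param anchor Linker sequence preceding the barcode in the read.
#' @returns Tibble with `barcode_id` and `count` (whitelist order), with a
#'   `discarded` attribute tallying `no_anchor`, `truncated`, and
#'   `off_whitelist` reads.
#' @export
count_barcodes <- function(reads, whitelist, anchor) {
  stopifnot(nchar(anchor) > 0L)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  if (is.data.frame(whitelist)) {
    wl <- setNames(as.character(whitelist$sequence),
                   as.character(whitelist$barcode_id))
  } else {
    wl <- whitelist
  }
  if (length(wl) == 0L) stop("whitelist is empty", call. = FALSE)
  bc_len <- unique(nchar(wl))
  if (length(bc_len) != 1L) {
    stop("whitelist barcodes must share one length", call. = FALSE)
  }

  reads <- toupper(reads)
  hit <- regexpr(toupper(anchor), reads, fixed = TRUE)
  start <- ifelse(hit > 0L, hit + nchar(anchor), NA_integer_)
  observed <- substr(reads, start, start + bc_len - 1L)
  no_anchor <- is.na(start)
  truncated <- !no_anchor & nchar(observed) < bc_len
  idx <- match(observed, wl)
  off_whitelist <- !no_anchor & !truncated & is.na(idx)
  matched <- idx[!is.na(idx) & !truncated]

  counts <- tabulate(matched, nbins = length(wl))
  structure(
    tibble::tibble(barcode_id = names(wl), count = counts),
    discarded = c(
      no_anchor = sum(no_anchor),
      truncated = sum(truncated),
      off_whitelist = sum(off_whitelist)
    )
  )
}

#' Counts-per-million normalization
#'
#' Scales each sample column of a barcode count table to counts per
#' million, so column sums of the result equal `1e6`.
#'
#' @param counts Wide tibble: `barcode_id` plus one numeric column per
#'   sample.
#' @returns Tibble of the same shape with CPM values.
#' @export
cpm_normalize <- function(counts) {
  m <- count_matrix(counts)
  depth <- colSums(m)
  if (any(depth <= 0)) {
    stop(sprintf("zero-depth sample(s): %s",
                 paste(colnames(m)[depth <= 0], collapse = ", ")), call. = FALSE)
  }
  out <- sweep(m, 2L, depth, "/") * 1e6
  tibble::as_tibble(
    c(list(barcode_id = counts$barcode_id), as.data.frame(out))
  )
}

measure_fractions <- function(measure) {
  switch(measure,
    transcript_abundance = c(num = "Input", den = "DNA"),
    ribosome_occupancy = c(num = "TRAP", den = "DNA"),
    translation_efficiency = c(num = "TRAP", den = "Input"),
    stop(sprintf("unknown measure '%s'", measure), call. = FALSE)
  )
}

#' Per-barcode activity measurements
#'
#' Computes `log2(numerator CPM / denominator CPM)` per barcode per
#' replicate for the requested measure: `transcript_abundance` (Input/DNA),
#' `ribosome_occupancy` (TRAP/DNA), or `translation_efficiency`
#' (TRAP/Input). Cells where the raw count falls below `min_count` in
#' either member of the ratio are dropped, not imputed, so a zero count
#' never reaches the log. When the denominator is DNA, `dna_policy` chooses
#' between the mean DNA CPM across DNA libraries (`"mean"`, the default;
#' the corresponding floor is the mean raw DNA count) and per-replicate
#' pairing (`"paired"`, requiring a DNA library for every RNA replicate).
#'
#' @param counts Wide count tibble (`barcode_id` + sample columns).
#' @param samples Sample sheet: `sample_id`, `fraction` (`DNA`/`Input`/
#'   `TRAP`), `replicate`.
#' @param measure One of `"transcript_abundance"`, `"ribosome_occupancy"`,
#'   `"translation_efficiency"`.
#' @param min_count Raw-count floor applied to both members (default 10).
#' @param dna_policy `"mean"` or `"paired"` DNA denominator handling.
#' @param design Optional `mpra_design` (or barcode-to-element map) used to
#'   attach `element_id`.
#' @returns Long tibble: `barcode_id`, (`element_id`,) `replicate`,
#'   `measure`, `value`.
#' @export
barcode_activity <- function(counts, samples, measure = "transcript_abundance",
                             min_count = 10L, dna_policy = c("mean", "paired"),
                             design = NULL) {
  dna_policy <- match.arg(dna_policy)
  fr <- measure_fractions(measure)
  samples <- tibble::as_tibble(samples)
  raw <- count_matrix(counts)
  cpm <- count_matrix(cpm_normalize(counts))

  sample_of <- function(fraction, replicate) {
    id <- samples$sample_id[samples$fraction == fraction &
                              samples$replicate == replicate]
    if (length(id) != 1L) NA_character_ else id
  }
  num_samples <- samples[samples$fraction == fr[["num"]], ]
  if (nrow(num_samples) == 0L) {
    stop(sprintf("no '%s' samples for measure '%s'", fr[["num"]], measure),
         call. = FALSE)
  }

  dna_mean_cpm <- dna_mean_raw <- NULL
  if (fr[["den"]] == "DNA" && dna_policy == "mean") {
    dna_cols <- samples$sample_id[samples$fraction == "DNA"]
    if (length(dna_cols) == 0L) stop("no DNA samples present", call. = FALSE)
    dna_mean_cpm <- rowMeans(cpm[, dna_cols, drop = FALSE])
    dna_mean_raw <- rowMeans(raw[, dna_cols, drop = FALSE])
  }

  out <- purrr::map_dfr(seq_len(nrow(num_samples)), function(i) {
    num_id <- num_samples$sample_id[i]
    rep_i <- num_samples$replicate[i]
    if (!is.null(dna_mean_cpm)) {
      den_cpm <- dna_mean_cpm
      den_raw <- dna_mean_raw
    } else {
      den_id <- sample_of(fr[["den"]], rep_i)
      if (is.na(den_id)) {
        stop(sprintf("no %s sample paired with replicate %s", fr[["den"]], rep_i),
             call. = FALSE)
      }
      den_cpm <- cpm[, den_id]
      den_raw <- raw[, den_id]
    }
    pass <- raw[, num_id] >= min_count & den_raw >= min_count
    tibble::tibble(
      barcode_id = rownames(raw)[pass],
      replicate = rep_i,
      measure = measure,
      value = unname(log2(cpm[pass, num_id] / den_cpm[pass]))
    )
  })

  if (!is.null(design)) {
    map <- if (inherits(design, "mpra_design")) design$barcodes else design
    out <- dplyr::left_join(
      out, dplyr::select(map, "barcode_id", "element_id"), by = "barcode_id"
    )
    out <- dplyr::relocate(out, "element_id", .after = "barcode_id")
  }
  out
}

#' Summarize one element's activity with the random-intercept model
#'
#' Fits `Activity ~ (1 | barcode)` by ML to the barcode-level measurements
#' of a single element and reports the model intercept as the element
#' activity. With a single barcode, or when the barcode variance estimate
#' is clamped at zero, the fit degenerates gracefully to the sample mean.
#'
#' @param measurements Data frame with `value` and `barcode_id` (rows =
#'   barcode-replicate measurements of one element).
#' @returns An `mpra_lmm` fit; its intercept is the element activity.
#' @export
element_activity <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    stop("no measurements for this element", call. = FALSE)
  }
  fit_lmm(measurements$value, measurements$barcode_id)
}

#' Per-element activity quantification
#'
#' End-to-end barcode-to-element summarization: computes per-barcode
#' activities with [barcode_activity()], then fits the random-intercept
#' model per element and tabulates intercepts and variance components.
#' Elements of the design with no passing measurements are retained as
#' dropped rows (`n_obs = 0`, `dropped = TRUE`). Count-table barcodes
#' absent from the design are reported via the `unknown_barcodes`
#' attribute, not an error.
#'
#' @inheritParams barcode_activity
#' @param design An `mpra_design` or barcode-to-element map (required).
#' @returns Tibble: `element_id`, `element_class`, `estimate` (activity,
#'   log2), `sigma_b`, `sigma_e`, `loglik`, `n_barcodes`, `n_obs`,
#'   `converged`, `dropped`.
#' @export
quantify <- function(counts, samples, design,
                     measure = "transcript_abundance", min_count = 10L,
                     dna_policy = c("mean", "paired")) {
  map <- if (inherits(design, "mpra_design")) design$barcodes else design
  elements <- if (inherits(design, "mpra_design")) {
    dplyr::select(design$elements, "element_id", "element_class")
  } else {
    dplyr::distinct(tibble::as_tibble(design), .data$element_id) |>
      dplyr::mutate(element_class = NA_character_)
  }
  unknown <- setdiff(counts$barcode_id, map$barcode_id)

  act <- barcode_activity(counts, samples, measure = measure,
                          min_count = min_count, dna_policy = dna_policy,
                          design = design)
  act <- act[!is.na(act$element_id), ]

  fits <- act |>
    dplyr::group_by(.data$element_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_lmm(df$value, df$barcode_id)
      tibble::tibble(
        estimate = fit$beta[[1L]], sigma_b = fit$sigma_b,
        sigma_e = fit$sigma_e, loglik = fit$loglik,
        n_barcodes = fit$n_groups, n_obs = fit$n_obs,
        converged = fit$converged
      )
    }) |>
    dplyr::ungroup()

  out <- dplyr::left_join(elements, fits, by = "element_id") |>
    dplyr::mutate(
      n_obs = dplyr::coalesce(.data$n_obs, 0L),
      n_barcodes = dplyr::coalesce(.data$n_barcodes, 0L),
      converged = dplyr::coalesce(.data$converged, FALSE),
      dropped = .data$n_obs == 0L
    )
  attr(out, "unknown_barcodes") <- unknown
  out
}
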