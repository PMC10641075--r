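#' Likelihood-ratio test for a two-sided activity comparison
#'
#' Fits the full model `Activity ~ side + (1 | barcode)` and the reduced
#' model `Activity ~ (1 | barcode)` by ML and compares them with a
#' likelihood-ratio test against a chi-squared reference with one degree of
#' freedom (the tested fixed effect is interior, so no boundary correction
#' applies). The reported `log2FC` is the fixed-effect estimate for the
#' second factor level of `side` relative to the first.
#'
#' @param measurements Data frame with `value`, `barcode_id`, and `side`
#'   (two levels; every barcode belongs to one side).
#' @returns One-row tibble: `log2FC`, `p_value`, `loglik_full`,
#'   `loglik_reduced`, `n_barcodes_a`, `n_barcodes_b`, `n_obs`,
#'   `converged`. Non-convergence is reported as `converged = FALSE` with
#'   `p_value = 1`.
#' @export
lrt_pair_test <- function(measurements) {
  side <- factor(measurements$side)
  if (nlevels(side) != 2L) {
    stop("`side` must have exactly two levels", call. = FALSE)
  }
  y <- measurements$value
  X <- cbind("(Intercept)" = 1, side = as.numeric(side == levels(side)[2L]))
  full <- fit_lmm(y, measurements$barcode_id, X)
  reduced <- fit_lmm(y, measurements$barcode_id)
  ok <- full$converged && reduced$converged
  stat <- max(2 * (full$loglik - reduced$loglik), 0)
  tibble::tibble(
    log2FC = as.numeric(full$beta[["side"]]),
    p_value = if (ok) pchisq(stat, df = 1L, lower.tail = FALSE) else 1,
    loglik_full = full$loglik,
    loglik_reduced = reduced$loglik,
    n_barcodes_a = length(unique(measurements$barcode_id[side == levels(side)[1L]])),
    n_barcodes_b = length(unique(measurements$barcode_id[side == levels(side)[2L]])),
    n_obs = full$n_obs,
    converged = ok
  )
}

#' Enumerate the comparisons of a design
#'
#' Builds the comparison table consumed by [differential_activity()]:
#' either the allelic ref-vs-alt pair of every variant (`log2FC` reported
#' as alt minus ref) or every ref-vs-shuffled-control pair (`log2FC`
#' reported as ref minus shuf).
#'
#' @param design An `mpra_design`.
#' @param type `"allelic"` or `"ref_shuf"`.
#' @returns Tibble: `comparison_id`, `element_a`, `element_b` (effect =
#'   b minus a).
#' @export
mpra_comparisons <- function(design, type = c("allelic", "ref_shuf")) {
  type <- match.arg(type)
  el <- design$elements
  if (type == "allelic") {
    refs <- el[el$element_class == "ref" & !is.na(el$variant_id), ]
    tibble::tibble(
      comparison_id = refs$variant_id,
      element_a = refs$element_id,
      element_b = refs$paired_element_id
    )
  } else {
    shufs <- el[el$element_class == "shuf", ]
    tibble::tibble(
      comparison_id = paste0(shufs$paired_element_id, "_vs_shuf"),
      element_a = shufs$element_id,
      element_b = shufs$paired_element_id
    )
  }
}

#' Differential activity testing across comparisons
#'
#' Runs [lrt_pair_test()] for every comparison with at least one passing
#' barcode on each side and applies Benjamini-Hochberg FDR adjustment
#' across all computed p-values.
#'
#' @param measurements Barcode-level activity table (from
#'   [barcode_activity()] with a design attached): `element_id`,
#'   `barcode_id`, `value`.
#' @param comparisons Comparison table from [mpra_comparisons()] (or any
#'   tibble with `comparison_id`, `element_a`, `element_b`).
#' @param fdr Significance threshold recorded in the `significant` column.
#' @returns Tibble: `comparison_id`, `log2FC`, `p_value`, `q_value`,
#'   `significant`, `n_barcodes_a`, `n_barcodes_b`, `n_obs`, `converged`.
#'   Comparisons with a missing side are omitted.
#' @export
differential_activity <- function(measurements, comparisons, fdr = 0.05) {
  res <- purrr::map_dfr(seq_len(nrow(comparisons)), function(i) {
    cmp <- comparisons[i, ]
    a <- measurements[measurements$element_id == cmp$element_a, ]
    b <- measurements[measurements$element_id == cmp$element_b, ]
    if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
    df <- dplyr::bind_rows(
      dplyr::mutate(a, side = "a"),
      dplyr::mutate(b, side = "b")
    )
    df$side <- factor(df$side, levels = c("a", "b"))
    dplyr::bind_cols(tibble::tibble(comparison_id = cmp$comparison_id),
                     lrt_pair_test(df))
  })
  if (nrow(res) == 0L) {
    return(tibble::tibble(
      comparison_id = character(), log2FC = numeric(), p_value = numeric(),
      q_value = numeric(), significant = logical()
    ))
  }
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < fdr
  dplyr::relocate(res, "q_value", "significant", .after = "p_value")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1), delegated to
#' [stats::p.adjust()] after input validation.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @returns Numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences `a - b`: zero
#' differences are dropped, tied absolute differences receive mid-ranks,
#' and the tail probability is exact (dynamic-programming enumeration over
#' all sign assignments) for up to 25 non-zero pairs, switching to the
#' normal approximation with tie and continuity corrections above that.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @returns List: `statistic` (positive-rank sum `V`), `p_value`, `n_used`
#'   (non-zero pairs), `method`, `degenerate` (`TRUE` when all differences
#'   are zero, in which case `p_value = 1`).
#' @export
paired_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])

  if (n <= 25L) {
    # Exact null distribution of the doubled rank sum (doubling keeps
    # mid-ranks integral) by the usual generating-function recursion.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (w in r2) {
      shifted <- c(numeric(w), f[seq_len(total + 1L - w)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n_used = n, method = method,
       degenerate = FALSE)
}

#' Direction-of-effect enrichment
#'
#' Tests whether significant comparisons skew toward one direction more
#' than the non-significant background by a one-sided hypergeometric
#' (Fisher) test on the 2x2 table with rows significant / non-significant
#' and columns down / up. The odds ratio is the sample cross-product ratio.
#'
#' @param n_down,n_up Down- and up-regulated significant comparisons.
#' @param bg_down,bg_up Down- and up-trending non-significant comparisons.
#' @returns List: `odds_ratio`, `p_value` (one-sided, enrichment of the
#'   down direction among significant), `table`, `degenerate`.
#' @export
direction_enrichment <- function(n_down, n_up, bg_down, bg_up) {
  stopifnot(n_down >= 0, n_up >= 0, bg_down >= 0, bg_up >= 0)
  tab <- matrix(c(n_down, bg_down, n_up, bg_up), nrow = 2L,
                dimnames = list(c("significant", "background"),
                                c("down", "up")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab,
                degenerate = TRUE))
  }
  or <- (n_down * bg_up) / (n_up * bg_down)
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, p_value = p, table = tab, degenerate = FALSE)
}

#' Grid search over inclusion thresholds
#'
#' Sweeps candidate `(min_count, min_barcodes, min_replicates)` inclusion
#' thresholds. At each grid point a comparison is retained when, in at
#' least `min_replicates` replicates, both of its sides have at least
#' `min_barcodes` barcodes passing the `min_count` raw-count floor in both
#' the RNA and DNA libraries; the retained comparisons are then tested with
#' [differential_activity()]. The returned thresholds maximize the number
#' of comparisons significant at the given FDR, breaking ties toward
#' stringency (largest `min_barcodes`, then `min_replicates`, then
#' `min_count`).
#'
#' @inheritParams barcode_activity
#' @param design An `mpra_design` (or barcode-to-element map).
#' @param comparisons Comparison table (see [mpra_comparisons()]).
#' @param min_count_grid Candidate count floors (values below 10 are not
#'   allowed).
#' @param min_barcodes_grid Candidate per-side barcode minima.
#' @param min_replicates_grid Candidate replicate minima.
#' @param fdr FDR threshold defining "significant" (default 0.05).
#' @returns List of class `mpra_grid_search`: `best` (one-row tibble of
#'   thresholds), `audit` (per grid point: thresholds, `n_testable`,
#'   `n_significant`), and `results` (the test table at the best point).
#'   If no grid point yields a testable comparison, `best` is `NULL`.
#' @export
grid_search_filter <- function(counts, samples, design, comparisons,
                               measure = "transcript_abundance",
                               min_count_grid = 10L,
                               min_barcodes_grid = c(3L, 5L),
                               min_replicates_grid = c(4L, 6L),
                               fdr = 0.05,
                               dna_policy = c("mean", "paired")) {
  dna_policy <- match.arg(dna_policy)
  if (any(min_count_grid < 10L)) {
    stop("min_count_grid values below the enforced floor of 10", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    min_count = sort(unique(as.integer(min_count_grid))),
    min_barcodes = sort(unique(as.integer(min_barcodes_grid))),
    min_replicates = sort(unique(as.integer(min_replicates_grid)))
  )

  audit <- list()
  results_by_point <- vector("list", nrow(grid))
  for (mc in unique(grid$min_count)) {
    act <- barcode_activity(counts, samples, measure = measure,
                            min_count = mc, dna_policy = dna_policy,
                            design = design)
    act <- act[!is.na(act$element_id), ]
    # barcodes passing the floor, per element per replicate
    tallies <- act |>
      dplyr::count(.data$element_id, .data$replicate, name = "n_bc")
    rows <- which(grid$min_count == mc)
    for (i in rows) {
      g <- grid[i, ]
      retained <- retained_comparisons(comparisons, tallies,
                                       g$min_barcodes, g$min_replicates)
      if (length(retained) == 0L) {
        audit[[i]] <- dplyr::bind_cols(g, tibble::tibble(
          n_testable = 0L, n_significant = 0L
        ))
        next
      }
      res <- differential_activity(
        act, comparisons[comparisons$comparison_id %in% retained, ], fdr = fdr
      )
      results_by_point[[i]] <- res
      audit[[i]] <- dplyr::bind_cols(g, tibble::tibble(
        n_testable = nrow(res), n_significant = sum(res$significant)
      ))
    }
  }
  audit <- dplyr::arrange(dplyr::bind_rows(audit), .data$min_count,
                          .data$min_barcodes, .data$min_replicates)

  if (all(audit$n_testable == 0L)) {
    out <- list(best = NULL, audit = audit, results = NULL)
    class(out) <- "mpra_grid_search"
    return(out)
  }
  ranked <- dplyr::arrange(
    audit,
    dplyr::desc(.data$n_significant), dplyr::desc(.data$min_barcodes),
    dplyr::desc(.data$min_replicates), dplyr::desc(.data$min_count)
  )
  best <- ranked[1L, ]
  best_idx <- which(
    grid$min_count == best$min_count &
      grid$min_barcodes == best$min_barcodes &
      grid$min_replicates == best$min_replicates
  )
  out <- list(
    best = dplyr::select(best, "min_count", "min_barcodes", "min_replicates"),
    audit = audit,
    results = results_by_point[[best_idx]]
  )
  class(out) <- "mpra_grid_search"
  out
}

# Comparison ids whose both sides reach `min_barcodes` passing barcodes in
# at least `min_replicates` replicates.
retained_comparisons <- function(comparisons, tallies, min_barcodes,
                                 min_replicates) {
  ok_cells <- tallies[tallies$n_bc >= min_barcodes, ]
  keep <- purrr::map_lgl(seq_len(nrow(comparisons)), function(i) {
    cmp <- comparisons[i, ]
    reps_a <- ok_cells$replicate[ok_cells$element_id == cmp$element_a]
    reps_b <- ok_cells$replicate[ok_cells$element_id == cmp$element_b]
    length(intersect(reps_a, reps_b)) >= min_replicates
  })
  comparisons$comparison_id[keep]
}

#' @export
print.mpra_grid_search <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<mpra_grid_search> no grid point yielded testable comparisons\n")
  } else {
    cat(sprintf(
      "<mpra_grid_search> best thresholds: count >= %d, barcodes >= %d, replicates >= %d (%d significant of %d testable)\n",
      x$best$min_count, x$best$min_barcodes, x$best$min_replicates,
      x$audit$n_significant[
        x$audit$min_count == x$best$min_count &
          x$audit$min_barcodes == x$best$min_barcodes &
          x$audit$min_replicates == x$best$min_replicates
      ],
      x$audit$n_testable[
        x$audit$min_count == x$best$min_count &
          x$audit$min_barcodes == x$best$min_barcodes &
          x$audit$min_replicates == x$best$min_replicates
      ]
    ))
  }
  invisible(x)
}
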