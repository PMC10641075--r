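#' Simulate a null barcode pool
#'
#' Generates per-replicate activity values for a pool of barcodes tagging a
#' single null element: barcode effects `b_i ~ N(0, sigma_b^2)` plus
#' replicate noise `N(0, sigma_e^2)` around a common mean. This is the
#' input for [power_curve()], which measures how often purely
#' barcode-driven variation masquerades as an allelic effect. A pool can
#' equally be derived from real or simulated count data by filtering a
#' [barcode_activity()] table to one element's barcodes.
#'
#' @param n_barcodes Pool size (default 100).
#' @param n_replicates Replicates per barcode (default 6).
#' @param sigma_b Barcode effect SD, log2 units.
#' @param sigma_e Residual (replicate) SD, log2 units.
#' @param mean Common element mean (default 0).
#' @param seed Integer seed.
#' @returns Tibble: `barcode_id`, `replicate`, `value`.
#' @export
simulate_pool <- function(n_barcodes = 100L, n_replicates = 6L,
                          sigma_b = 0.3, sigma_e = 0.1, mean = 0,
                          seed = NULL) {
  stopifnot(n_barcodes >= 2L, n_replicates >= 1L, sigma_b >= 0, sigma_e >= 0)
  with_seed(seed, {
    b <- rnorm(n_barcodes, 0, sigma_b)
    tidyr::expand_grid(
      barcode = seq_len(n_barcodes), replicate = seq_len(n_replicates)
    ) |>
      dplyr::mutate(
        barcode_id = sprintf("BC%03d", .data$barcode),
        value = mean + b[.data$barcode] + rnorm(dplyr::n(), 0, sigma_e)
      ) |>
      dplyr::select("barcode_id", "replicate", "value")
  })
}

#' Draw two disjoint pseudo-allele barcode sets
#'
#' Samples `2k` distinct barcodes from the pool uniformly without
#' replacement and splits them into two size-`k` "alleles". Both sets tag
#' the same element, so any apparent allelic difference is a barcode
#' artifact.
#'
#' @param barcode_ids Character vector of available barcode ids.
#' @param k Barcodes per pseudo-allele.
#' @returns List with `a` and `b`, disjoint character vectors of length `k`.
#' @export
draw_pseudo_alleles <- function(barcode_ids, k) {
  barcode_ids <- unique(barcode_ids)
  if (length(barcode_ids) < 2L * k) {
    stop(sprintf("pool of %d barcodes cannot supply two disjoint sets of %d",
                 length(barcode_ids), k), call. = FALSE)
  }
  picked <- sample(barcode_ids, 2L * k)
  list(a = picked[seq_len(k)], b = picked[k + seq_len(k)])
}

#' False-allelic-effect curve over barcodes per allele
#'
#' For each `k` in `k_range`, repeatedly draws disjoint pseudo-allele
#' barcode sets from a null pool, computes the apparent log2 fold-change
#' (difference of the two sets' barcode-mean activities) and the
#' random-intercept LRT p-value ([lrt_pair_test()]), and summarizes the
#' distribution of spurious effects: quantiles of `|log2FC|`, the
#' probability of exceeding `fc_threshold`, and the Type-I error rate at
#' `alpha`. Deterministic given `seed`, including across `k`.
#'
#' @param pool Pool tibble from [simulate_pool()] (`barcode_id`,
#'   `replicate`, `value`); every barcode must have the same replicates.
#' @param k_range Integer vector of barcodes per allele (e.g. `3:50`).
#' @param n_iter Iterations per `k` (default 10000).
#' @param fc_threshold Absolute log2FC magnitude of interest (default 0.25).
#' @param alpha Nominal test level for the Type-I rate (default 0.05).
#' @param seed Integer seed.
#' @returns Tibble of class `mpra_power_curve`: `k`, `fc_q25`, `fc_q50`,
#'   `fc_q75`, `fc_iqr`, `p_fc_gt_threshold`, `type1_rate`, `n_iter`.
#' @export
power_curve <- function(pool, k_range, n_iter = 10000L, fc_threshold = 0.25,
                        alpha = 0.05, seed = NULL) {
  stopifnot(n_iter >= 100L)
  wide <- tidyr::pivot_wider(pool, id_cols = "barcode_id",
                             names_from = "replicate", values_from = "value")
  Y <- as.matrix(wide[-1L])
  if (anyNA(Y)) stop("pool must be complete (every barcode x replicate)",
                     call. = FALSE)
  nB <- nrow(Y)
  n_rep <- ncol(Y)

  with_seed(seed, {
    purrr::map_dfr(sort(unique(as.integer(k_range))), function(k) {
      if (nB < 2L * k) {
        stop(sprintf("pool of %d barcodes cannot supply k = %d", nB, k),
             call. = FALSE)
      }
      # Fixed structural parts of the two nested LMMs for this k: groups
      # are the 2k drawn barcodes (n_rep obs each), side flags the second k.
      N <- 2L * k * n_rep
      ni <- rep(n_rep, 2L * k)
      side <- rep(c(0, 1), each = k)
      S_full <- cbind(n_rep, n_rep * side)
      S_red <- matrix(n_rep, nrow = 2L * k, ncol = 1L)
      XtX_full <- matrix(c(N, N / 2, N / 2, N / 2), 2L)
      XtX_red <- matrix(N, 1L)

      fc <- numeric(n_iter)
      pval <- numeric(n_iter)
      for (it in seq_len(n_iter)) {
        idx <- sample.int(nB, 2L * k)
        ti <- Y[idx, , drop = FALSE] %*% rep(1, n_rep)
        ti <- ti[, 1L]
        yty <- sum(Y[idx, ]^2)
        sum_y <- sum(ti)
        sum_yb <- sum(ti[(k + 1L):(2L * k)])
        full <- .lmm_fit_stats(ni, S_full, ti, yty, XtX_full,
                               c(sum_y, sum_yb), N)
        red <- .lmm_fit_stats(ni, S_red, ti, yty, XtX_red, sum_y, N)
        fc[it] <- sum_yb / (k * n_rep) - (sum_y - sum_yb) / (k * n_rep)
        stat <- max(2 * (full$loglik - red$loglik), 0)
        pval[it] <- pchisq(stat, df = 1L, lower.tail = FALSE)
      }
      q <- quantile(abs(fc), c(0.25, 0.5, 0.75), names = FALSE)
      tibble::tibble(
        k = k, fc_q25 = q[1L], fc_q50 = q[2L], fc_q75 = q[3L],
        fc_iqr = q[3L] - q[1L],
        p_fc_gt_threshold = mean(abs(fc) > fc_threshold),
        type1_rate = mean(pval < alpha),
        n_iter = n_iter
      )
    }) |>
      structure(class = c("mpra_power_curve", "tbl_df", "tbl", "data.frame"))
  })
}

#' Recommend a barcode count from a power curve
#'
#' Returns the smallest `k` whose Type-I error rate does not exceed
#' `max_type1`, or `NA` if no point on the curve satisfies the bound.
#'
#' @param curve Output of [power_curve()].
#' @param max_type1 Tolerated Type-I error rate.
#' @returns Integer `k`, or `NA_integer_`.
#' @export
recommend_barcode_count <- function(curve, max_type1 = 0.05) {
  stopifnot(nrow(curve) > 0L)
  ok <- curve$k[curve$type1_rate <= max_type1]
  if (length(ok) == 0L) NA_integer_ else min(ok)
}

#' @method autoplot mpra_power_curve
#' @export
autoplot.mpra_power_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("k", "p_fc_gt_threshold", "type1_rate")],
    cols = c("p_fc_gt_threshold", "type1_rate"),
    names_to = "metric", values_to = "rate"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$rate,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "barcodes per allele", y = "fraction of iterations",
      colour = NULL,
      title = "Spurious allelic effects from barcode sampling"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mpra_power_curve
#' @param curve Output of [power_curve()].
#' @export
plot_power_curve <- function(curve, ...) autoplot(curve, ...)
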