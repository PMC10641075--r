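test_that("the LRT is null for identical sides and recovers planted effects", {
  base <- make_pair_measurements(k = 4L, n_rep = 3L, sigma_e = 0.2, seed = 51)
  same <- dplyr::bind_rows(
    dplyr::mutate(base[base$side == "a", ], side = "a"),
    dplyr::mutate(base[base$side == "a", ], side = "b",
                  barcode_id = paste0("copy_", barcode_id))
  )
  res <- lrt_pair_test(same)
  expect_equal(res$log2FC, 0, tolerance = 1e-8)
  expect_gt(res$p_value, 0.99)

  planted <- make_pair_measurements(k = 6L, n_rep = 6L, beta = 1, sigma_b = 0,
                                    sigma_e = 0.1, seed = 52)
  res2 <- lrt_pair_test(planted)
  expect_gt(res2$log2FC, 0.8)
  expect_lt(res2$log2FC, 1.2)
  expect_lt(res2$p_value, 1e-6)
  expect_true(res2$converged)
  expect_identical(res2$n_barcodes_a, 6L)
})

test_that("few barcodes with real barcode effects inflate the LRT rejection rate", {
  # anti-conservatism: the barcode random effect is confounded with the
  # pseudo-allelic split, so at sigma_b > 0 and k = 3 the test over-rejects
  rej <- withr::with_seed(61, {
    mean(vapply(1:500, function(i) {
      df <- make_pair_measurements(k = 3L, n_rep = 4L, beta = 0,
                                   sigma_b = 0.3, sigma_e = 0.1)
      lrt_pair_test(df)$p_value < 0.05
    }, logical(1)))
  })
  expect_gt(rej, 0.05)
})

test_that("BH adjustment matches the step-up formula on random inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_identical(bh_adjust(numeric()), numeric())
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")

  bh_oracle <- function(p) {
    # direct p * m / rank with a cumulative minimum from the largest p down
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
  }
  withr::with_seed(71, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_oracle(p))
      # monotone: a smaller p never gets a larger q
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
})

test_that("signed-rank p-values match brute-force sign enumeration for n <= 10", {
  enum_oracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p_le <- mean(v_all <= v_obs + 1e-9)
    p_ge <- mean(v_all >= v_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  withr::with_seed(81, {
    for (i in 1:15) {
      n <- sample(3:10, 1)
      a <- round(rnorm(n), 1)  # rounding forces occasional ties
      b <- round(rnorm(n), 1)
      keep <- a != b
      if (sum(keep) < 2) next
      ours <- paired_signed_rank(a, b)
      expect_equal(ours$p_value, enum_oracle((a - b)[keep]), tolerance = 1e-10)
    }
  })
})

test_that("signed-rank agrees with wilcox.test on tie-free data", {
  withr::with_seed(91, {
    for (i in 1:10) {
      a <- rnorm(12)
      b <- rnorm(12)
      ours <- paired_signed_rank(a, b)
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    }
    # large-n normal approximation with continuity correction
    a <- rnorm(60); b <- rnorm(60, -0.3)
    ours <- paired_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("signed-rank handles all-positive and degenerate inputs", {
  res <- paired_signed_rank(7:12, 6:11 - c(0, 1, 2, 3, 4, 5))
  # differences 1..6, all positive: two-sided exact p = 2/2^6
  expect_equal(res$p_value, 0.03125)
  same <- paired_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_identical(same$p_value, 1)
  # a strong consistent shift at n = 300 is overwhelmingly significant
  shifted <- withr::with_seed(95, {
    x <- rnorm(300)
    paired_signed_rank(x + rnorm(300, 0.5, 0.1), x)
  })
  expect_lt(shifted$p_value, 1e-3)
})

test_that("direction enrichment builds the documented 2x2 table", {
  even <- direction_enrichment(5, 5, 20, 20)
  expect_equal(even$odds_ratio, 1)
  expect_gte(even$p_value, 0.5)

  res <- direction_enrichment(9, 1, 5, 5)
  expect_equal(res$odds_ratio, 9)
  # hypergeometric tail oracle: P(X >= 9) drawing 10 from 14 down / 6 up
  p_oracle <- sum(stats::dhyper(9:10, 14, 6, 10))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)

  degen <- direction_enrichment(0, 0, 10, 10)
  expect_true(degen$degenerate)
  expect_identical(degen$p_value, 1)
})

test_that("differential activity orchestrates comparisons and flags alt-ref sign", {
  map <- make_bc_map(n_variants = 12L)
  sim <- simulate_counts(map, n_replicates = 6L, depth_dna = 2e6,
                         depth_rna = 2e6, element_effect_sd = 0.3,
                         barcode_effect_sd = 0,
                         allelic_effects = c(v003 = 1.2, v007 = -0.8),
                         seed = 103)
  act <- barcode_activity(sim$counts, sim$samples, design = map)
  comparisons <- tibble::tibble(
    comparison_id = sprintf("v%03d", 1:12),
    element_a = sprintf("v%03d_ref", 1:12),
    element_b = sprintf("v%03d_alt", 1:12)
  )
  res <- differential_activity(act, comparisons)
  expect_identical(nrow(res), 12L)
  expect_true(all(res$q_value >= res$p_value))
  expect_equal(res$log2FC[res$comparison_id == "v003"], 1.2, tolerance = 0.25)
  expect_equal(res$log2FC[res$comparison_id == "v007"], -0.8, tolerance = 0.25)
  expect_true(all(res$significant[res$comparison_id %in% c("v003", "v007")]))
  expect_false(any(res$significant[!res$comparison_id %in% c("v003", "v007")]))
})

test_that("grid search reproduces a brute-force re-filter and prefers stringency", {
  map <- make_bc_map(n_variants = 10L)
  sim <- simulate_counts(map, n_replicates = 6L, depth_dna = 3e5,
                         depth_rna = 3e5, element_effect_sd = 0.3,
                         barcode_effect_sd = 0.1,
                         allelic_effects = c(v001 = 1.5, v002 = 1.5, v003 = -1.5),
                         plasmid_abundance_sd = 1.2, seed = 107)
  comparisons <- tibble::tibble(
    comparison_id = sprintf("v%03d", 1:10),
    element_a = sprintf("v%03d_ref", 1:10),
    element_b = sprintf("v%03d_alt", 1:10)
  )
  gs <- grid_search_filter(
    sim$counts, sim$samples, map, comparisons,
    min_count_grid = c(10L, 20L), min_barcodes_grid = c(3L, 5L),
    min_replicates_grid = c(4L, 6L)
  )
  expect_identical(nrow(gs$audit), 8L)

  # independent brute-force re-filter oracle
  raw <- as.data.frame(sim$counts)
  rownames(raw) <- raw$barcode_id
  dna_cols <- sim$samples$sample_id[sim$samples$fraction == "DNA"]
  dna_mean <- rowMeans(raw[dna_cols])
  for (row in seq_len(nrow(gs$audit))) {
    g <- gs$audit[row, ]
    n_testable <- 0L
    for (v in comparisons$comparison_id) {
      ok_reps <- 0L
      for (r in 1:6) {
        rna <- raw[[paste0("Input_", r)]]
        names(rna) <- rownames(raw)
        pass <- function(el) {
          ids <- map$barcode_id[map$element_id == el]
          sum(rna[ids] >= g$min_count & dna_mean[ids] >= g$min_count,
              na.rm = TRUE)
        }
        if (pass(paste0(v, "_ref")) >= g$min_barcodes &&
            pass(paste0(v, "_alt")) >= g$min_barcodes) {
          ok_reps <- ok_reps + 1L
        }
      }
      if (ok_reps >= g$min_replicates) n_testable <- n_testable + 1L
    }
    expect_identical(g$n_testable, n_testable)
  }

  # the in vitro and in vivo threshold settings are representable grid points
  expect_true(nrow(dplyr::filter(gs$audit, min_count == 10, min_barcodes == 3,
                                 min_replicates == 4)) == 1L)
  expect_true(nrow(dplyr::filter(gs$audit, min_count == 10, min_barcodes == 5,
                                 min_replicates == 6)) == 1L)
  expect_error(grid_search_filter(sim$counts, sim$samples, map, comparisons,
                                  min_count_grid = 5L), "floor of 10")
})

test_that("a grid with no testable comparisons returns the explicit empty signal", {
  map <- make_bc_map(n_variants = 2L)
  sim <- simulate_counts(map, n_replicates = 2L, depth_dna = 1e4,
                         depth_rna = 1e4, seed = 109)
  comparisons <- tibble::tibble(comparison_id = c("v001", "v002"),
                                element_a = c("v001_ref", "v002_ref"),
                                element_b = c("v001_alt", "v002_alt"))
  gs <- grid_search_filter(sim$counts, sim$samples, map, comparisons,
                           min_count_grid = 10000L, min_barcodes_grid = 6L,
                           min_replicates_grid = 2L)
  expect_null(gs$best)
  expect_true(all(gs$audit$n_testable == 0L))
  # and an activity table with no usable comparison yields a typed empty result
  act <- barcode_activity(sim$counts, sim$samples, design = map)
  empty <- differential_activity(act[0, ], comparisons)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("comparison_id", "log2FC", "p_value", "q_value") %in%
                    names(empty)))
})
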