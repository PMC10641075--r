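#' Simulate DNA / Input-RNA / TRAP-RNA barcode count tables
#'
#' Generates a barcode-by-sample integer count table with known ground truth
#' from an [build_library()] design, following the generative chain the
#' downstream analysis assumes. Per barcode `i` of element `e` (allele `a`):
#'
#' * plasmid copy number `p_i ~ LogNormal(0, plasmid_abundance_sd)` — DNA
#'   counts are multinomial draws of the normalized copy numbers, so
#'   replicate DNA libraries share composition (copy number dominates
#'   abundance);
#' * expression `x_i = p_i * 2^(mu_e + beta_v * [a = alt] + b_i)` with
#'   element means `mu_e ~ N(0, element_effect_sd)` (shared within a
#'   ref/alt pair), planted allelic shifts `beta_v` from `allelic_effects`,
#'   and barcode effects `b_i ~ N(0, barcode_effect_sd^2)`;
#' * a transduction bottleneck per replicate: effective template copies
#'   `m_ir ~ Poisson(bottleneck_lambda)` scale the RNA rate by
#'   `m_ir / bottleneck_lambda` (zero templates drop the barcode from that
#'   replicate). `bottleneck_lambda = Inf` disables the bottleneck; small
#'   values produce the "jackpotting" seen when few template molecules
#'   enter library prep;
#' * Input RNA counts are multinomial over (optionally gamma-overdispersed,
#'   `nb_dispersion`) rates; TRAP rates are additionally scaled by
#'   `2^te_e` from `te_effects` before sampling, so the TRAP/Input ratio
#'   carries the translation-efficiency shift.
#'
#' The bottleneck draw is shared between the Input and TRAP sample of a
#' replicate (both derive from the same transduced cells).
#'
#' @param design An `mpra_design`, or a data frame with `barcode_id`,
#'   `element_id`, `element_class`, `variant_id`.
#' @param n_replicates Number of RNA replicates (default 6).
#' @param n_dna_replicates Number of DNA library replicates (default 2).
#' @param depth_dna,depth_rna Sequencing depth per sample (reads).
#' @param element_effect_sd SD of element means, log2 units (default 0.55).
#' @param allelic_effects Named numeric vector, `variant_id -> log2FC`
#'   planted on the alt allele (default: none, all zero).
#' @param te_effects Named numeric vector, `element_id -> log2 TE shift`.
#' @param barcode_effect_sd SD of barcode random effects, log2 units.
#' @param plasmid_abundance_sd Log-normal sdlog of plasmid copy number.
#' @param bottleneck_lambda Mean transduced template copies per barcode per
#'   replicate; `Inf` disables jackpotting.
#' @param nb_dispersion Gamma over-dispersion of RNA sampling rates
#'   (negative-binomial mixing; 0 = pure multinomial).
#' @param seed Integer seed; the whole table is deterministic given it.
#' @returns A list of class `mpra_sim`: `counts` (wide tibble, `barcode_id`
#'   plus one column per sample), `samples` (`sample_id`, `fraction`,
#'   `replicate`), and `truth` (tibbles `element`, `barcode`, `allelic`).
#' @export
simulate_counts <- function(design,
                            n_replicates = 6L,
                            n_dna_replicates = 2L,
                            depth_dna = 1e6,
                            depth_rna = 1e6,
                            element_effect_sd = 0.55,
                            allelic_effects = NULL,
                            te_effects = NULL,
                            barcode_effect_sd = 0.25,
                            plasmid_abundance_sd = 1.0,
                            bottleneck_lambda = Inf,
                            nb_dispersion = 0,
                            seed = NULL) {
  stopifnot(n_replicates >= 1L, element_effect_sd >= 0, barcode_effect_sd >= 0,
            plasmid_abundance_sd >= 0, nb_dispersion >= 0, bottleneck_lambda > 0)
  bc <- sim_barcode_frame(design)
  nB <- nrow(bc)

  with_seed(seed, {
    # element means, shared within a ref/alt pair
    el <- dplyr::distinct(bc, .data$element_id, .data$element_class, .data$variant_id)
    pair_key <- ifelse(
      el$element_class %in% c("ref", "alt") & !is.na(el$variant_id),
      paste0("v:", el$variant_id), paste0("e:", el$element_id)
    )
    keys <- unique(pair_key)
    mu_by_key <- setNames(rnorm(length(keys), 0, element_effect_sd), keys)
    el$mu <- as.numeric(mu_by_key[pair_key])
    el$beta <- 0
    if (!is.null(allelic_effects) && length(allelic_effects)) {
      hit <- el$element_class == "alt" & el$variant_id %in% names(allelic_effects)
      el$beta[hit] <- as.numeric(allelic_effects[el$variant_id[hit]])
    }
    el$te_shift <- 0
    if (!is.null(te_effects) && length(te_effects)) {
      hit <- el$element_id %in% names(te_effects)
      el$te_shift[hit] <- as.numeric(te_effects[el$element_id[hit]])
    }

    bc <- dplyr::left_join(
      bc, dplyr::select(el, "element_id", "mu", "beta", "te_shift"),
      by = "element_id"
    )
    bc$b <- rnorm(nB, 0, barcode_effect_sd)
    bc$plasmid_copy <- rlnorm(nB, 0, plasmid_abundance_sd)
    x <- bc$plasmid_copy * 2^(bc$mu + bc$beta + bc$b)
    te_mult <- 2^bc$te_shift

    draw <- function(rate, depth) {
      if (sum(rate) <= 0) return(integer(length(rate)))
      as.integer(rmultinom(1L, size = depth, prob = rate))
    }
    overdisperse <- function(rate) {
      if (nb_dispersion <= 0) return(rate)
      rate * rgamma(length(rate), shape = 1 / nb_dispersion, rate = 1 / nb_dispersion)
    }

    cols <- list()
    samples <- list()
    for (d in seq_len(n_dna_replicates)) {
      id <- sprintf("DNA_%d", d)
      cols[[id]] <- draw(bc$plasmid_copy, depth_dna)
      samples[[id]] <- tibble::tibble(sample_id = id, fraction = "DNA",
                                      replicate = d)
    }
    for (r in seq_len(n_replicates)) {
      f <- if (is.finite(bottleneck_lambda)) {
        rpois(nB, bottleneck_lambda) / bottleneck_lambda
      } else {
        1
      }
      id_in <- sprintf("Input_%d", r)
      cols[[id_in]] <- draw(overdisperse(x * f), depth_rna)
      samples[[id_in]] <- tibble::tibble(sample_id = id_in, fraction = "Input",
                                         replicate = r)
      id_tr <- sprintf("TRAP_%d", r)
      cols[[id_tr]] <- draw(overdisperse(x * te_mult * f), depth_rna)
      samples[[id_tr]] <- tibble::tibble(sample_id = id_tr, fraction = "TRAP",
                                         replicate = r)
    }

    structure(
      list(
        counts = tibble::as_tibble(c(list(barcode_id = bc$barcode_id), cols)),
        samples = dplyr::bind_rows(samples),
        truth = list(
          element = tibble::as_tibble(el),
          barcode = dplyr::select(bc, "barcode_id", "element_id", "b",
                                  "plasmid_copy"),
          allelic = {
            av <- unique(el$variant_id[!is.na(el$variant_id)])
            bv <- rep(0, length(av))
            if (!is.null(allelic_effects) && length(allelic_effects)) {
              hit <- av %in% names(allelic_effects)
              bv[hit] <- as.numeric(allelic_effects[av[hit]])
            }
            tibble::tibble(variant_id = av, beta = bv)
          }
        )
      ),
      class = "mpra_sim"
    )
  })
}

# Normalize the design argument to a barcode-level frame.
sim_barcode_frame <- function(design) {
  if (inherits(design, "mpra_design")) {
    bc <- dplyr::left_join(
      dplyr::select(design$barcodes, "barcode_id", "element_id"),
      dplyr::select(design$elements, "element_id", "element_class", "variant_id"),
      by = "element_id"
    )
  } else {
    bc <- tibble::as_tibble(design)
    stopifnot(all(c("barcode_id", "element_id", "element_class") %in% names(bc)))
    if (!"variant_id" %in% names(bc)) bc$variant_id <- NA_character_
  }
  if (anyDuplicated(bc$barcode_id)) {
    stop("barcode_id must be unique across the design", call. = FALSE)
  }
  bc
}

#' @export
print.mpra_sim <- function(x, ...) {
  cat(sprintf(
    "<mpra_sim> %d barcodes x %d samples (%s)\n",
    nrow(x$counts), nrow(x$samples),
    paste(sprintf("%s: %d", names(table(x$samples$fraction)),
                  table(x$samples$fraction)), collapse = ", ")
  ))
  invisible(x)
}

#' Tabulate simulation ground truth for joining against estimates
#'
#' Expands the truth component of an [simulate_counts()] result into a
#' per-element table of expected activity (element mean plus allelic shift
#' for alt alleles), expected translation-efficiency shift, and, for
#' variant-linked elements, the planted allelic log2 fold-change.
#'
#' @param sim An `mpra_sim` object, or its `truth` list.
#' @returns Tibble with `element_id`, `element_class`, `variant_id`,
#'   `expected_activity`, `expected_te`, `allelic_log2fc`.
#' @export
truth_table <- function(sim) {
  truth <- if (inherits(sim, "mpra_sim")) sim$truth else sim
  el <- truth$element
  tibble::tibble(
    element_id = el$element_id,
    element_class = el$element_class,
    variant_id = el$variant_id,
    expected_activity = el$mu + el$beta,
    expected_te = el$te_shift,
    allelic_log2fc = ifelse(
      is.na(el$variant_id), NA_real_,
      as.numeric(
        setNames(truth$allelic$beta, truth$allelic$variant_id)[el$variant_id]
      )
    )
  )
}
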