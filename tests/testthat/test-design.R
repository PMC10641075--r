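test_that("SNV windows are centered with the variant at offset window/2", {
  ref <- c(chrA = strrep("A", 300))
  v <- list(variant_id = "v1", chrom = "chrA", pos = 150, ref_allele = "A",
            alt_allele = "T")
  w <- extract_window(ref, v)
  expect_identical(w$ref_context, strrep("A", 120))
  expect_identical(nchar(w$alt_context), 120L)
  expect_identical(w$variant_offset, 60L)
  expect_identical(substr(w$alt_context, 61, 61), "T")
  expect_identical(gsub("T", "A", w$alt_context), strrep("A", 120))
})

test_that("windows near a sequence end are clipped, not errors", {
  ref <- make_reference(len = 300L, seed = 7L)
  base <- substr(ref[[1L]], 10, 10)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1L]
  v <- list(variant_id = "edge", chrom = "chr1", pos = 10, ref_allele = base,
            alt_allele = alt)
  w <- extract_window(ref, v)
  # brute-force slice oracle: 9 left flank bases available, 59 right
  expect_identical(w$ref_context, substr(ref[[1L]], 1, 69))
  expect_identical(w$variant_offset, 9L)
  expect_identical(substr(w$alt_context, 10, 10), alt)
})

test_that("a wrong reference allele raises a mismatch error naming the variant", {
  ref <- c(chr1 = strrep("G", 200))
  v <- list(variant_id = "bad_v", chrom = "chr1", pos = 100, ref_allele = "C",
            alt_allele = "T")
  expect_error(extract_window(ref, v), "bad_v")
  expect_error(extract_window(ref, v), "does not match")
})

test_that("indel contexts share flanks and fit the window", {
  ref <- make_reference(len = 400L, seed = 9L)
  del_ref <- substr(ref[[1L]], 200, 202)
  v <- list(variant_id = "del1", chrom = "chr1", pos = 200,
            ref_allele = del_ref, alt_allele = substr(del_ref, 1, 1))
  w <- extract_window(ref, v)
  expect_identical(nchar(w$ref_context), 120L)
  expect_identical(nchar(w$alt_context), 118L)
  # both contexts share the genomic flanks
  left <- w$variant_offset
  expect_identical(substr(w$ref_context, 1, left), substr(w$alt_context, 1, left))
  expect_identical(substr(w$ref_context, left + 4, 120),
                   substr(w$alt_context, left + 2, 118))
})

test_that("shuffles conserve composition and are seed-deterministic", {
  expect_identical(shuffle_sequence("AAAA", seed = 1), "AAAA")
  s <- shuffle_sequence("ACGTACGT", seed = 5)
  expect_identical(sort(strsplit(s, "")[[1]]), sort(strsplit("ACGTACGT", "")[[1]]))
  expect_identical(shuffle_sequence("ACGTACGTTTGCA", seed = 11),
                   shuffle_sequence("ACGTACGTTTGCA", seed = 11))

  # multiset permutations of AAACCC: 6!/(3!3!) = 20 distinct outcomes, so
  # the chance of reproducing the input is 1/20
  hits <- withr::with_seed(99, {
    mean(vapply(1:1000, function(i) {
      identical(shuffle_sequence("AAACCC"), "AAACCC")
    }, logical(1)))
  })
  expect_gt(hits, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(hits, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("generated barcodes satisfy all whitelist constraints", {
  wl <- generate_barcodes(400, seed = 21)
  expect_identical(nrow(wl), 400L)
  expect_true(all(nchar(wl$sequence) == 9L))
  expect_false(any(grepl("AAAA|CCCC|GGGG|TTTT", wl$sequence)))
  expect_false(any(grepl("GCTAGC|GGTACC", wl$sequence)))
  expect_identical(min_hamming_distance(wl$sequence), 2L)
  expect_identical(generate_barcodes(50, seed = 3), generate_barcodes(50, seed = 3))
})

test_that("an unsatisfiable barcode request raises a capacity error", {
  # length-2 barcodes at Hamming distance 2: at most 4 can coexist
  expect_error(generate_barcodes(20, length = 2, seed = 1),
               "constraints unsatisfiable")
})

test_that("min_hamming_distance detects duplicates and adjacent pairs", {
  expect_identical(min_hamming_distance(c("ACGTACGTA", "ACGTACGTA")), 0L)
  expect_identical(min_hamming_distance(c("ACGTACGTA", "ACGTACGTC")), 1L)
  expect_identical(min_hamming_distance(c("AAAAAAAAA", "CCCCCCCCC")), 2L)
})

test_that("assembled oligos have the documented layout and round-trip", {
  design <- make_design(n_variants = 2L, n_shuffle = 1L,
                        barcodes_per_element = 2L)
  ol <- design$oligos
  expect_true(all(nchar(ol$full_sequence) == 210L))
  for (lay in ol$layout[1:3]) {
    expect_identical(lay$start[1L], 0L)
    expect_identical(lay$end[nrow(lay)], 210L)
    expect_identical(lay$start[-1L], lay$end[-nrow(lay)])  # contiguous
  }
  # slicing by layout recovers barcode and element exactly
  bc_seq <- design$barcodes$sequence[match(ol$barcode_id, design$barcodes$barcode_id)]
  expect_identical(oligo_segment(ol, "barcode"), bc_seq)
  el_seq <- design$elements$sequence[match(ol$element_id, design$elements$element_id)]
  expect_identical(oligo_segment(ol, "utr_context"), el_seq)
})

test_that("short elements are padded to the constant oligo length", {
  el <- tibble::tibble(element_id = "short", sequence = strrep("ACGT", 25))
  bc <- tibble::tibble(element_id = "short", barcode_id = "b1",
                       sequence = "ACGTACGTA")
  ol <- assemble_oligo(el, bc)
  expect_identical(nchar(ol$full_sequence), 210L)
  expect_true("pad5" %in% ol$layout[[1]]$segment)
  expect_identical(oligo_segment(ol, "utr_context"), strrep("ACGT", 25))
  # padding sits outside the 5' cut site
  lay <- ol$layout[[1]]
  expect_lt(lay$end[lay$segment == "pad5"],
            lay$start[lay$segment == "cutsite5"] + 1L)

  too_long <- tibble::tibble(element_id = "long", sequence = strrep("A", 121))
  expect_error(assemble_oligo(too_long, dplyr::mutate(bc, element_id = "long")),
               "longer than")
})

test_that("library element and oligo counts follow the design arithmetic", {
  ref <- make_reference(len = 3000L, seed = 31L)

  d1 <- build_library(make_variants(ref, 1L, seed = 32L), ref,
                      barcodes_per_element = 1L, seed = 1)
  expect_identical(nrow(d1$elements), 2L)
  expect_identical(nrow(d1$oligos), 2L)

  d2 <- build_library(make_variants(ref, 2L, seed = 33L), ref, n_shuffle = 2L,
                      barcodes_per_element = 3L, seed = 1)
  expect_identical(nrow(d2$elements), 6L)
  expect_identical(nrow(d2$oligos), 18L)

  # every shuf element conserves its partner's letter counts
  shufs <- d2$elements[d2$elements$element_class == "shuf", ]
  for (i in seq_len(nrow(shufs))) {
    src <- d2$elements$sequence[d2$elements$element_id == shufs$paired_element_id[i]]
    expect_identical(sort(strsplit(shufs$sequence[i], "")[[1]]),
                     sort(strsplit(src, "")[[1]]))
    expect_equal(shufs$gc_content[i],
                 d2$elements$gc_content[d2$elements$element_id == shufs$paired_element_id[i]])
  }

  # barcode -> element assignment is a function: no barcode reused
  expect_false(anyDuplicated(d2$barcodes$sequence) > 0)
  expect_true(all(table(d2$oligos$element_id) == 3L))

  expect_error(
    build_library(dplyr::bind_rows(make_variants(ref, 1L), make_variants(ref, 1L)),
                  ref, seed = 1),
    "duplicate variant_id"
  )
})

test_that("identical inputs and seed give a byte-identical manifest", {
  d1 <- make_design(seed = 404L)
  d2 <- make_design(seed = 404L)
  expect_identical(d1$elements, d2$elements)
  expect_identical(d1$barcodes, d2$barcodes)
  expect_identical(d1$oligos, d2$oligos)
})

test_that("colony coverage follows the Poisson-approximate formula", {
  expect_identical(colony_coverage(100, 0), 0)
  expect_identical(colony_coverage(1, 10, 0), 1)
  expect_equal(colony_coverage(9744, 71000, 0.5),
               1 - (1 - 1 / 9744)^35500)
  expect_equal(colony_coverage(9744, 71000, 0.5), 0.974, tolerance = 1e-3)
  expect_error(colony_coverage(10, 10, 1.5), "error_rate")
})

test_that("design files round-trip through plain-text output", {
  design <- make_design(n_variants = 2L, n_shuffle = 0L,
                        barcodes_per_element = 2L)
  dir <- withr::local_tempdir()
  paths <- write_design(design, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths[["oligos"]])
  expect_identical(length(fa), nrow(design$oligos))
  expect_identical(unname(as.character(fa)), design$oligos$full_sequence)
})
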