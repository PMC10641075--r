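#' Generate a whitelist of well-separated barcodes
#'
#' Draws random DNA barcodes by rejection sampling and keeps a candidate only
#' if it (i) contains no homopolymer run longer than `max_homopolymer`,
#' (ii) contains none of the `forbidden` motifs (by default the NheI and KpnI
#' recognition sites used for cloning), and (iii) sits at Hamming distance at
#' least `min_hamming` from every barcode accepted so far. Separation is
#' enforced with a hash of the distance-(`min_hamming` - 1) neighborhoods of
#' accepted barcodes, so each candidate is screened in O(1) rather than
#' against the whole accepted set.
#'
#' @param n Number of barcodes requested.
#' @param length Barcode length in nucleotides (default 9).
#' @param min_hamming Minimum pairwise Hamming distance (default 2; only
#'   values 1 and 2 are supported by the neighborhood hash).
#' @param max_homopolymer Longest allowed run of one base (default 3).
#' @param forbidden Character vector of motifs that must not occur.
#' @param seed Integer seed for determinism.
#' @param max_attempts Total candidate budget before giving up.
#' @returns Tibble with `barcode_id` and `sequence`.
#' @export
#' @examples
#' generate_barcodes(8, seed = 1)
generate_barcodes <- function(n, length = 9L, min_hamming = 2L,
                              max_homopolymer = 3L,
                              forbidden = c("GCTAGC", "GGTACC"),
                              seed = NULL, max_attempts = 400L * n) {
  stopifnot(n >= 1L, length >= 1L, min_hamming %in% c(1L, 2L))
  hp_pattern <- paste0(
    "(", paste0(DNA_BASES, "{", max_homopolymer + 1L, ",}", collapse = "|"), ")"
  )
  forbidden <- toupper(forbidden)
  forbidden <- forbidden[nchar(forbidden) <= length]

  with_seed(seed, {
    accepted <- character(n)
    n_acc <- 0L
    attempts <- 0L
    # Hash of every word within Hamming distance (min_hamming - 1) of an
    # accepted barcode; a candidate present here would violate separation.
    blocked <- new.env(hash = TRUE, parent = emptyenv(), size = 32L * n)
    batch <- max(256L, min(4096L, n))

    while (n_acc < n && attempts < max_attempts) {
      take <- min(batch, max_attempts - attempts)
      attempts <- attempts + take
      m <- matrix(sample(DNA_BASES, take * length, replace = TRUE),
                  nrow = take, ncol = length)
      cand <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      keep <- !grepl(hp_pattern, cand)
      for (f in forbidden) keep <- keep & !grepl(f, cand, fixed = TRUE)
      for (s in cand[keep]) {
        if (n_acc >= n) break
        if (exists(s, envir = blocked, inherits = FALSE)) next
        n_acc <- n_acc + 1L
        accepted[n_acc] <- s
        assign(s, TRUE, envir = blocked)
        if (min_hamming >= 2L) {
          for (nb in hamming_neighbors(s)) {
            assign(nb, TRUE, envir = blocked)
          }
        }
      }
    }
    if (n_acc < n) {
      stop(sprintf(
        paste0("barcode constraints unsatisfiable within attempt budget: ",
               "found %d of %d requested (length %d, min Hamming %d)"),
        n_acc, n, length, min_hamming
      ), call. = FALSE)
    }
    tibble::tibble(
      barcode_id = sprintf("BC%0*d", nchar(n), seq_len(n)),
      sequence = accepted
    )
  })
}

# All sequences at Hamming distance exactly 1 from `s`.
hamming_neighbors <- function(s) {
  letters <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(letters)
  out <- character(3L * L)
  idx <- 0L
  for (i in seq_len(L)) {
    for (b in DNA_BASES) {
      if (b != letters[i]) {
        mutated <- letters
        mutated[i] <- b
        idx <- idx + 1L
        out[idx] <- paste(mutated, collapse = "")
      }
    }
  }
  out
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' Exhaustively verifies the separation of an equal-length barcode set. For
#' sets designed at distance >= 2 the check is done via distance-1
#' neighborhood hashing (linear in the set size); the minimum is reported as
#' 2 whenever it is >= 2 (the design constraint of interest), and exactly
#' otherwise (0 for duplicated barcodes, 1 for adjacent ones).
#'
#' @param sequences Character vector of equal-length barcodes.
#' @returns Integer: minimum pairwise Hamming distance, capped at 2.
#' @export
min_hamming_distance <- function(sequences) {
  stopifnot(length(sequences) >= 2L)
  if (anyDuplicated(sequences)) return(0L)
  seen <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * length(sequences))
  for (s in sequences) assign(s, TRUE, envir = seen)
  for (s in sequences) {
    for (nb in hamming_neighbors(s)) {
      if (exists(nb, envir = seen, inherits = FALSE)) return(1L)
    }
  }
  2L
}
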