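#' Reference barcode list for barcode extraction
#'
#' Validates that all barcodes share one length and that every pair is more
#' than `2 * max_mismatch` apart in Hamming distance, which makes mismatch-
#' tolerant assignment unambiguous.
#'
#' @param barcodes Character vector of DNA barcodes of uniform length.
#' @param max_mismatch Maximum Hamming mismatches tolerated per assignment
#'   (default 1; Tn5 tagging does not introduce gaps, so only substitutions
#'   are modeled).
#' @return List of class `barcode_ref` with elements `barcodes`, `length`,
#'   `max_mismatch`.
#' @export
barcode_ref <- function(barcodes, max_mismatch = 1L) {
  stopifnot(length(barcodes) >= 1, max_mismatch >= 0)
  lens <- unique(nchar(barcodes))
  if (length(lens) != 1) abort("all barcodes must share one length")
  if (anyDuplicated(barcodes)) abort("duplicate barcodes")
  mats <- do.call(rbind, strsplit(barcodes, ""))
  if (length(barcodes) > 1) {
    for (i in seq_len(length(barcodes) - 1)) {
      d <- rowSums(mats[(i + 1):length(barcodes), , drop = FALSE] !=
                     matrix(mats[i, ], nrow = length(barcodes) - i,
                            ncol = lens, byrow = TRUE))
      if (any(d <= 2 * max_mismatch)) {
        abort("barcodes closer than 2*max_mismatch; assignment would be ambiguous")
      }
    }
  }
  structure(list(barcodes = barcodes, length = as.integer(lens),
                 max_mismatch = as.integer(max_mismatch)),
            class = "barcode_ref")
}

#' Generate a random barcode list
#'
#' Greedy rejection sampling so that all pairwise Hamming distances exceed
#' `min_dist - 1`.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bp.
#' @param min_dist Minimum pairwise Hamming distance (default 3, compatible
#'   with `max_mismatch = 1`).
#' @param seed Integer seed.
#' @return Character vector of barcodes.
#' @export
make_barcodes <- function(n = 96, length = 8, min_dist = 3, seed) {
  with_seed(as.integer(seed), {
    out <- character(0)
    tries <- 0L
    while (base::length(out) < n) {
      cand <- random_dna(length)
      tries <- tries + 1L
      if (tries > 50000L) abort("could not generate barcode set; relax parameters")
      if (base::length(out) == 0 ||
          all(vapply(out, function(b) hamming(b, cand), numeric(1)) >= min_dist)) {
        out <- c(out, cand)
      }
    }
    out
  })
}
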