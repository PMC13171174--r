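# Grouping aligned duplex reads into original DNA molecules by barcode pair
# and Tn5 cut sites, and recovering the strand of origin of each read.

#' Assign each read to its strand of origin
#'
#' The two strands of a Tn5-tagged molecule present the barcode pair in
#' opposite orientation: mate 1 of a plus-strand pair starts at the leftmost
#' fragment coordinate (so the merged read aligns forward), while mate 1 of a
#' minus-strand pair starts at the rightmost coordinate (merged read aligns
#' reverse). Strand is therefore read off the alignment orientation.
#'
#' @param reads Aligned duplex read tibble (see [read_duplex_bam()]), with a
#'   logical `reverse` column.
#' @return Input tibble with a `strand` column (`"+"` / `"-"`).
#' @export
assign_strand <- function(reads) {
  if (any(is.na(reads$chrom) | is.na(reads$pos))) abort("unmapped")
  reads$strand <- ifelse(reads$reverse, "-", "+")
  reads
}

fragment_bounds <- function(reads) {
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  reads$fragment_start <- reads$pos - 1L          # 0-based
  reads$fragment_end <- reads$pos - 1L + span     # half-open
  reads
}

#' Group aligned reads into single DNA molecules
#'
#' Reads sharing a barcode pair (in either orientation) and the same Tn5 cut
#' sites (fragment endpoints, within `cutsite_tolerance`) form one molecule.
#' Reads with the same barcode pair but incompatible fragment coordinates are
#' split into distinct molecules, all flagged `cutsite_consistent = FALSE` —
#' the barcode-collision signature consumed by [filter_cutsite()]. Reads below
#' `min_mapq` are dropped before grouping.
#'
#' @param reads Aligned duplex read tibble with columns `read_id`, `chrom`,
#'   `pos`, `cigar`, `mapq`, `reverse`, `bc1`, `bc2`.
#' @param cutsite_tolerance Maximum endpoint difference (bp) treated as the
#'   same cut site (default 0; Tn5 cuts are exact).
#' @param min_mapq Minimum mapping quality (default 30).
#' @return Input tibble (filtered) with added columns `strand`,
#'   `fragment_start`, `fragment_end`, `bc_lo`, `bc_hi`, `molecule_id`,
#'   `cutsite_consistent`.
#' @export
group_molecules <- function(reads, cutsite_tolerance = 0L, min_mapq = 30L) {
  stopifnot(cutsite_tolerance >= 0)
  reads <- as_tibble(reads)
  reads <- dplyr::filter(reads, .data$mapq >= min_mapq)
  reads <- assign_strand(fragment_bounds(reads))
  reads$bc_lo <- pmin(reads$bc1, reads$bc2)
  reads$bc_hi <- pmax(reads$bc1, reads$bc2)
  reads <- dplyr::arrange(reads, .data$chrom, .data$fragment_start,
                          .data$fragment_end, .data$read_id)
  grouped <- reads |>
    group_by(.data$chrom, .data$bc_lo, .data$bc_hi) |>
    mutate(.frag_cluster = cluster_fragments(
      .data$fragment_start, .data$fragment_end, cutsite_tolerance)) |>
    ungroup()
  # representative coordinates per (chrom, pair, cluster)
  grouped <- grouped |>
    group_by(.data$chrom, .data$bc_lo, .data$bc_hi, .data$.frag_cluster) |>
    mutate(molecule_id = paste0(.data$chrom[1], ":", .data$bc_lo[1], "+",
                                .data$bc_hi[1], ":", min(.data$fragment_start),
                                "-", max(.data$fragment_end))) |>
    ungroup()
  # a barcode pair mapping to >1 molecule anywhere in the genome is a collision
  collided <- grouped |>
    distinct(.data$bc_lo, .data$bc_hi, .data$molecule_id) |>
    count(.data$bc_lo, .data$bc_hi, name = ".n_mol") |>
    dplyr::filter(.data$.n_mol > 1)
  grouped$cutsite_consistent <- !paste(grouped$bc_lo, grouped$bc_hi) %in%
    paste(collided$bc_lo, collided$bc_hi)
  grouped$.frag_cluster <- NULL
  grouped
}

# single-linkage clustering of fragment intervals: consecutive (sorted)
# fragments join one cluster when both endpoints agree within tol
cluster_fragments <- function(starts, ends, tol) {
  n <- length(starts)
  if (n == 1) return(1L)
  cl <- integer(n)
  cl[1] <- 1L
  for (i in 2:n) {
    same <- abs(starts[i] - starts[i - 1]) <= tol &&
      abs(ends[i] - ends[i - 1]) <= tol
    cl[i] <- if (same) cl[i - 1] else cl[i - 1] + 1L
  }
  cl
}

#' Summarise grouped reads at the molecule level
#'
#' @param grouped Output of [group_molecules()].
#' @return One row per molecule: key fields, per-strand read counts, and
#'   `cutsite_consistent`.
#' @export
summarise_molecules <- function(grouped) {
  grouped |>
    group_by(.data$molecule_id) |>
    summarise(
      chrom = .data$chrom[1],
      bc_lo = .data$bc_lo[1],
      bc_hi = .data$bc_hi[1],
      fragment_start = min(.data$fragment_start),
      fragment_end = max(.data$fragment_end),
      n_reads = dplyr::n(),
      n_plus = sum(.data$strand == "+"),
      n_minus = sum(.data$strand == "-"),
      cutsite_consistent = all(.data$cutsite_consistent),
      .groups = "drop"
    )
}
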