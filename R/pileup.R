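# Per-position, per-strand pileup of duplex reads; indel observation
# extraction from alignments; strand-aware candidate generation.

#' Extract indel observations from aligned reads
#'
#' Walks the alignment operations of each read (no local realignment — the
#' aligner's gaps are taken as-is) and emits one observation per insertion or
#' deletion, left-normalized against the reference so that equivalent
#' representations from different reads coincide. An observation passes the
#' base-quality gate when the anchor base and the first base after the event
#' both have quality >= `min_bq` on the read.
#'
#' @param reads Aligned read tibble (columns `read_id`, `chrom`, `pos`,
#'   `cigar`, `seq`, `qual`).
#' @param reference Reference genome (see [as_reference()]).
#' @param min_bq Minimum flanking base quality (default 20).
#' @return Tibble with one row per observation: `read_id`, `chrom`, `pos`
#'   (anchor), `ref`, `alt`, `kind`, `length`, `bq_ok`.
#' @export
indel_observations <- function(reads, reference, min_bq = 20L) {
  reference <- as_reference(reference)
  reads <- as_tibble(reads)
  has_indel <- str_detect(reads$cigar, "[ID]")
  sub <- reads[has_indel, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble(read_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), kind = character(),
                  length = integer(), bq_ok = logical()))
  }
  ops_l <- GenomicAlignments::explodeCigarOps(sub$cigar)
  len_l <- GenomicAlignments::explodeCigarOpLengths(sub$cigar)
  rows <- map(seq_len(nrow(sub)), function(i) {
    ops <- ops_l[[i]]; lens <- len_l[[i]]
    contig <- reference[[sub$chrom[i]]]
    qv <- phred_ints(sub$qual[i])
    r <- sub$pos[i]  # next reference position to consume
    q <- 1L          # next read position to consume
    out <- list()
    for (j in seq_along(ops)) {
      op <- ops[j]; l <- lens[j]
      if (op %in% c("M", "=", "X")) {
        r <- r + l; q <- q + l
      } else if (op == "S") {
        q <- q + l
      } else if (op == "I") {
        anchor <- r - 1L
        if (anchor >= sub$pos[i]) {
          ins <- substr(sub$seq[i], q, q + l - 1L)
          bq_ok <- q > 1L && q + l <= nchar(sub$seq[i]) &&
            qv[q - 1L] >= min_bq && qv[q + l] >= min_bq
          out[[length(out) + 1L]] <- list(
            pos = anchor, ref = substr(contig, anchor, anchor),
            alt = paste0(substr(contig, anchor, anchor), ins), bq_ok = bq_ok)
        }
        q <- q + l
      } else if (op == "D") {
        anchor <- r - 1L
        if (anchor >= sub$pos[i]) {
          bq_ok <- q > 1L && q <= nchar(sub$seq[i]) &&
            qv[q - 1L] >= min_bq && qv[q] >= min_bq
          out[[length(out) + 1L]] <- list(
            pos = anchor, ref = substr(contig, anchor, anchor + l),
            alt = substr(contig, anchor, anchor), bq_ok = bq_ok)
        }
        r <- r + l
      } else if (op %in% c("N", "H", "P")) {
        if (op == "N") r <- r + l
      }
    }
    if (length(out) == 0) return(NULL)
    tibble(read_id = sub$read_id[i], chrom = sub$chrom[i],
           pos = map_int(out, function(x) as.integer(x$pos)),
           ref = map_chr(out, "ref"), alt = map_chr(out, "alt"),
           bq_ok = map_lgl(out, "bq_ok"))
  })
  obs <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  normalize_indels(obs, reference)
}

#' Strand-aware duplex pileup columns
#'
#' Counts, per genomic position and strand, the reads covering the position,
#' those supporting the reference, and those supporting each indel allele
#' anchored there. Reads below `min_mapq` and observations failing the
#' flanking base-quality gate are excluded.
#'
#' @param reads Aligned read tibble; run through [group_molecules()] first if
#'   strand columns are not yet present.
#' @param reference Reference genome.
#' @param chrom,start,end Optional region restriction (1-based inclusive).
#' @param min_mapq,min_bq Quality cutoffs.
#' @return List of two tibbles: `columns` (per position: `chrom`, `pos`,
#'   `depth`, `n_ref_plus`, `n_ref_minus`) and `alleles` (per indel allele:
#'   `chrom`, `pos`, `ref`, `alt`, `n_alt_plus`, `n_alt_minus`).
#' @export
pileup_columns <- function(reads, reference, chrom = NULL, start = NULL,
                           end = NULL, min_mapq = 30L, min_bq = 20L) {
  reference <- as_reference(reference)
  reads <- as_tibble(reads)
  reads <- dplyr::filter(reads, .data$mapq >= min_mapq)
  if (!"strand" %in% names(reads)) reads <- assign_strand(reads)
  if (!"fragment_start" %in% names(reads)) reads <- fragment_bounds(reads)
  if (!is.null(chrom)) {
    reads <- dplyr::filter(reads, .data$chrom == !!chrom)
    if (!chrom %in% names(reference)) abort("region outside reference")
    if (!is.null(end) && end > nchar(reference[[chrom]])) {
      abort("region outside reference")
    }
  }
  obs <- indel_observations(reads, reference, min_bq = min_bq)
  obs <- dplyr::filter(obs, .data$bq_ok)
  obs <- dplyr::inner_join(obs, dplyr::select(reads, "read_id", "strand"),
                           by = "read_id")
  cols <- map(split(reads, reads$chrom), function(rr) {
    cov_p <- IRanges::coverage(IRanges::IRanges(
      rr$fragment_start[rr$strand == "+"] + 1L, rr$fragment_end[rr$strand == "+"]))
    cov_m <- IRanges::coverage(IRanges::IRanges(
      rr$fragment_start[rr$strand == "-"] + 1L, rr$fragment_end[rr$strand == "-"]))
    n <- max(length(cov_p), length(cov_m))
    vp <- as.integer(cov_p); vm <- as.integer(cov_m)
    vp <- c(vp, integer(n - length(vp))); vm <- c(vm, integer(n - length(vm)))
    covered <- which(vp + vm > 0L)
    tibble(chrom = rr$chrom[1], pos = covered,
           cov_plus = vp[covered], cov_minus = vm[covered])
  }) |> list_rbind()
  if (!is.null(start)) cols <- dplyr::filter(cols, .data$pos >= start)
  if (!is.null(end)) cols <- dplyr::filter(cols, .data$pos <= end)
  obs_at <- obs |>
    count(.data$chrom, .data$pos, .data$strand) |>
    tidyr::pivot_wider(names_from = "strand", values_from = "n",
                       values_fill = 0L, names_prefix = "obs_")
  for (nm in c("obs_+", "obs_-")) if (!nm %in% names(obs_at)) obs_at[[nm]] <- 0L
  cols <- dplyr::left_join(cols, obs_at, by = c("chrom", "pos")) |>
    mutate(`obs_+` = dplyr::coalesce(.data$`obs_+`, 0L),
           `obs_-` = dplyr::coalesce(.data$`obs_-`, 0L),
           depth = .data$cov_plus + .data$cov_minus,
           n_ref_plus = .data$cov_plus - .data$`obs_+`,
           n_ref_minus = .data$cov_minus - .data$`obs_-`) |>
    dplyr::select("chrom", "pos", "depth", "n_ref_plus", "n_ref_minus")
  alleles <- obs |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(n_alt_plus = sum(.data$strand == "+"),
              n_alt_minus = sum(.data$strand == "-"), .groups = "drop")
  if (!is.null(start)) alleles <- dplyr::filter(alleles, .data$pos >= start)
  if (!is.null(end)) alleles <- dplyr::filter(alleles, .data$pos <= end)
  list(columns = cols, alleles = alleles)
}

#' Strand-aware calling threshold
#'
#' The `aXsY` threshold of duplex consensus calling: `a` is the minimum total
#' number of alternative-allele reads and `s` the minimum number required on
#' each strand for a double-stranded (consensus) call. The default `a4s2`
#' requires four supporting reads in total with two on each strand.
#'
#' @param a Minimum total alternative reads (`a >= 2 s`).
#' @param s Minimum per-strand alternative reads (`s >= 1`).
#' @return List of class `call_threshold`.
#' @export
call_threshold <- function(a = 4L, s = 2L) {
  a <- as.integer(a); s <- as.integer(s)
  if (s < 1L || a < 2L * s) abort("need a >= 2*s >= 2 for double-strand calling")
  structure(list(a = a, s = s), class = "call_threshold")
}

#' @export
format.call_threshold <- function(x, ...) sprintf("a%ds%d", x$a, x$s)

#' @export
print.call_threshold <- function(x, ...) {
  cat("duplex calling threshold", format(x), "\n")
  invisible(x)
}

#' Generate per-molecule indel candidates under an aXsY threshold
#'
#' One candidate is emitted per (molecule, normalized allele) reaching `a`
#' total supporting reads. The complementarity check sets `strandedness`:
#' `DOUBLE` when both strands reach `s` supporting reads, `SINGLE` otherwise
#' (the variant is only present, or only sufficiently supported, on one
#' strand). Candidates on sex chromosomes are excluded; when a genome mask is
#' supplied, candidates outside it are labeled `masked`.
#'
#' @param grouped Output of [group_molecules()].
#' @param observations Output of [indel_observations()] on the same reads
#'   (recomputed internally when `NULL`).
#' @param reference Reference genome.
#' @param threshold A [call_threshold()].
#' @param mask Optional `GRanges` of high-confidence regions.
#' @param exclude_sex Drop sex-chromosome candidates (default TRUE).
#' @param min_bq Flanking base-quality cutoff for supporting observations.
#' @return Candidate tibble: allele fields, `molecule_id`, `n_total`,
#'   `n_plus`, `n_minus`, `strandedness`, `filters` (empty string = pass so
#'   far).
#' @export
call_candidates <- function(grouped, observations = NULL, reference,
                            threshold = call_threshold(4, 2), mask = NULL,
                            exclude_sex = TRUE, min_bq = 20L) {
  stopifnot(inherits(threshold, "call_threshold"))
  if (is.null(observations)) {
    observations <- indel_observations(grouped, reference, min_bq = min_bq)
  }
  obs <- dplyr::filter(observations, .data$bq_ok)
  obs <- dplyr::inner_join(
    obs, dplyr::select(grouped, "read_id", "molecule_id", "strand"),
    by = "read_id")
  cands <- obs |>
    group_by(.data$molecule_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$kind, .data$length) |>
    summarise(n_plus = sum(.data$strand == "+"),
              n_minus = sum(.data$strand == "-"), .groups = "drop") |>
    mutate(n_total = .data$n_plus + .data$n_minus) |>
    dplyr::filter(.data$n_total >= threshold$a) |>
    mutate(strandedness = ifelse(
      .data$n_plus >= threshold$s & .data$n_minus >= threshold$s,
      "DOUBLE", "SINGLE"))
  if (exclude_sex) cands <- dplyr::filter(cands, !is_sex_chrom(.data$chrom))
  cands$filters <- ""
  if (!is.null(mask) && nrow(cands) > 0) {
    gr <- GenomicRanges::GRanges(cands$chrom,
                                 IRanges::IRanges(cands$pos, cands$pos))
    inside <- IRanges::overlapsAny(gr, mask)
    cands <- add_filter_label(cands, !inside, "masked")
  }
  arrange(cands, .data$chrom, .data$pos, .data$ref, .data$alt,
          .data$molecule_id)
}

add_filter_label <- function(cands, hit, label) {
  hit[is.na(hit)] <- FALSE
  cands$filters <- ifelse(
    hit,
    ifelse(cands$filters == "", label, paste(cands$filters, label, sep = ";")),
    cands$filters)
  cands
}
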