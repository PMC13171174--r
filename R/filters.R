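# Artifact and germline filter stack. Every filter is tibble-in / tibble-out,
# appends a label to the candidate's `filters` column and never removes rows,
# so the filters commute and the final label set is order-independent.

#' Filter configuration
#'
#' @param enabled Character vector of enabled filters, a subset of
#'   `c("germline", "merge_confound", "adjacent_germline", "cutsite",
#'   "population_af")`. All are enabled by default; each is skipped gracefully
#'   when its evidence (bulk pileup, AF table, ...) is not supplied to
#'   [run_pipeline()].
#' @param germline_min_bulk_depth Minimum bulk depth below which a candidate is
#'   conservatively removed as `low_bulk_depth` (default 10).
#' @param adjacency_window Window in bp around a candidate within which a
#'   distinct germline indel triggers `near_germline` (default 10).
#' @param af_cutoff Population allele-frequency cutoff for `common_variant`
#'   (default 0.01, i.e. >= 1%).
#' @param require_cutsite_consistency Label candidates from barcode-collision
#'   molecules (default TRUE).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(enabled = c("germline", "merge_confound",
                                      "adjacent_germline", "cutsite",
                                      "population_af"),
                          germline_min_bulk_depth = 10L,
                          adjacency_window = 10L,
                          af_cutoff = 0.01,
                          require_cutsite_consistency = TRUE) {
  stopifnot(adjacency_window >= 0, af_cutoff >= 0, af_cutoff <= 1)
  structure(list(enabled = enabled,
                 germline_min_bulk_depth = as.integer(germline_min_bulk_depth),
                 adjacency_window = as.integer(adjacency_window),
                 af_cutoff = af_cutoff,
                 require_cutsite_consistency = require_cutsite_consistency),
            class = "filter_config")
}

#' Bulk WGS evidence table
#'
#' Per normalized allele: bulk depth and alternative-read count at the site.
#' Positions absent from the table are assumed to have `default_depth`
#' coverage and zero alternative reads.
#'
#' @param tbl Tibble with columns `chrom`, `pos`, `ref`, `alt`, `bulk_depth`,
#'   `bulk_alt`.
#' @param default_depth Depth assumed at unlisted positions (default 30).
#' @return The tibble with class `bulk_evidence` and a `default_depth`
#'   attribute.
#' @export
bulk_evidence <- function(tbl, default_depth = 30L) {
  tbl <- as_tibble(tbl)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "bulk_depth", "bulk_alt")
                %in% names(tbl)),
            all(tbl$bulk_alt <= tbl$bulk_depth), all(tbl$bulk_alt >= 0))
  attr(tbl, "default_depth") <- as.integer(default_depth)
  class(tbl) <- c("bulk_evidence", class(tbl))
  tbl
}

bulk_lookup <- function(cands, bulk) {
  dflt <- attr(bulk, "default_depth") %||% 30L
  m <- dplyr::left_join(
    dplyr::select(cands, "chrom", "pos", "ref", "alt"),
    dplyr::select(as_tibble(bulk), "chrom", "pos", "ref", "alt",
                  "bulk_depth", "bulk_alt"),
    by = c("chrom", "pos", "ref", "alt"))
  # depth at the position even when the exact allele is absent from the table
  if (nrow(bulk) > 0) {
    pos_depth <- as_tibble(bulk) |>
      group_by(.data$chrom, .data$pos) |>
      summarise(.pos_depth = max(.data$bulk_depth), .groups = "drop")
    m <- dplyr::left_join(m, pos_depth, by = c("chrom", "pos"))
  } else {
    m$.pos_depth <- NA_integer_
  }
  m$bulk_alt <- dplyr::coalesce(m$bulk_alt, 0L)
  m$bulk_depth <- dplyr::coalesce(m$bulk_depth, m$.pos_depth, dflt)
  m
}

#' Germline filter
#'
#' Labels a candidate `germline` when the same normalized allele has any
#' supporting read in the matched bulk WGS data, and `low_bulk_depth` when the
#' bulk lacks the depth (`< germline_min_bulk_depth`) to rule germline status
#' out — such sites are conservatively removed rather than passed.
#'
#' @param cands Candidate tibble ([call_candidates()]).
#' @param bulk A [bulk_evidence()] table over alleles normalized the same way.
#' @param cfg A [filter_config()].
#' @return Candidates with labels appended to `filters`.
#' @export
filter_germline <- function(cands, bulk, cfg = filter_config()) {
  if (nrow(cands) == 0) return(cands)
  m <- bulk_lookup(cands, bulk)
  cands <- add_filter_label(cands, m$bulk_alt >= 1L, "germline")
  cands <- add_filter_label(cands, m$bulk_alt < 1L &
                              m$bulk_depth < cfg$germline_min_bulk_depth,
                            "low_bulk_depth")
  cands
}

#' Germline indel set from bulk evidence
#'
#' The "difficult region" anchors used by [filter_adjacent_germline()]: bulk
#' alleles with at least `min_alt` supporting reads or VAF of at least
#' `min_vaf`, so that single-read bulk noise does not define a difficult
#' region.
#'
#' @param bulk A [bulk_evidence()] table.
#' @param min_alt,min_vaf Evidence thresholds (defaults 2 reads / VAF 0.2).
#' @return Tibble of germline alleles (`chrom`, `pos`, `ref`, `alt`).
#' @export
germline_set <- function(bulk, min_alt = 2L, min_vaf = 0.2) {
  as_tibble(bulk) |>
    dplyr::filter(.data$bulk_alt >= min_alt |
                    (.data$bulk_depth > 0 &
                       .data$bulk_alt / .data$bulk_depth >= min_vaf)) |>
    dplyr::select("chrom", "pos", "ref", "alt")
}

#' Adjacent-germline filter
#'
#' Mapping errors concentrate around germline indels; a candidate within
#' `window` bp of a *distinct* germline indel allele is labeled
#' `near_germline` (the identical allele is the germline filter's job).
#'
#' @param cands Candidate tibble.
#' @param germline_indels Tibble of germline indel alleles
#'   (see [germline_set()]).
#' @param window Distance in bp (default from `cfg`).
#' @param cfg A [filter_config()].
#' @return Candidates with labels appended.
#' @export
filter_adjacent_germline <- function(cands, germline_indels,
                                     window = cfg$adjacency_window,
                                     cfg = filter_config()) {
  if (nrow(cands) == 0 || nrow(germline_indels) == 0) return(cands)
  hit <- vapply(seq_len(nrow(cands)), function(i) {
    g <- germline_indels[germline_indels$chrom == cands$chrom[i] &
                           abs(germline_indels$pos - cands$pos[i]) <= window, ]
    any(!(g$pos == cands$pos[i] & g$ref == cands$ref[i] & g$alt == cands$alt[i]))
  }, logical(1))
  add_filter_label(cands, hit, "near_germline")
}

#' Tn5 cut-site consistency filter
#'
#' Labels candidates from molecules whose barcode pair was seen with more than
#' one fragment interval (barcode collision) as `cutsite_inconsistent`.
#'
#' @param cands Candidate tibble.
#' @param molecules Output of [summarise_molecules()] (or grouped reads).
#' @return Candidates with labels appended.
#' @export
filter_cutsite <- function(cands, molecules) {
  if (nrow(cands) == 0) return(cands)
  mol <- distinct(as_tibble(molecules), .data$molecule_id,
                  .data$cutsite_consistent)
  m <- dplyr::left_join(dplyr::select(cands, "molecule_id"), mol,
                        by = "molecule_id")
  add_filter_label(cands, !m$cutsite_consistent, "cutsite_inconsistent")
}

#' Population allele-frequency filter
#'
#' Labels candidates whose normalized allele has population allele frequency
#' of at least `af_cutoff` (default 1%) in the supplied table (gnomAD-style)
#' as `common_variant`. Alleles absent from the table are treated as AF 0.
#'
#' @param cands Candidate tibble.
#' @param af_table Tibble with `chrom`, `pos`, `ref`, `alt`, `af`.
#' @param af_cutoff Frequency cutoff (default from `cfg`).
#' @param cfg A [filter_config()].
#' @return Candidates with labels appended.
#' @export
filter_population_af <- function(cands, af_table, af_cutoff = cfg$af_cutoff,
                                 cfg = filter_config()) {
  if (nrow(cands) == 0) return(cands)
  m <- dplyr::left_join(
    dplyr::select(cands, "chrom", "pos", "ref", "alt"),
    dplyr::select(as_tibble(af_table), "chrom", "pos", "ref", "alt", "af"),
    by = c("chrom", "pos", "ref", "alt"))
  af <- dplyr::coalesce(m$af, 0)
  add_filter_label(cands, af >= af_cutoff, "common_variant")
}

#' Merge-confound filter
#'
#' Read-pair merging at a wrong offset in tandem-repeat or microhomology
#' context fabricates indels. A candidate is labeled `merge_confound` when
#' (a) every supporting read places the indel inside its merged-overlap
#' interval *and* at least one supporting read's merge was ambiguous, or
#' (b) the indel's repeat tract (unit <= 6 bp, tract >= 12 bp) spans a merge
#' boundary of a supporting read. Candidates whose supporting reads lack merge
#' metadata are labeled `not_evaluable` and pass with a warning.
#'
#' @param cands Candidate tibble.
#' @param grouped Grouped reads ([group_molecules()]) with merge metadata
#'   columns `merged`, `overlap_start`, `overlap_end`, `ambiguous`.
#' @param observations Indel observations linking reads to alleles.
#' @param reference Reference genome.
#' @return Candidates with labels appended.
#' @export
filter_merge_confound <- function(cands, grouped, observations, reference) {
  if (nrow(cands) == 0) return(cands)
  reference <- as_reference(reference)
  has_meta <- all(c("merged", "overlap_start", "overlap_end", "ambiguous")
                  %in% names(grouped))
  if (!has_meta) {
    warn("merge metadata missing; merge-confound filter not evaluable")
    return(add_filter_label(cands, rep(TRUE, nrow(cands)), "not_evaluable"))
  }
  obs <- dplyr::inner_join(
    dplyr::filter(observations, .data$bq_ok),
    dplyr::select(grouped, "read_id", "molecule_id", "merged",
                  "overlap_start", "overlap_end", "ambiguous"),
    by = "read_id")
  labels <- vapply(seq_len(nrow(cands)), function(i) {
    sup <- obs[obs$molecule_id == cands$molecule_id[i] &
                 obs$chrom == cands$chrom[i] & obs$pos == cands$pos[i] &
                 obs$ref == cands$ref[i] & obs$alt == cands$alt[i], ]
    if (nrow(sup) == 0) return("")
    if (anyNA(sup$merged)) return("not_evaluable")
    in_overlap <- sup$merged & !is.na(sup$overlap_start) &
      cands$pos[i] >= sup$overlap_start & cands$pos[i] <= sup$overlap_end
    rule_a <- all(in_overlap) && any(sup$ambiguous)
    tract <- repeat_tract(reference, cands$chrom[i], cands$pos[i])
    rule_b <- FALSE
    if (!is.null(tract) && tract$len >= 12L) {
      bounds <- c(sup$overlap_start[sup$merged], sup$overlap_end[sup$merged])
      bounds <- bounds[!is.na(bounds)]
      rule_b <- any(bounds >= tract$start & bounds <= tract$end)
    }
    if (rule_a || rule_b) "merge_confound" else ""
  }, character(1))
  if (any(labels == "not_evaluable")) {
    warn("some candidates lack merge metadata; labeled not_evaluable (passing)")
  }
  cands <- add_filter_label(cands, labels == "merge_confound", "merge_confound")
  add_filter_label(cands, labels == "not_evaluable", "not_evaluable")
}

# longest tandem tract (unit length 1..max_unit, >= 2 copies) containing a
# 1-based position; returns NULL when the position sits in no tract
repeat_tract <- function(reference, chrom, pos, max_unit = 6L) {
  contig <- reference[[chrom]]
  n <- nchar(contig)
  best <- NULL
  for (u in seq_len(max_unit)) {
    # scan candidate tract phases covering pos
    lo <- max(1L, pos - 30L)
    for (anchor in max(lo, pos - u + 1L):pos) {
      unit <- substr(contig, anchor, anchor + u - 1L)
      if (nchar(unit) < u) next
      k_right <- count_unit_copies(contig, anchor, unit)
      # extend leftwards
      start <- anchor
      while (start - u >= 1L &&
             substr(contig, start - u, start - 1L) == unit) {
        start <- start - u
        k_right <- k_right + 1L
      }
      if (k_right >= 2L) {
        len <- k_right * u
        end <- start + len - 1L
        if (pos >= start && pos <= end &&
            (is.null(best) || len > best$len)) {
          best <- list(start = start, end = end, len = len, unit = unit)
        }
      }
    }
  }
  best
}

#' Finalize somatic calls
#'
#' Sorts each candidate's filter labels (order independence), assigns the VCF
#' `FILTER` string, splits calls into the double-strand track and the
#' single-strand track (`SINGLE_STRAND`; such calls are emitted but never
#' PASS), and marks PASS records: empty filter set and `DOUBLE` strandedness.
#' The advisory `not_evaluable` label does not block PASS.
#'
#' @param cands Candidate tibble after filtering.
#' @param cfg A [filter_config()].
#' @return Tibble of class `somatic_calls` with `FILTER`, `track`, `pass`
#'   columns, sorted by position.
#' @export
finalize_calls <- function(cands, cfg = filter_config()) {
  cands <- as_tibble(cands)
  sort_labels <- function(f) {
    if (f == "") return("")
    lab <- sort(unique(strsplit(f, ";")[[1]]))
    lab <- lab[order(match(lab, FILTER_ORDER))]
    paste(lab, collapse = ";")
  }
  cands$filters <- vapply(cands$filters, sort_labels, character(1),
                          USE.NAMES = FALSE)
  blocking <- vapply(cands$filters, function(f) {
    lab <- setdiff(strsplit(f, ";")[[1]], "not_evaluable")
    length(lab) > 0
  }, logical(1), USE.NAMES = FALSE)
  cands$FILTER <- ifelse(blocking, cands$filters, "PASS")
  cands$track <- ifelse(cands$strandedness == "DOUBLE", "DOUBLE",
                        "SINGLE_STRAND")
  cands$pass <- !blocking & cands$track == "DOUBLE"
  out <- arrange(cands, .data$chrom, .data$pos, .data$ref, .data$alt,
                 .data$molecule_id)
  class(out) <- c("somatic_calls", class(out))
  out
}
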