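# End-to-end orchestration: grouping, pileup, candidate generation, filter
# stack, finalization, reporting.

#' Run the duplex indel-calling pipeline
#'
#' Orchestrates the full caller on aligned duplex reads: molecule grouping by
#' barcode pair and Tn5 cut sites, per-molecule strand-aware candidate
#' generation under the aXsY threshold, the artifact/germline filter stack,
#' and call finalization. Deterministic given its inputs. Inputs may be
#' in-memory objects (tibbles, named character reference) or file paths (BAM,
#' FASTA, TSV, BED), which are read with the package's readers.
#'
#' @param reads Aligned duplex read tibble or BAM path (tag contract of
#'   [write_sam()]).
#' @param reference Reference genome (named character vector, `DNAStringSet`,
#'   or FASTA path).
#' @param bulk Optional [bulk_evidence()] table or TSV path (enables the
#'   germline and adjacent-germline filters).
#' @param af_table Optional population-AF tibble or TSV path.
#' @param mask Optional `GRanges` or BED path of high-confidence regions.
#' @param threshold A [call_threshold()] (default a4s2).
#' @param filters A [filter_config()].
#' @param min_mapq,min_bq,cutsite_tolerance Upstream quality/grouping knobs.
#' @param exclude_sex Drop sex-chromosome candidates (default TRUE).
#' @param output_dir Optional directory; when given, the final VCF
#'   (`somatic.vcf` + `somatic.single_strand.vcf`), the intermediate candidate
#'   VCF (`candidates.vcf`) and the run report (`report.tsv`) are written.
#' @return Object of class `duplex_run`: list with `calls`
#'   ([finalize_calls()] output), `candidates`, `molecules`, `grouped` reads,
#'   `report` (per-filter removal counts), `threshold`, `config`.
#' @export
run_pipeline <- function(reads, reference, bulk = NULL, af_table = NULL,
                         mask = NULL, threshold = call_threshold(4, 2),
                         filters = filter_config(), min_mapq = 30L,
                         min_bq = 20L, cutsite_tolerance = 0L,
                         exclude_sex = TRUE, output_dir = NULL) {
  if (is.character(reads)) reads <- read_duplex_bam(reads)
  reference <- as_reference(reference)
  if (is.character(bulk)) bulk <- read_bulk_table(bulk)
  if (is.character(af_table)) af_table <- read_af_table(af_table)
  if (is.character(mask)) mask <- read_genome_mask(mask)

  grouped <- group_molecules(reads, cutsite_tolerance = cutsite_tolerance,
                             min_mapq = min_mapq)
  molecules <- summarise_molecules(grouped)
  observations <- indel_observations(grouped, reference, min_bq = min_bq)
  candidates <- call_candidates(grouped, observations, reference,
                                threshold = threshold, mask = mask,
                                exclude_sex = exclude_sex, min_bq = min_bq)
  cands <- candidates
  on <- function(f) f %in% filters$enabled
  if (on("germline") && !is.null(bulk)) {
    cands <- filter_germline(cands, bulk, filters)
  }
  if (on("adjacent_germline") && !is.null(bulk)) {
    cands <- filter_adjacent_germline(cands, germline_set(bulk),
                                      window = filters$adjacency_window)
  }
  if (on("merge_confound")) {
    cands <- filter_merge_confound(cands, grouped, observations, reference)
  }
  if (on("cutsite") && filters$require_cutsite_consistency) {
    cands <- filter_cutsite(cands, molecules)
  }
  if (on("population_af") && !is.null(af_table)) {
    cands <- filter_population_af(cands, af_table,
                                  af_cutoff = filters$af_cutoff)
  }
  calls <- finalize_calls(cands, filters)
  report <- run_report(calls, molecules)
  run <- structure(list(calls = calls, candidates = candidates,
                        molecules = molecules, grouped = grouped,
                        report = report, threshold = threshold,
                        config = filters),
                   class = "duplex_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_somatic_vcf(calls, reference, file.path(output_dir, "somatic.vcf"),
                      threshold)
    write_somatic_vcf(candidates, reference,
                      file.path(output_dir, "candidates.vcf"), threshold)
    readr::write_tsv(report, file.path(output_dir, "report.tsv"))
  }
  run
}

# per-filter removal counts; every candidate is attributed once, to its first
# label in the fixed order, plus a multi-label tally
run_report <- function(calls, molecules) {
  first_label <- vapply(calls$filters, function(f) {
    lab <- setdiff(strsplit(f, ";")[[1]], "not_evaluable")
    if (length(lab) == 0) return("PASS_OR_SINGLE")
    lab[which.min(match(lab, FILTER_ORDER))]
  }, character(1), USE.NAMES = FALSE)
  n_labels <- vapply(calls$filters, function(f) {
    length(setdiff(strsplit(f, ";")[[1]], "not_evaluable"))
  }, integer(1), USE.NAMES = FALSE)
  counts <- table(factor(first_label, levels = c(FILTER_ORDER,
                                                 "PASS_OR_SINGLE")))
  tibble(
    metric = c("n_molecules", "n_molecules_collided", "n_candidates",
               "n_double", "n_single", "n_pass",
               paste0("filtered_", FILTER_ORDER), "multi_label"),
    value = c(nrow(molecules), sum(!molecules$cutsite_consistent),
              nrow(calls),
              sum(calls$track == "DOUBLE"),
              sum(calls$track == "SINGLE_STRAND"),
              sum(calls$pass),
              as.integer(counts[FILTER_ORDER]),
              sum(n_labels > 1))
  )
}

#' @export
print.duplex_run <- function(x, ...) {
  cat("duplex indel-calling run (", format(x$threshold), ")\n", sep = "")
  cat("  molecules:  ", nrow(x$molecules), "\n")
  cat("  candidates: ", nrow(x$calls), "\n")
  cat("  PASS calls: ", sum(x$calls$pass), "\n")
  cat("  single-strand track: ", sum(x$calls$track == "SINGLE_STRAND"), "\n")
  invisible(x)
}

#' Tidy a duplex run into its call table
#'
#' @param x A `duplex_run`.
#' @param ... Unused.
#' @return The finalized calls tibble (one row per molecule-level candidate,
#'   with `FILTER`, `track`, `pass`).
#' @exportS3Method generics::tidy
#' @export
tidy.duplex_run <- function(x, ...) as_tibble(x$calls)

#' One-row summary of a duplex run
#'
#' @param x A `duplex_run`.
#' @param ... Unused.
#' @return One-row tibble: threshold, molecule / candidate / call counts.
#' @exportS3Method generics::glance
#' @export
glance.duplex_run <- function(x, ...) {
  tibble(
    threshold = format(x$threshold),
    n_molecules = nrow(x$molecules),
    n_candidates = nrow(x$calls),
    n_double = sum(x$calls$track == "DOUBLE"),
    n_single = sum(x$calls$track == "SINGLE_STRAND"),
    n_pass = sum(x$calls$pass),
    n_filtered = sum(!x$calls$pass & x$calls$track == "DOUBLE")
  )
}

#' Sweep calling thresholds over one dataset
#'
#' Re-runs candidate generation and filtering under each threshold; with
#' rising thresholds the PASS sets are nested and call counts non-increasing
#' (the filters only consume per-molecule support counts, which do not depend
#' on the threshold).
#'
#' @param reads,reference,bulk,af_table,mask,filters As in [run_pipeline()].
#' @param thresholds List of [call_threshold()]s.
#' @param ... Passed to [run_pipeline()].
#' @return Tibble with one row per threshold: `a`, `s`, `n_pass`, `n_double`,
#'   `n_single`, and `pass_keys` (list-column of PASS allele/molecule keys).
#' @export
sweep_thresholds <- function(reads, reference,
                             thresholds = list(call_threshold(4, 2),
                                               call_threshold(6, 3),
                                               call_threshold(8, 4),
                                               call_threshold(10, 5)),
                             bulk = NULL, af_table = NULL, mask = NULL,
                             filters = filter_config(), ...) {
  if (is.character(reads)) reads <- read_duplex_bam(reads)
  runs <- map(thresholds, function(th) {
    run_pipeline(reads, reference, bulk = bulk, af_table = af_table,
                 mask = mask, threshold = th, filters = filters, ...)
  })
  tibble(
    a = map_int(thresholds, "a"),
    s = map_int(thresholds, "s"),
    n_pass = map_int(runs, function(r) sum(r$calls$pass)),
    n_double = map_int(runs, function(r) sum(r$calls$track == "DOUBLE")),
    n_single = map_int(runs, function(r) sum(r$calls$track == "SINGLE_STRAND")),
    pass_keys = map(runs, function(r) {
      k <- r$calls[r$calls$pass, ]
      paste(k$chrom, k$pos, k$ref, k$alt, k$molecule_id, sep = ":")
    })
  )
}
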