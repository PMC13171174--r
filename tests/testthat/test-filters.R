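make_candidate <- function(chrom = "chr1", pos = 55L, ref = "GATC", alt = "G",
                           molecule_id = "mol1", n_plus = 2L, n_minus = 2L,
                           strandedness = "DOUBLE") {
  tibble::tibble(molecule_id = molecule_id, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, kind = "DEL", length = 3L,
                 n_plus = n_plus, n_minus = n_minus,
                 n_total = n_plus + n_minus, strandedness = strandedness,
                 filters = "")
}

test_that("germline filter labels bulk-supported and low-depth candidates", {
  cand <- make_candidate()
  het <- bulk_evidence(tibble::tibble(chrom = "chr1", pos = 55L, ref = "GATC",
                                      alt = "G", bulk_depth = 30L,
                                      bulk_alt = 15L))
  expect_equal(filter_germline(cand, het)$filters, "germline")
  clean <- bulk_evidence(tibble::tibble(chrom = "chr1", pos = 55L,
                                        ref = "GATC", alt = "G",
                                        bulk_depth = 40L, bulk_alt = 0L))
  expect_equal(filter_germline(cand, clean)$filters, "")
  shallow <- bulk_evidence(tibble::tibble(chrom = "chr1", pos = 55L,
                                          ref = "GATC", alt = "G",
                                          bulk_depth = 5L, bulk_alt = 0L))
  expect_equal(filter_germline(cand, shallow)$filters, "low_bulk_depth")
  # allele absent from the table: default depth applies, no germline evidence
  absent <- bulk_evidence(tibble::tibble(chrom = character(), pos = integer(),
                                         ref = character(), alt = character(),
                                         bulk_depth = integer(),
                                         bulk_alt = integer()),
                          default_depth = 30L)
  expect_equal(filter_germline(cand, absent)$filters, "")
})

test_that("on simulated truth the germline filter is exact", {
  sim <- simulate_duplex(sim_config(seed = 51, n_molecules = 150,
                                    n_somatic = 30, n_germline = 20,
                                    reference_length = 60000))
  g <- group_molecules(sim$reads)
  cands <- call_candidates(g, reference = sim$reference)
  out <- filter_germline(cands, sim$bulk)
  gkeys <- allele_keys(sim$truth$germline)
  skeys <- allele_keys(sim$truth$somatic)
  ckeys <- allele_keys(out)
  germ_cands <- out[ckeys %in% gkeys, ]
  som_cands <- out[ckeys %in% skeys, ]
  expect_gt(nrow(germ_cands), 0)
  expect_true(all(grepl("germline", germ_cands$filters)))
  expect_false(any(grepl("germline", som_cands$filters)))
})

test_that("adjacent-germline filter respects the window and allele identity", {
  cand <- make_candidate(pos = 100L, ref = "AT", alt = "A")
  germ_near <- tibble::tibble(chrom = "chr1", pos = 106L, ref = "CTTTTT",
                              alt = "C")
  germ_far <- tibble::tibble(chrom = "chr1", pos = 150L, ref = "CT", alt = "C")
  expect_equal(filter_adjacent_germline(cand, germ_near, window = 10)$filters,
               "near_germline")
  expect_equal(filter_adjacent_germline(cand, germ_far, window = 10)$filters,
               "")
  # the identical allele does not trigger adjacency
  same <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "AT", alt = "A")
  expect_equal(filter_adjacent_germline(cand, same, window = 10)$filters, "")
  # W = 0: only same-position distinct alleles
  other_same_pos <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "ATT",
                                   alt = "A")
  expect_equal(filter_adjacent_germline(cand, other_same_pos,
                                        window = 0)$filters, "near_germline")
  expect_equal(filter_adjacent_germline(cand, germ_near, window = 0)$filters,
               "")
})

test_that("population-AF filter uses the >= cutoff with absent alleles at 0", {
  cand <- make_candidate()
  af_hi <- tibble::tibble(chrom = "chr1", pos = 55L, ref = "GATC", alt = "G",
                          af = 0.05)
  af_edge <- af_hi; af_edge$af <- 0.0099
  af_at <- af_hi; af_at$af <- 0.01
  expect_equal(filter_population_af(cand, af_hi)$filters, "common_variant")
  expect_equal(filter_population_af(cand, af_edge)$filters, "")
  expect_equal(filter_population_af(cand, af_at)$filters, "common_variant")
  af_other <- tibble::tibble(chrom = "chr1", pos = 99L, ref = "A", alt = "AT",
                             af = 0.9)
  expect_equal(filter_population_af(cand, af_other)$filters, "")
})

test_that("cut-site filter labels exactly the collided molecules' candidates", {
  sim <- simulate_duplex(sim_config(seed = 52, n_molecules = 150,
                                    n_somatic = 40, n_germline = 10,
                                    reference_length = 60000,
                                    collision_rate = 0.1))
  g <- group_molecules(sim$reads)
  mols <- summarise_molecules(g)
  cands <- filter_cutsite(call_candidates(g, reference = sim$reference), mols)
  labeled <- grepl("cutsite_inconsistent", cands$filters)
  in_collided <- cands$molecule_id %in% sim$truth$collisions$molecule_id
  expect_equal(labeled, in_collided)
  expect_gt(sum(in_collided), 0)
})

test_that("merge-confound filter fires on ambiguous overlaps and repeat tracts", {
  ref <- fixture_reference()
  contig <- ref[["chr1"]]
  seq <- paste0(substr(contig, 41, 55), substr(contig, 59, 80))
  base_fam <- function(ambiguous, ov = c(46L, 70L)) {
    fam <- fixture_family(ref, pos = 41, flen = 40, cigar = "15M3D22M",
                          seq = seq)
    fam$overlap_start <- ov[1]; fam$overlap_end <- ov[2]
    fam$ambiguous <- ambiguous
    fam
  }
  run_filter <- function(fam) {
    g <- group_molecules(fam)
    obs <- indel_observations(g, ref)
    filter_merge_confound(call_candidates(g, obs, ref), g, obs, ref)
  }
  # support inside unambiguous overlaps: pass
  expect_equal(run_filter(base_fam(FALSE))$filters, "")
  # one ambiguous read, all support inside overlaps: labeled
  fam <- base_fam(FALSE)
  fam$ambiguous[1] <- TRUE
  expect_equal(run_filter(fam)$filters, "merge_confound")
  # ambiguous but indel outside every overlap (and no merge boundary inside
  # the local CGAT tract at 50..61): rule (a) does not fire
  fam_out <- base_fam(TRUE, ov = c(42L, 48L))
  expect_equal(run_filter(fam_out)$filters, "")
  # an unambiguous merge whose boundary cuts through a >= 12 bp repeat tract
  # is still confound-labeled (rule b)
  fam_tract <- base_fam(FALSE, ov = c(56L, 75L))
  expect_equal(run_filter(fam_tract)$filters, "merge_confound")
  # missing merge metadata: advisory label plus warning
  fam_na <- base_fam(FALSE)
  fam_na$merged <- NA
  g <- group_molecules(fam_na)
  obs <- indel_observations(g, ref)
  expect_warning(
    out <- filter_merge_confound(call_candidates(g, obs, ref), g, obs, ref),
    "not_evaluable")
  expect_equal(out$filters, "not_evaluable")
  expect_true(all(finalize_calls(out)$pass))
})

test_that("planted mis-merges at tandem repeats are labeled end to end", {
  sim <- simulate_duplex(sim_config(seed = 53, n_molecules = 120,
                                    n_somatic = 10, n_germline = 5,
                                    reference_length = 60000,
                                    mismerge_rate = 0.08))
  run <- run_pipeline(sim$reads, sim$reference, bulk = sim$bulk)
  calls <- tidy(run)
  mm <- sim$truth$artifacts[sim$truth$artifacts$type == "mismerge", ]
  expect_gt(nrow(mm), 0)
  mkeys <- paste(allele_keys(mm), mm$molecule_id)
  ckeys <- paste(allele_keys(calls), calls$molecule_id)
  hit <- calls[ckeys %in% mkeys, ]
  expect_equal(nrow(hit), nrow(mm))
  expect_true(all(grepl("merge_confound", hit$filters)))
  expect_false(any(hit$pass))
})

test_that("filters commute and disabling a filter never removes PASS calls", {
  sim <- simulate_duplex(sim_config(seed = 54, n_molecules = 120,
                                    n_somatic = 25, n_germline = 15,
                                    reference_length = 60000,
                                    collision_rate = 0.05,
                                    artifact_rate = 0.05))
  g <- group_molecules(sim$reads)
  mols <- summarise_molecules(g)
  obs <- indel_observations(g, sim$reference)
  cands <- call_candidates(g, obs, sim$reference)
  af <- tibble::tibble(chrom = sim$truth$somatic$chrom[1:5],
                       pos = sim$truth$somatic$pos[1:5],
                       ref = sim$truth$somatic$ref[1:5],
                       alt = sim$truth$somatic$alt[1:5],
                       af = c(0.05, 0.5, 0.009, 0.01, 0))
  order1 <- cands |>
    filter_germline(sim$bulk) |>
    filter_adjacent_germline(germline_set(sim$bulk), window = 10) |>
    filter_cutsite(mols) |>
    filter_population_af(af)
  order2 <- cands |>
    filter_population_af(af) |>
    filter_cutsite(mols) |>
    filter_adjacent_germline(germline_set(sim$bulk), window = 10) |>
    filter_germline(sim$bulk)
  f1 <- finalize_calls(order1)
  f2 <- finalize_calls(order2)
  expect_equal(f1$filters, f2$filters)
  expect_equal(f1$pass, f2$pass)
  # monotonicity: dropping the AF filter can only grow the PASS set
  f_no_af <- finalize_calls(
    cands |> filter_germline(sim$bulk) |>
      filter_adjacent_germline(germline_set(sim$bulk), window = 10) |>
      filter_cutsite(mols))
  keys <- function(d) paste(allele_keys(d), d$molecule_id)
  expect_true(all(keys(f1[f1$pass, ]) %in% keys(f_no_af[f_no_af$pass, ])))
})

test_that("finalization assigns PASS only to clean double-strand calls", {
  clean_double <- make_candidate()
  labeled <- make_candidate(molecule_id = "mol2")
  labeled$filters <- "germline"
  single <- make_candidate(molecule_id = "mol3", n_plus = 4L, n_minus = 0L,
                           strandedness = "SINGLE")
  out <- finalize_calls(dplyr::bind_rows(clean_double, labeled, single))
  expect_equal(out$FILTER[out$molecule_id == "mol1"], "PASS")
  expect_true(out$pass[out$molecule_id == "mol1"])
  expect_equal(out$FILTER[out$molecule_id == "mol2"], "germline")
  expect_false(out$pass[out$molecule_id == "mol2"])
  expect_equal(out$track[out$molecule_id == "mol3"], "SINGLE_STRAND")
  expect_false(out$pass[out$molecule_id == "mol3"])
})
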