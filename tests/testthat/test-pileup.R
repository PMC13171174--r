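test_that("a shared deletion is counted per strand at the anchored column", {
  ref <- fixture_reference()
  # fragment [41, 80]; delete the "CGA" at 56..58 (anchor 55, "GAT CGA TCGA")
  contig <- ref[["chr1"]]
  seq <- paste0(substr(contig, 41, 55), substr(contig, 59, 80))
  fam <- fixture_family(ref, pos = 41, flen = 40, n_plus = 3, n_minus = 3,
                        cigar = "15M3D22M", seq = seq)
  pc <- pileup_columns(fam, ref)
  al <- pc$alleles
  expect_equal(nrow(al), 1L)
  expect_equal(al$n_alt_plus, 3L)
  expect_equal(al$n_alt_minus, 3L)
  # depth includes the deletion-spanning reads across the whole fragment
  expect_true(all(pc$columns$depth[pc$columns$pos %in% 41:80] == 6L))
})

test_that("reads failing the mapping-quality cut leave counts unchanged", {
  ref <- fixture_reference()
  contig <- ref[["chr1"]]
  seq <- paste0(substr(contig, 41, 55), substr(contig, 59, 80))
  fam <- fixture_family(ref, pos = 41, flen = 40, n_plus = 3, n_minus = 3,
                        cigar = "15M3D22M", seq = seq)
  low <- fixture_read("low_mq", "chr1", 41, "15M3D22M", seq, mapq = 10L)
  with_low <- pileup_columns(dplyr::bind_rows(fam, low), ref)
  without <- pileup_columns(fam, ref)
  expect_equal(with_low, without)
})

test_that("low flanking base quality suppresses the observation", {
  ref <- fixture_reference()
  contig <- ref[["chr1"]]
  seq <- paste0(substr(contig, 41, 55), substr(contig, 59, 80))
  qual <- strrep("I", nchar(seq))
  substr(qual, 15, 15) <- "!"   # anchor base at read offset 15 -> Q0
  rd <- fixture_read("bq", "chr1", 41, "15M3D22M", seq, qual = qual)
  obs <- indel_observations(rd, ref)
  expect_equal(nrow(obs), 1L)
  expect_false(obs$bq_ok)
  pc <- pileup_columns(rd, ref)
  expect_equal(nrow(pc$alleles), 0L)
})

test_that("pileup counts equal an independent brute-force recount", {
  sim <- simulate_duplex(sim_config(seed = 41, n_molecules = 60,
                                    n_somatic = 12, n_germline = 8,
                                    reference_length = 50000,
                                    artifact_rate = 0.05))
  pc <- pileup_columns(sim$reads, sim$reference)
  oc <- oracle_pileup(sim$reads, sim$reference)
  # allele counts
  got <- pc$alleles
  got_keys <- paste(got$chrom, got$pos, got$ref, got$alt)
  for (i in seq_len(nrow(got))) {
    expect_identical(oc$alleles[[paste(got_keys[i], "+")]] %||% 0L,
                     got$n_alt_plus[i])
    expect_identical(oc$alleles[[paste(got_keys[i], "-")]] %||% 0L,
                     got$n_alt_minus[i])
  }
  expect_equal(nrow(got), length(unique(sub(" [+-]$", "",
                                            names(oc$alleles)))))
  # depth and per-strand reference counts at every covered position
  cols <- pc$columns
  for (chrom in unique(cols$chrom)) {
    cc <- cols[cols$chrom == chrom, ]
    vp <- oc$cov[[paste(chrom, "+")]]
    vm <- oc$cov[[paste(chrom, "-")]]
    expect_identical(cc$depth, (vp + vm)[cc$pos])
    op <- vapply(cc$pos, function(p)
      oc$obs_at[[paste(chrom, p, "+")]] %||% 0L, integer(1))
    om <- vapply(cc$pos, function(p)
      oc$obs_at[[paste(chrom, p, "-")]] %||% 0L, integer(1))
    expect_identical(cc$n_ref_plus, vp[cc$pos] - op)
    expect_identical(cc$n_ref_minus, vm[cc$pos] - om)
    # no coverage outside the reported columns
    expect_true(all((vp + vm)[setdiff(seq_along(vp), cc$pos)] == 0L))
  }
})

test_that("candidate generation applies the aXsY complementarity check", {
  ref <- fixture_reference()
  contig <- ref[["chr1"]]
  seq <- paste0(substr(contig, 41, 55), substr(contig, 59, 80))
  make_cands <- function(n_plus, n_minus, th) {
    fam <- fixture_family(ref, pos = 41, flen = 40, n_plus = n_plus,
                          n_minus = n_minus, cigar = "15M3D22M", seq = seq)
    g <- group_molecules(fam)
    call_candidates(g, reference = ref, threshold = th)
  }
  # 2+2 under a4s2: one DOUBLE candidate
  c22 <- make_cands(2, 2, call_threshold(4, 2))
  expect_equal(nrow(c22), 1L)
  expect_equal(c22$strandedness, "DOUBLE")
  expect_equal(c22$n_total, 4L)
  # 4+0: SINGLE (fails the per-strand check)
  c40 <- make_cands(4, 0, call_threshold(4, 2))
  expect_equal(c40$strandedness, "SINGLE")
  # 2+1 = 3 total: below a, no candidate
  c21 <- make_cands(2, 1, call_threshold(4, 2))
  expect_equal(nrow(c21), 0L)
})

test_that("sex-chromosome candidates are excluded and mask labels applied", {
  ref <- fixture_reference()
  # chrX fixture: "ACGT" repeat; insert a base via cigar on chrX
  xseq <- paste0(substr(ref[["chrX"]], 5, 14), "A", substr(ref[["chrX"]], 15, 24))
  fam <- fixture_family(ref, chrom = "chrX", pos = 5, flen = 20,
                        cigar = "10M1I10M", seq = xseq)
  g <- group_molecules(fam)
  cands <- call_candidates(g, reference = ref, threshold = call_threshold(4, 2))
  expect_equal(nrow(cands), 0L)
  cands_keep <- call_candidates(g, reference = ref,
                                threshold = call_threshold(4, 2),
                                exclude_sex = FALSE)
  expect_equal(nrow(cands_keep), 1L)
  # mask: a window that does not contain the indel labels the candidate
  contig <- ref[["chr1"]]
  seq <- paste0(substr(contig, 41, 55), substr(contig, 59, 80))
  fam1 <- fixture_family(ref, pos = 41, flen = 40, cigar = "15M3D22M",
                         seq = seq)
  g1 <- group_molecules(fam1)
  mask_far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 100))
  mask_near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40, 80))
  out_far <- call_candidates(g1, reference = ref, mask = mask_far)
  out_near <- call_candidates(g1, reference = ref, mask = mask_near)
  expect_equal(out_far$filters, "masked")
  expect_equal(out_near$filters, "")
})

test_that("double-strand call sets are nested across rising thresholds", {
  sim <- simulate_duplex(sim_config(seed = 42, n_molecules = 80,
                                    n_somatic = 20, n_germline = 5,
                                    reference_length = 50000))
  g <- group_molecules(sim$reads)
  obs <- indel_observations(g, sim$reference)
  ths <- list(call_threshold(4, 2), call_threshold(6, 3), call_threshold(8, 4),
              call_threshold(10, 5))
  sets <- lapply(ths, function(th) {
    cc <- call_candidates(g, obs, sim$reference, threshold = th)
    dd <- cc[cc$strandedness == "DOUBLE", ]
    paste(dd$chrom, dd$pos, dd$ref, dd$alt, dd$molecule_id)
  })
  for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  expect_true(all(diff(vapply(sets, length, integer(1))) <= 0))
})

test_that("multi-allelic columns evaluate each allele independently", {
  ref <- fixture_reference()
  contig <- ref[["chr1"]]
  del_seq <- paste0(substr(contig, 41, 55), substr(contig, 59, 80))
  ins_seq <- paste0(substr(contig, 41, 55), "T", substr(contig, 56, 80))
  a <- fixture_family(ref, pos = 41, flen = 40, n_plus = 2, n_minus = 2,
                      cigar = "15M3D22M", seq = del_seq)
  b <- fixture_family(ref, pos = 41, flen = 40, n_plus = 3, n_minus = 3,
                      cigar = "15M1I25M", seq = ins_seq,
                      bc1 = "CCCCAAAA", bc2 = "TTTTGGGG")
  b$read_id <- paste0("b_", b$read_id)
  g <- group_molecules(dplyr::bind_rows(a, b))
  cands <- call_candidates(g, reference = ref)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$n_total, c(4L, 6L))
  expect_true(all(cands$strandedness == "DOUBLE"))
})
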