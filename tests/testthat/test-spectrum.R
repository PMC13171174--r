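test_that("the channel scheme has 83 distinct, well-formed labels", {
  ch <- id83_channels()
  expect_length(ch, 83)
  expect_equal(anyDuplicated(ch), 0L)
  expect_true(all(grepl("^[1-5]:(Del|Ins):(C|T|R|M):[0-5]$", ch)))
})

test_that("homopolymer strata match an independent run-length counter", {
  withr::with_seed(61, {
    # a contig rich in short runs
    contig <- paste(vapply(1:220, function(i)
      strrep(sample(c("A", "C", "G", "T"), 1), sample(1:7, 1)), character(1)),
      collapse = "")
    ref <- c(chr1 = contig)
    for (rep in 1:80) {
      pos <- sample(60:(nchar(contig) - 60), 1)
      base <- substr(contig, pos + 1, pos + 1)
      is_del <- runif(1) < 0.5
      if (is_del) {
        allele <- list(ref = paste0(substr(contig, pos, pos), base),
                       alt = substr(contig, pos, pos))
      } else {
        allele <- list(ref = substr(contig, pos, pos),
                       alt = paste0(substr(contig, pos, pos), base))
      }
      n <- normalize_indel("chr1", pos, allele$ref, allele$alt, ref)
      ch <- classify_indel("chr1", n$pos, n$ref, n$alt, ref)
      ev <- if (nchar(n$ref) > 1) substr(n$ref, 2, 2) else substr(n$alt, 2, 2)
      run <- oracle_run_length(contig, n$pos + 1, ev)
      want_stratum <- if (nchar(n$ref) > 1) min(run, 6) - 1 else min(run, 5)
      pyr <- if (ev %in% c("A", "G")) chartr("AG", "TC", ev) else ev
      want <- sprintf("1:%s:%s:%d", if (nchar(n$ref) > 1) "Del" else "Ins",
                      pyr, want_stratum)
      expect_equal(ch, want)
    }
  })
})

test_that("worked channel examples classify as specified", {
  # deletion of one T from a run of six Ts: run-length stratum capped at 5+
  ref1 <- c(chr1 = paste0(strrep("ACG", 25), "A", strrep("T", 6), "G",
                          strrep("CGA", 25)))
  pos_run <- 76L  # the "A" before the T-run
  expect_equal(substr(ref1[["chr1"]], pos_run, pos_run + 6), "ATTTTTT")
  n <- normalize_indel("chr1", pos_run, "AT", "A", ref1)
  expect_equal(classify_indel("chr1", n$pos, n$ref, n$alt, ref1), "1:Del:T:5")
  # insertion of a C adjacent to zero Cs
  ref2 <- c(chr1 = paste0(strrep("ATG", 30), "ATTA", strrep("GTA", 30)))
  p <- 91L
  expect_equal(substr(ref2[["chr1"]], p, p + 1), "AT")
  expect_equal(classify_indel("chr1", p, "A", "AC", ref2), "1:Ins:C:0")
  # 3-bp deletion whose deleted bases recur once downstream: repeat stratum,
  # not microhomology
  ref3 <- c(chr1 = paste0(strrep("AG", 30), "T", "CAT", "CAT", "GG",
                          strrep("TC", 30)))
  a <- 61L
  expect_equal(substr(ref3[["chr1"]], a, a + 6), "TCATCAT")
  n3 <- normalize_indel("chr1", a, "TCAT", "T", ref3)
  expect_equal(classify_indel("chr1", n3$pos, n3$ref, n3$alt, ref3),
               "3:Del:R:1")
  # a deletion with only a partial (2-bp) downstream echo: microhomology
  ref4 <- c(chr1 = paste0(strrep("AG", 30), "T", "GAC", "GAT", "T",
                          strrep("TC", 30)))
  expect_equal(substr(ref4[["chr1"]], 61, 67), "TGACGAT")
  n4 <- normalize_indel("chr1", 61L, "TGAC", "T", ref4)
  expect_equal(classify_indel("chr1", n4$pos, n4$ref, n4$alt, ref4),
               "3:Del:M:2")
})

test_that("classification is total on simulator output and errors at contig edges", {
  sim <- simulate_duplex(sim_config(seed = 62, n_molecules = 80,
                                    n_somatic = 40, n_germline = 20,
                                    reference_length = 60000))
  all_alleles <- dplyr::bind_rows(
    sim$truth$somatic[c("chrom", "pos", "ref", "alt")],
    sim$truth$germline[c("chrom", "pos", "ref", "alt")])
  cls <- classify_indels(all_alleles, sim$reference)
  expect_true(all(cls$channel %in% id83_channels()))
  expect_error(classify_indel("chr1", 5L, substr(sim$reference[["chr1"]], 5, 6),
                              substr(sim$reference[["chr1"]], 5, 5),
                              sim$reference),
               "context_unavailable")
})

test_that("cosine similarity has its closed-form values and invariances", {
  v <- rep(0, 83)
  s1 <- v; s1[1:3] <- c(1, 2, 2)
  s2 <- v; s2[1:3] <- c(2, 1, 2)
  s3 <- v; s3[10:12] <- c(3, 1, 4)
  expect_equal(cosine_similarity(s1, s1), 1.0, tolerance = 1e-12)
  expect_equal(cosine_similarity(s1, s3), 0.0, tolerance = 1e-12)
  expect_equal(cosine_similarity(s1, s2), 8 / 9, tolerance = 1e-12)
  # symmetry and scale invariance
  expect_equal(cosine_similarity(s1, s2), cosine_similarity(s2, s1))
  expect_equal(cosine_similarity(s1 * 17, s2), cosine_similarity(s1, s2))
  expect_error(cosine_similarity(v, s1), "empty_spectrum")
  # spectrum-tibble input
  sp <- indel_spectrum(c("1:Del:C:0", "1:Del:C:1", "1:Del:C:1"))
  expect_equal(cosine_similarity(sp, sp), 1.0)
})

test_that("spectrum construction counts every call exactly once", {
  withr::with_seed(63, {
    ch <- sample(id83_channels(), 200, replace = TRUE)
    sp <- indel_spectrum(ch)
    expect_equal(sum(sp$count), 200L)
    expect_equal(as.character(sp$channel), id83_channels())
    expect_error(indel_spectrum("9:Del:Q:9"), "unknown")
  })
})

test_that("calls sampled from a known spectrum recover it", {
  probs <- rep(0, 83)
  probs[c(2, 7, 14, 20, 30, 45, 55, 70, 78, 82)] <-
    c(0.2, 0.15, 0.12, 0.1, 0.1, 0.09, 0.09, 0.06, 0.05, 0.04)
  sp <- simulate_spectrum_calls(probs, 500, seed = 64)
  cls <- classify_indels(sp$calls, sp$reference)
  expect_equal(cls$channel, sp$calls$channel)   # constructed contexts are exact
  sim <- cosine_similarity(indel_spectrum(cls$channel), probs)
  expect_gte(sim, 0.95)
})

test_that("bootstrap similarities separate true references from controls", {
  withr::with_seed(65, {
    probs_a <- rep(0, 83); probs_a[1:10] <- 0.1
    probs_b <- rep(0, 83); probs_b[40:49] <- 0.1   # orthogonal support
    calls_a <- sample(id83_channels()[1:10], 200, replace = TRUE)
    bs <- bootstrap_similarity(calls_a, probs_a,
                               control_spectra = list(unrelated = probs_b),
                               n_boot = 300, seed = 9)
    obs_ref <- bs$observed[bs$spectrum == "reference"]
    expect_true(obs_ref >= bs$ci_lo[bs$spectrum == "reference"] &&
                  obs_ref <= bs$ci_hi[bs$spectrum == "reference"])
    expect_gt(obs_ref, bs$ci_hi[bs$spectrum == "unrelated"])
    # determinism under a fixed seed
    bs2 <- bootstrap_similarity(calls_a, probs_a,
                                control_spectra = list(unrelated = probs_b),
                                n_boot = 300, seed = 9)
    expect_identical(bs, bs2)
    expect_error(bootstrap_similarity(calls_a[1:5], probs_a, seed = 1),
                 "insufficient_calls")
  })
})

test_that("down-sampling keeps whole molecules with binomial retention", {
  reads <- tibble::tibble(molecule_id = rep(sprintf("m%04d", 1:5000), each = 2),
                          x = 1)
  expect_identical(downsample_molecules(reads, 1, seed = 1), reads)
  kept <- downsample_molecules(reads, 0.5, seed = 2)
  # molecules survive or vanish whole
  tab <- table(kept$molecule_id)
  expect_true(all(tab == 2))
  n_kept <- length(tab)
  bounds <- qbinom(c(0.005, 0.995), 5000, 0.5)
  expect_gte(n_kept, bounds[1])
  expect_lte(n_kept, bounds[2])
  expect_identical(downsample_molecules(reads, 0.5, seed = 2), kept)
  expect_false(identical(downsample_molecules(reads, 0.5, seed = 3), kept))
})

test_that("spectrum TSV round trip preserves counts", {
  withr::with_seed(66, {
    sp <- indel_spectrum(sample(id83_channels(), 120, replace = TRUE))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_spectrum(sp, path)
    back <- read_spectrum(path)
    expect_equal(back$count, sp$count)
    expect_equal(as.character(back$channel), as.character(sp$channel))
  })
})
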