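# Ground-truthed synthetic duplex sequencing data. The generator emits raw
# FASTQ pairs, the corresponding already-aligned duplex reads (so the caller
# is testable without an external aligner), bulk WGS evidence, and truth
# tables for every artifact class the filter stack targets.

#' Simulation configuration
#'
#' Defaults describe a realistic small Tn5 duplex experiment: 96 terminal
#' barcodes of 8 bp, fragments of 230 +/- 25 bp read as 150 bp pairs (so mates
#' always overlap and merge), duplex families of 4 + Poisson(1) reads per
#' strand (deep consensus families, so the default a4s2 threshold is
#' attainable on either strand alone), substitution sequencing errors at
#' 1e-3/bp, and no artifacts unless switched on.
#'
#' @param seed Integer seed (mandatory; all randomness derives from it).
#' @param reference_length Autosome (chr1) length in bp (>= 10000). A sex
#'   chromosome (chrX) of 20% that length is always added.
#' @param n_molecules Number of original DNA molecules.
#' @param n_somatic Somatic indels, each planted on both strands of one
#'   distinct autosomal molecule.
#' @param n_germline Germline indels at VAF 0.5 or 1.0, present in bulk.
#' @param reads_per_strand_min,reads_per_strand_lambda Reads per strand are
#'   `min + Poisson(lambda)`.
#' @param read_length Read length in bp (insert part, excluding the barcode).
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max Fragment-length
#'   distribution (truncated normal).
#' @param n_barcodes,barcode_length Barcode list parameters.
#' @param error_rate Per-base substitution sequencing-error rate (indel
#'   sequencing errors are off so truth stays unambiguous).
#' @param artifact_rate Per-molecule probability of a single-strand artifact
#'   indel (present on all reads of one strand only). Artifacts are planted on
#'   autosomal molecules, where calling is in scope.
#' @param collision_rate Per-molecule probability of reusing another
#'   molecule's barcode pair at a different locus (barcode collision).
#' @param mismerge_rate Per-molecule probability of a false merge at a planted
#'   tandem repeat: a spurious one-unit deletion inside the merged overlap
#'   with the merge flagged ambiguous.
#' @param mixture_fraction Fraction of somatic-designated molecules actually
#'   drawn from the mutant genome (emulates spiking a mutant sample into a
#'   wild-type background); realized somatic indels are flagged in the truth.
#' @param chrx_fraction Fraction of molecules placed on chrX (to exercise
#'   sex-chromosome exclusion).
#' @param germline_vaf_levels Candidate germline VAFs (heterozygous /
#'   homozygous).
#' @param bulk_depth_mean Mean bulk WGS depth (Poisson, floored at 10).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       reference_length = 200000L,
                       n_molecules = 1000L,
                       n_somatic = 200L,
                       n_germline = 60L,
                       reads_per_strand_min = 4L,
                       reads_per_strand_lambda = 1,
                       read_length = 150L,
                       fragment_mean = 230, fragment_sd = 25,
                       fragment_min = 170L, fragment_max = 270L,
                       n_barcodes = 96L, barcode_length = 8L,
                       error_rate = 0.001,
                       artifact_rate = 0,
                       collision_rate = 0,
                       mismerge_rate = 0,
                       mixture_fraction = 1,
                       chrx_fraction = 0.1,
                       germline_vaf_levels = c(0.5, 1),
                       bulk_depth_mean = 30L) {
  if (missing(seed)) abort("seed is mandatory")
  rates <- c(error_rate, artifact_rate, collision_rate, mismerge_rate,
             mixture_fraction, chrx_fraction)
  stopifnot(all(rates >= 0 & rates <= 1), reference_length >= 10000,
            n_somatic <= n_molecules, reads_per_strand_min >= 1,
            fragment_min > 0, fragment_max >= fragment_min)
  structure(as.list(environment()), class = "sim_config")
}

# sample one value from lo:hi without the length-1 sample() trap
sample_between <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Simulate a reference genome with planted repeat structure
#'
#' Deterministic given the seed. chr1 carries planted homopolymers (>= 8 bp)
#' and tandem repeats (unit 2-6 bp, >= 12 bp total) every ~5 kb, recorded in a
#' feature table, to exercise spectrum classification and merge-confound
#' logic; a chrX contig (20% of the length) exercises sex-chromosome
#' exclusion.
#'
#' @param length chr1 length in bp (>= 10000).
#' @param seed Integer seed.
#' @return List with `reference` (named character vector) and `features`
#'   tibble (`chrom`, `start`, `end`, `type`, `unit`).
#' @export
simulate_reference <- function(length = 200000L, seed) {
  stopifnot(length >= 10000)
  with_seed(as.integer(seed), {
    make_contig <- function(chrom, n, plant) {
      bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      feats <- list()
      if (plant) {
        at <- seq(2500L, n - 100L, by = 5000L)
        for (i in seq_along(at)) {
          p <- at[i]
          if (i %% 2 == 1) {
            b <- sample(c("A", "C", "G", "T"), 1)
            len <- sample(8:12, 1)
            bases[p:(p + len - 1L)] <- b
            bases[p - 1L] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
            bases[p + len] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
            feats[[i]] <- tibble(chrom = chrom, start = p, end = p + len - 1L,
                                 type = "homopolymer", unit = b)
          } else {
            u <- sample(2:6, 1)
            unit <- random_dna(u)
            k <- sample(ceiling(12 / u):ceiling(24 / u), 1)
            tract <- strsplit(strrep(unit, k), "")[[1]]
            bases[p:(p + base::length(tract) - 1L)] <- tract
            feats[[i]] <- tibble(chrom = chrom, start = p,
                                 end = p + base::length(tract) - 1L,
                                 type = "tandem_repeat", unit = unit)
          }
        }
      }
      list(seq = paste(bases, collapse = ""), features = list_rbind(feats))
    }
    c1 <- make_contig("chr1", as.integer(length), plant = TRUE)
    cx <- make_contig("chrX", as.integer(round(length * 0.2)), plant = FALSE)
    list(reference = c(chr1 = c1$seq, chrX = cx$seq),
         features = c1$features)
  })
}

# random simple indel anchored at a 1-based position; returns the normalized
# allele as a one-row tibble
random_indel_at <- function(reference, chrom, pos, max_len = 3L) {
  contig <- reference[[chrom]]
  kind <- sample(c("DEL", "INS"), 1, prob = c(0.6, 0.4))
  len <- sample.int(max_len, 1, prob = c(0.6, 0.25, 0.15)[seq_len(max_len)])
  anchor <- substr(contig, pos, pos)
  if (kind == "DEL") {
    ref <- substr(contig, pos, pos + len)
    alt <- anchor
  } else {
    ref <- anchor
    alt <- paste0(anchor, random_dna(len))
  }
  n <- normalize_indel(chrom, pos, ref, alt, reference)
  tibble(chrom = n$chrom, pos = n$pos, ref = n$ref, alt = n$alt)
}

# n random positions in [lo, hi] pairwise at least `spacing` apart
spaced_positions <- function(n, lo, hi, spacing) {
  cand <- sort(sample(lo:hi, min(n * 10L, hi - lo + 1L)))
  keep <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last >= spacing) { keep <- c(keep, p); last <- p }
    if (base::length(keep) == n) break
  }
  if (base::length(keep) < n) abort("could not place variants; enlarge reference")
  keep
}

# haplotype sequence + CIGAR of a fragment [fs1, fe1] (1-based inclusive)
# carrying the given normalized alleles
apply_variants_to_fragment <- function(contig, fs1, fe1, vars) {
  if (nrow(vars) == 0) {
    return(list(seq = substr(contig, fs1, fe1),
                cigar = sprintf("%dM", fe1 - fs1 + 1L)))
  }
  vars <- vars[order(vars$pos), , drop = FALSE]
  ops <- character(0); lens <- integer(0)
  push <- function(op, l) {
    if (l == 0L) return()
    k <- base::length(ops)
    if (k > 0 && ops[k] == op) {
      lens[k] <<- lens[k] + l
    } else {
      ops[k + 1L] <<- op
      lens[k + 1L] <<- l
    }
  }
  seq <- character(0)
  cur <- fs1
  for (i in seq_len(nrow(vars))) {
    pos <- vars$pos[i]; ref <- vars$ref[i]; alt <- vars$alt[i]
    stopifnot(pos >= cur)
    seq <- c(seq, substr(contig, cur, pos))
    push("M", pos - cur + 1L)
    if (nchar(ref) > nchar(alt)) {
      dlen <- nchar(ref) - 1L
      push("D", dlen)
      cur <- pos + dlen + 1L
    } else {
      ins <- substr(alt, 2L, nchar(alt))
      push("I", nchar(ins))
      seq <- c(seq, ins)
      cur <- pos + 1L
    }
  }
  stopifnot(cur <= fe1 + 1L)
  if (cur <= fe1) {
    seq <- c(seq, substr(contig, cur, fe1))
    push("M", fe1 - cur + 1L)
  }
  list(seq = paste(seq, collapse = ""),
       cigar = paste0(lens, ops, collapse = ""))
}

inject_substitutions <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  at <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate a complete ground-truthed duplex sequencing dataset
#'
#' Each molecule receives a barcode pair, a fragment, and strand-split merged
#' reads: both the raw FASTQ pairs (barcodes and adapters attached) and the
#' corresponding already-aligned read records are emitted, so the caller can
#' be exercised with or without a real aligner. Somatic indels are planted on
#' both strands of their molecule, single-strand artifacts on one strand only,
#' collisions reuse a barcode pair at a distant locus, mis-merges plant a
#' spurious deletion inside an ambiguous merge overlap at a tandem repeat, and
#' bulk evidence contains germline but not somatic alleles (every germline
#' allele has at least one bulk supporting read — the truth contract is that
#' germline variants are detectable in bulk).
#'
#' @param cfg A [sim_config()].
#' @return List of class `duplex_sim`: `reference`, `features`, `reads`
#'   (aligned tibble with ground-truth `true_strand`), `fastq` (raw pair
#'   tibble), `barcodes`, `bulk` ([bulk_evidence()]), `truth` (list:
#'   `germline`, `somatic`, `artifacts`, `collisions`, `spectrum`),
#'   `molecules`, `config`.
#' @export
simulate_duplex <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  refsim <- simulate_reference(cfg$reference_length, seed = cfg$seed)
  reference <- refsim$reference
  barcodes <- make_barcodes(cfg$n_barcodes, cfg$barcode_length,
                            seed = as.integer(cfg$seed) + 2L)
  with_seed(as.integer(cfg$seed) + 1L, {
    n <- cfg$n_molecules
    len1 <- nchar(reference[["chr1"]])
    lenx <- nchar(reference[["chrX"]])

    ## --- variant truth ------------------------------------------------------
    pos_all <- spaced_positions(cfg$n_somatic + cfg$n_germline, 100L,
                                len1 - 100L, 60L)
    pos_all <- sample(pos_all)  # decouple role from genomic order
    somatic <- list_rbind(map(pos_all[seq_len(cfg$n_somatic)], function(p)
      random_indel_at(reference, "chr1", p)))
    germline <- list_rbind(map(pos_all[cfg$n_somatic + seq_len(cfg$n_germline)],
                               function(p) random_indel_at(reference, "chr1", p)))
    germline$vaf <- sample(cfg$germline_vaf_levels, nrow(germline),
                           replace = TRUE)
    somatic$realized <- runif(cfg$n_somatic) < cfg$mixture_fraction

    ## --- molecules ----------------------------------------------------------
    mol <- tibble(idx = seq_len(n))
    mol$chrom <- ifelse(runif(n) < cfg$chrx_fraction, "chrX", "chr1")
    som_mols <- sample(which(mol$chrom == "chr1"), cfg$n_somatic)
    mol$somatic_idx <- NA_integer_
    mol$somatic_idx[som_mols] <- seq_len(cfg$n_somatic)
    mol$flen <- as.integer(pmin(pmax(
      round(rnorm(n, cfg$fragment_mean, cfg$fragment_sd)),
      cfg$fragment_min), cfg$fragment_max))

    mismerge <- runif(n) < cfg$mismerge_rate & mol$chrom == "chr1" &
      is.na(mol$somatic_idx)
    repeats <- refsim$features[refsim$features$type == "tandem_repeat", ]

    place_fragment <- function(i) {
      clen <- if (mol$chrom[i] == "chr1") len1 else lenx
      fl <- mol$flen[i]
      si <- mol$somatic_idx[i]
      if (!is.na(si)) {
        p <- somatic$pos[si]
        w <- nchar(somatic$ref[si])
        lo <- max(1L, p - fl + 25L + w)
        hi <- min(p - 25L, clen - fl + 1L)
        if (lo > hi) { lo <- hi <- max(1L, min(p - 25L, clen - fl + 1L)) }
        fs <- sample_between(lo, hi)
      } else if (mismerge[i] && nrow(repeats) > 0) {
        r <- repeats[sample.int(nrow(repeats), 1), ]
        center <- as.integer((r$start + r$end) / 2)
        fs <- min(max(1L, center - as.integer(fl / 2)), clen - fl + 1L)
      } else {
        fs <- sample.int(clen - fl + 1L, 1)
      }
      as.integer(c(fs, fs + fl - 1L))
    }
    bounds <- t(vapply(seq_len(n), place_fragment, integer(2)))
    mol$fs1 <- bounds[, 1]   # 1-based inclusive
    mol$fe1 <- bounds[, 2]

    ## --- barcode pairs ------------------------------------------------------
    colliders <- runif(n) < cfg$collision_rate
    colliders[1] <- FALSE
    b_left <- character(n); b_right <- character(n); pair_key <- character(n)
    used <- character(0)
    for (i in seq_len(n)) {
      if (colliders[i]) next
      repeat {
        bp <- sample(barcodes, 2)
        key <- paste(sort(bp), collapse = "+")
        if (!key %in% used) break
      }
      used <- c(used, key)
      b_left[i] <- bp[1]; b_right[i] <- bp[2]; pair_key[i] <- key
    }
    victims <- which(!colliders)
    for (i in which(colliders)) {
      v <- victims[sample.int(base::length(victims), 1)]
      if (mol$chrom[i] == mol$chrom[v] && mol$fs1[i] == mol$fs1[v] &&
          mol$fe1[i] == mol$fe1[v]) {
        shift <- if (mol$fs1[i] > 40L) -37L else 37L
        mol$fs1[i] <- mol$fs1[i] + shift
        mol$fe1[i] <- mol$fs1[i] + mol$flen[i] - 1L
      }
      b_left[i] <- b_left[v]; b_right[i] <- b_right[v]
      pair_key[i] <- pair_key[v]
    }
    mol$b_left <- b_left; mol$b_right <- b_right; mol$pair_key <- pair_key
    mol$collided <- pair_key %in% pair_key[colliders]

    ## --- per-molecule haplotypes and reads ----------------------------------
    rl <- cfg$read_length
    artifact_rows <- list()
    mismerge_rows <- list()
    read_rows <- vector("list", n)
    for (i in seq_len(n)) {
      contig <- reference[[mol$chrom[i]]]
      vars <- germline[
        germline$chrom == mol$chrom[i] &
          germline$pos >= mol$fs1[i] + 10L &
          germline$pos + nchar(germline$ref) - 1L <= mol$fe1[i] - 10L, ]
      vars <- vars[runif(nrow(vars)) < vars$vaf,
                   c("chrom", "pos", "ref", "alt")]
      si <- mol$somatic_idx[i]
      if (!is.na(si) && somatic$realized[si]) {
        vars <- bind_rows(vars, somatic[si, c("chrom", "pos", "ref", "alt")])
      }
      mm <- NULL
      if (mismerge[i]) {
        hit <- which(repeats$start >= mol$fs1[i] + 10L &
                       repeats$end <= mol$fe1[i] - 10L)
        if (base::length(hit) > 0) {
          r <- repeats[hit[1], ]
          u <- nchar(r$unit)
          del <- normalize_indel(
            mol$chrom[i], r$start - 1L,
            substr(contig, r$start - 1L, r$start - 1L + u),
            substr(contig, r$start - 1L, r$start - 1L), reference)
          if (nrow(vars) == 0 || all(abs(vars$pos - del$pos) >= 40L)) {
            mm <- tibble(chrom = del$chrom, pos = del$pos, ref = del$ref,
                         alt = del$alt, molecule_i = i)
            vars <- bind_rows(vars, mm[, c("chrom", "pos", "ref", "alt")])
          }
        }
      }
      art <- NULL
      if (mol$chrom[i] == "chr1" && runif(1) < cfg$artifact_rate) {
        for (try in 1:20) {
          p <- sample_between(mol$fs1[i] + 30L, mol$fe1[i] - 30L)
          cand <- random_indel_at(reference, mol$chrom[i], p)
          if (nrow(vars) == 0 || all(abs(vars$pos - cand$pos) >= 40L)) {
            art <- cand
            art$strand <- sample(c("+", "-"), 1)
            art$molecule_i <- i
            break
          }
        }
      }
      ov_start <- max(mol$fe1[i] - rl + 1L, mol$fs1[i])
      ov_end <- min(mol$fs1[i] + rl - 1L, mol$fe1[i])
      strand_tbl <- function(strand) {
        v <- vars
        if (!is.null(art) && art$strand == strand) {
          v <- bind_rows(v, art[, c("chrom", "pos", "ref", "alt")])
        }
        hap <- apply_variants_to_fragment(contig, mol$fs1[i], mol$fe1[i], v)
        nr <- cfg$reads_per_strand_min + rpois(1, cfg$reads_per_strand_lambda)
        tibble(
          read_id = sprintf("m%05d_%s%d", i,
                            if (strand == "+") "p" else "m", seq_len(nr)),
          chrom = mol$chrom[i],
          pos = mol$fs1[i],
          mapq = 60L,
          cigar = hap$cigar,
          seq = vapply(seq_len(nr), function(j)
            inject_substitutions(hap$seq, cfg$error_rate), character(1)),
          qual = vapply(seq_len(nr), function(j)
            phred_string(sample(30:40, nchar(hap$seq), replace = TRUE)),
            character(1)),
          reverse = strand == "-",
          bc1 = if (strand == "+") mol$b_left[i] else mol$b_right[i],
          bc2 = if (strand == "+") mol$b_right[i] else mol$b_left[i],
          merged = TRUE,
          overlap_start = ov_start,
          overlap_end = ov_end,
          ambiguous = isTRUE(mismerge[i] && !is.null(mm)),
          true_strand = strand,
          molecule_i = i
        )
      }
      read_rows[[i]] <- bind_rows(strand_tbl("+"), strand_tbl("-"))
      if (!is.null(art)) artifact_rows[[base::length(artifact_rows) + 1L]] <- art
      if (!is.null(mm)) mismerge_rows[[base::length(mismerge_rows) + 1L]] <- mm
    }
    reads <- list_rbind(read_rows)

    ## --- truth + bulk -------------------------------------------------------
    mol$molecule_id <- paste0(mol$chrom, ":",
                              pmin(mol$b_left, mol$b_right), "+",
                              pmax(mol$b_left, mol$b_right), ":",
                              mol$fs1 - 1L, "-", mol$fe1)
    somatic$molecule_id <- mol$molecule_id[som_mols]
    empty_art <- tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        strand = character(), molecule_id = character(),
                        type = character())
    artifacts <- if (base::length(artifact_rows) > 0) {
      a <- list_rbind(artifact_rows)
      a$molecule_id <- mol$molecule_id[a$molecule_i]
      a$type <- "single_strand"
      dplyr::select(a, -"molecule_i")
    } else empty_art
    mismerges <- if (base::length(mismerge_rows) > 0) {
      m <- list_rbind(mismerge_rows)
      m$molecule_id <- mol$molecule_id[m$molecule_i]
      m$strand <- "both"
      m$type <- "mismerge"
      dplyr::select(m, -"molecule_i")
    } else NULL
    collisions <- tibble(molecule_id = mol$molecule_id[mol$collided],
                         pair_key = mol$pair_key[mol$collided])

    bulk_tbl <- germline
    bulk_tbl$bulk_depth <- pmax(rpois(nrow(bulk_tbl), cfg$bulk_depth_mean), 10L)
    bulk_tbl$bulk_alt <- pmax(
      rbinom(nrow(bulk_tbl), bulk_tbl$bulk_depth, bulk_tbl$vaf), 1L)
    bulk <- bulk_evidence(
      dplyr::select(bulk_tbl, "chrom", "pos", "ref", "alt", "bulk_depth",
                    "bulk_alt"),
      default_depth = cfg$bulk_depth_mean)

    realized <- somatic[somatic$realized, , drop = FALSE]
    spectrum <- indel_spectrum(classify_indels(realized, reference)$channel)

    fastq <- make_raw_pairs(reads, rl, tn5_adapter())
    reads$molecule_i <- NULL

    structure(list(
      reference = reference,
      features = refsim$features,
      reads = reads,
      fastq = fastq,
      barcodes = barcodes,
      bulk = bulk,
      truth = list(germline = germline, somatic = somatic,
                   artifacts = bind_rows(artifacts, mismerges),
                   collisions = collisions, spectrum = spectrum),
      molecules = dplyr::select(mol, "molecule_id", "chrom", "fs1", "fe1",
                                "b_left", "b_right", "collided"),
      config = cfg
    ), class = "duplex_sim")
  })
}

# reconstruct raw paired-end reads: barcode + insert (truncated to the read
# length), adapter appended when the insert runs short. Mate 1 starts at the
# barcode its strand reads first.
make_raw_pairs <- function(reads, read_length, adapter) {
  frag <- reads$seq  # aligned orientation == fragment forward
  rc <- revcomp(frag)
  qf <- reads$qual
  qr <- rev_string(qf)
  plus <- reads$true_strand == "+"
  m1_seq <- ifelse(plus, frag, rc)
  m2_seq <- ifelse(plus, rc, frag)
  m1_q <- ifelse(plus, qf, qr)
  m2_q <- ifelse(plus, qr, qf)
  build <- function(bc, insert, q) {
    full <- paste0(bc, insert, adapter)
    fullq <- paste0(strrep("I", nchar(bc)), q, strrep("I", nchar(adapter)))
    list(seq = substr(full, 1L, read_length + nchar(bc)),
         qual = substr(fullq, 1L, read_length + nchar(bc)))
  }
  p1 <- build(reads$bc1, m1_seq, m1_q)
  p2 <- build(reads$bc2, m2_seq, m2_q)
  tibble(read_id = reads$read_id,
         seq1 = p1$seq, qual1 = p1$qual,
         seq2 = p2$seq, qual2 = p2$qual)
}

#' Sample indel calls from a known 83-channel distribution
#'
#' For each draw, a dedicated reference context realizing the drawn channel is
#' planted on a synthetic contig and the corresponding left-normalized allele
#' recorded; each constructed context is verified by re-classification (and
#' redrawn on the rare construction clash), so the recorded channel is exact.
#' Used to test spectrum recovery end-to-end.
#'
#' @param probs Numeric vector of 83 channel probabilities (or an
#'   `indel_spectrum` of counts), in [id83_channels()] order.
#' @param n Number of calls.
#' @param seed Integer seed.
#' @return List with `reference` (single synthetic contig `spec1`) and `calls`
#'   tibble (`chrom`, `pos`, `ref`, `alt`, `channel`).
#' @export
simulate_spectrum_calls <- function(probs, n, seed) {
  probs <- spectrum_counts(probs)
  stopifnot(length(probs) == 83, all(probs >= 0), sum(probs) > 0)
  channels <- id83_channels()
  with_seed(as.integer(seed), {
    drawn <- sample(channels, n, replace = TRUE, prob = probs)
    seg_len <- 130L
    segs <- character(n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      parsed <- strsplit(drawn[i], ":")[[1]]
      size <- as.integer(parsed[1]); kind <- parsed[2]
      ctx <- parsed[3]; stratum <- as.integer(parsed[4])
      repeat {
        built <- build_channel_context(size, kind, ctx, stratum, seg_len)
        tmp <- c(tmp = built$seq)
        ok <- tryCatch({
          nrm <- normalize_indel("tmp", built$pos, built$ref, built$alt, tmp)
          nrm$pos == built$pos && nrm$ref == built$ref &&
            nrm$alt == built$alt &&
            classify_indel("tmp", built$pos, built$ref, built$alt, tmp) ==
              drawn[i]
        }, error = function(e) FALSE)
        if (ok) break
      }
      segs[i] <- built$seq
      rows[[i]] <- tibble(pos = built$pos, ref = built$ref, alt = built$alt,
                          channel = drawn[i])
    }
    offsets <- cumsum(c(0L, nchar(segs)[-n]))
    calls <- list_rbind(rows)
    calls$pos <- as.integer(calls$pos + offsets)
    calls$chrom <- "spec1"
    list(reference = c(spec1 = paste(segs, collapse = "")),
         calls = dplyr::select(calls, "chrom", "pos", "ref", "alt", "channel"))
  })
}

# build one context segment realizing a channel; anchor placed mid-segment
build_channel_context <- function(size, kind, ctx, stratum, seg_len) {
  anchor_at <- 60L  # 1-based anchor offset within the segment
  if (ctx %in% c("C", "T")) {
    base <- ctx
    run <- if (kind == "Del") stratum + 1L else stratum
    others <- setdiff(c("A", "C", "G", "T"), base)
    left <- paste0(random_dna(anchor_at - 1L), sample(others, 1))
    right <- paste0(sample(others, 1),
                    random_dna(seg_len - anchor_at - run - 1L))
    seq <- paste0(left, strrep(base, run), right)
    pos <- anchor_at
    anchor <- substr(seq, pos, pos)
    if (kind == "Del") {
      list(seq = seq, pos = pos, ref = paste0(anchor, base), alt = anchor)
    } else {
      list(seq = seq, pos = pos, ref = anchor, alt = paste0(anchor, base))
    }
  } else if (ctx == "R") {
    L <- if (size == 5L) sample(5:6, 1) else size
    unit <- random_dna(L)
    k_exist <- if (kind == "Del") stratum + 1L else stratum
    mid <- strrep(unit, k_exist)
    seq <- paste0(random_dna(anchor_at), mid,
                  random_dna(seg_len - anchor_at - nchar(mid)))
    pos <- anchor_at
    anchor <- substr(seq, pos, pos)
    if (kind == "Del") {
      list(seq = seq, pos = pos, ref = paste0(anchor, unit), alt = anchor)
    } else {
      list(seq = seq, pos = pos, ref = anchor, alt = paste0(anchor, unit))
    }
  } else {
    # microhomology deletion: the deleted unit's prefix of length `stratum`
    # recurs immediately downstream, with no full adjacent copy
    L <- if (size == 5L) max(5L, stratum + 1L) else size
    unit <- random_dna(L)
    mh <- substr(unit, 1L, stratum)
    seq <- paste0(random_dna(anchor_at), unit, mh,
                  random_dna(seg_len - anchor_at - L - stratum))
    pos <- anchor_at
    anchor <- substr(seq, pos, pos)
    list(seq = seq, pos = pos, ref = paste0(anchor, unit), alt = anchor)
  }
}

#' Write a simulated dataset to disk
#'
#' Emits reference FASTA (+index), raw FASTQ pair, aligned duplex SAM and BAM
#' (+index), bulk evidence TSV, truth VCF of somatic alleles, truth tables as
#' TSV, the barcode list, and a YAML echo of the configuration.
#'
#' @param sim A [simulate_duplex()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    fq1 = file.path(dir, "duplex_R1.fastq"),
    fq2 = file.path(dir, "duplex_R2.fastq"),
    sam = file.path(dir, "duplex.sam"),
    bulk = file.path(dir, "bulk_pileup.tsv"),
    truth_vcf = file.path(dir, "truth_somatic.vcf"),
    truth_germline = file.path(dir, "truth_germline.tsv"),
    truth_artifacts = file.path(dir, "truth_artifacts.tsv"),
    truth_collisions = file.path(dir, "truth_collisions.tsv"),
    barcodes = file.path(dir, "barcodes.txt"),
    config = file.path(dir, "sim_config.yaml")
  )
  write_reference(sim$reference, paths$fasta)
  write_fastq(sim$fastq$read_id, sim$fastq$seq1, sim$fastq$qual1, paths$fq1)
  write_fastq(sim$fastq$read_id, sim$fastq$seq2, sim$fastq$qual2, paths$fq2)
  write_sam(sim$reads, sim$reference, paths$sam)
  paths$bam <- as.character(sam_to_bam(paths$sam))
  write_bulk_table(sim$bulk, paths$bulk)
  som <- sim$truth$somatic
  truth_vcf <- c(
    "##fileformat=VCFv4.2", "##source=duplexcall-sim",
    sprintf("##contig=<ID=%s,length=%d>", names(sim$reference),
            nchar(sim$reference)),
    "##INFO=<ID=MOL,Number=1,Type=String,Description=\"Originating molecule\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMOL=%s", som$chrom, som$pos, som$ref,
            som$alt, som$molecule_id))
  writeLines(truth_vcf, paths$truth_vcf)
  readr::write_tsv(sim$truth$germline, paths$truth_germline)
  readr::write_tsv(sim$truth$artifacts, paths$truth_artifacts)
  readr::write_tsv(sim$truth$collisions, paths$truth_collisions)
  writeLines(sim$barcodes, paths$barcodes)
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
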