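# Independent oracles. These deliberately re-derive results with naive,
# separately written code (own CIGAR parsing, own left-shift, exhaustive
# scans) so that the package implementation is checked against an
# implementation-independent path.

# --- brute-force per-read pileup recount ------------------------------------

oracle_parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

# naive left shift of a simple indel: slide the event left one base at a time
# while the sequence context permits an equivalent representation
oracle_left_shift <- function(contig, pos, ref, alt) {
  repeat {
    if (pos <= 1) break
    event <- if (nchar(ref) > nchar(alt)) substr(ref, 2, nchar(ref)) else
      substr(alt, 2, nchar(alt))
    L <- nchar(event)
    prev <- substr(contig, pos, pos)        # current anchor
    before <- substr(contig, pos - 1, pos - 1)
    # shifting left by one is valid iff the base entering the event window
    # equals the base leaving it (classic rotation property)
    last_ev <- substr(event, L, L)
    if (prev == "" || before == "") break
    if (last_ev != prev) break
    new_event <- paste0(prev, substr(event, 1, L - 1))
    pos <- pos - 1
    anchor <- substr(contig, pos, pos)
    if (nchar(ref) > nchar(alt)) {
      ref <- paste0(anchor, new_event); alt <- anchor
    } else {
      alt <- paste0(anchor, new_event); ref <- anchor
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

# exhaustive equivalence check: does deleting/inserting at (pos2, ref2, alt2)
# produce the same mutated sequence as (pos1, ref1, alt1)?
oracle_apply_edit <- function(contig, pos, ref, alt) {
  paste0(substr(contig, 1, pos - 1), alt,
         substr(contig, pos + nchar(ref), nchar(contig)))
}

# leftmost equivalent representation found by exhaustive scan over a window
oracle_leftmost <- function(contig, pos, ref, alt, window = 40) {
  target <- oracle_apply_edit(contig, pos, ref, alt)
  is_del <- nchar(ref) > nchar(alt)
  L <- abs(nchar(ref) - nchar(alt))
  best <- NULL
  for (p in max(1, pos - window):(pos + window)) {
    if (is_del) {
      r2 <- substr(contig, p, p + L)
      if (nchar(r2) < L + 1) next
      a2 <- substr(contig, p, p)
      if (oracle_apply_edit(contig, p, r2, a2) == target) {
        best <- list(pos = p, ref = r2, alt = a2); break
      }
    } else {
      a1 <- substr(contig, p, p)
      ins <- substr(alt, 2, nchar(alt))
      # try all insertions of length L at p that reproduce the target
      done <- FALSE
      for (rot in 0:(L - 1)) {
        cand_ins <- paste0(substr(ins, rot + 1, L), substr(ins, 1, rot))
        if (oracle_apply_edit(contig, p, a1, paste0(a1, cand_ins)) == target) {
          best <- list(pos = p, ref = a1, alt = paste0(a1, cand_ins))
          done <- TRUE; break
        }
      }
      if (done) break
    }
  }
  best
}

# full per-read recount of coverage and indel support
oracle_pileup <- function(reads, reference, min_mapq = 30, min_bq = 20) {
  cov <- list()   # "chrom strand" -> integer vector over the contig
  for (chrom in unique(reads$chrom)) {
    for (strand in c("+", "-")) {
      cov[[paste(chrom, strand)]] <- integer(nchar(reference[[chrom]]))
    }
  }
  alleles <- list()
  obs_at <- list()
  reads <- as.data.frame(reads)
  for (i in seq_len(nrow(reads))) {
    rd <- lapply(reads, `[`, i)
    if (rd$mapq < min_mapq) next
    strand <- if (rd$reverse) "-" else "+"
    ckey <- paste(rd$chrom, strand)
    contig <- reference[[rd$chrom]]
    pc <- oracle_parse_cigar(rd$cigar)
    qv <- utf8ToInt(rd$qual) - 33L
    r <- rd$pos; q <- 1L
    for (j in seq_along(pc$op)) {
      op <- pc$op[j]; l <- pc$len[j]
      if (op %in% c("M", "=", "X")) {
        cov[[ckey]][r:(r + l - 1L)] <- cov[[ckey]][r:(r + l - 1L)] + 1L
        r <- r + l; q <- q + l
      } else if (op == "S") {
        q <- q + l
      } else if (op == "I") {
        anchor <- r - 1L
        ins <- substr(rd$seq, q, q + l - 1L)
        ok <- q > 1L && q + l <= nchar(rd$seq) &&
          qv[q - 1L] >= min_bq && qv[q + l] >= min_bq
        if (ok && anchor >= rd$pos) {
          n <- oracle_left_shift(contig, anchor,
                                 substr(contig, anchor, anchor),
                                 paste0(substr(contig, anchor, anchor), ins))
          key <- paste(rd$chrom, n$pos, n$ref, n$alt, strand)
          alleles[[key]] <- (alleles[[key]] %||% 0L) + 1L
          okey <- paste(rd$chrom, n$pos, strand)
          obs_at[[okey]] <- (obs_at[[okey]] %||% 0L) + 1L
        }
        q <- q + l
      } else if (op == "D") {
        anchor <- r - 1L
        ok <- q > 1L && q <= nchar(rd$seq) &&
          qv[q - 1L] >= min_bq && qv[q] >= min_bq
        if (ok && anchor >= rd$pos) {
          n <- oracle_left_shift(contig, anchor,
                                 substr(contig, anchor, anchor + l),
                                 substr(contig, anchor, anchor))
          key <- paste(rd$chrom, n$pos, n$ref, n$alt, strand)
          alleles[[key]] <- (alleles[[key]] %||% 0L) + 1L
          okey <- paste(rd$chrom, n$pos, strand)
          obs_at[[okey]] <- (obs_at[[okey]] %||% 0L) + 1L
        }
        # deleted positions are still spanned by the read
        cov[[ckey]][r:(r + l - 1L)] <- cov[[ckey]][r:(r + l - 1L)] + 1L
        r <- r + l
      }
    }
  }
  list(cov = cov, alleles = alleles, obs_at = obs_at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent homopolymer run counter used against classify_indel strata
oracle_run_length <- function(contig, start, base) {
  n <- 0L
  while (start + n <= nchar(contig) &&
         substr(contig, start + n, start + n) == base) n <- n + 1L
  n
}
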