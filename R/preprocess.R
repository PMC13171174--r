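# Raw-read preprocessing: barcode extraction, adapter trimming, overlap
# merging. Operates on tibbles of read pairs (one row per pair) so the steps
# chain with the pipe; scalar workhorses are exported for direct use.

#' Extract terminal barcodes from raw read pairs
#'
#' The first `L` bases of each mate are matched against the reference barcode
#' list within `max_mismatch` Hamming mismatches; matched bases are removed
#' from the read. A pair is rejected when either mate is too short
#' (`too_short`) or matches no barcode (`no_match`). Because the reference
#' list keeps barcodes more than `2 * max_mismatch` apart, an ambiguous match
#' cannot occur, but it is still checked (`ambiguous_match`).
#'
#' @param pairs Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param ref A [barcode_ref()].
#' @return Input tibble with `bc1`, `bc2`, trimmed `seq*`/`qual*`, and
#'   `rejected` / `reject_reason` columns.
#' @export
extract_barcodes <- function(pairs, ref) {
  stopifnot(inherits(ref, "barcode_ref"))
  pairs <- as_tibble(pairs)
  L <- ref$length
  match_one <- function(seqs) {
    n <- length(seqs)
    # pad so short (to-be-rejected) reads still form a rectangular matrix
    prefix <- substr(paste0(seqs, strrep("N", L)), 1L, L)
    pm <- do.call(rbind, strsplit(prefix, ""))
    if (is.null(pm)) pm <- matrix(character(0), nrow = 0, ncol = L)
    hit <- rep(NA_integer_, n)
    nhit <- rep(0L, n)
    ok_len <- nchar(seqs) >= L + 1L
    for (j in seq_along(ref$barcodes)) {
      bc <- strsplit(ref$barcodes[j], "")[[1]]
      mm <- rowSums(pm != matrix(bc, nrow = n, ncol = L, byrow = TRUE))
      within <- ok_len & mm <= ref$max_mismatch
      nhit <- nhit + as.integer(within)
      hit[within & is.na(hit)] <- j
    }
    list(hit = hit, nhit = nhit, ok_len = ok_len)
  }
  m1 <- match_one(pairs$seq1)
  m2 <- match_one(pairs$seq2)
  reason <- rep(NA_character_, nrow(pairs))
  reason[m1$nhit > 1 | m2$nhit > 1] <- "ambiguous_match"
  reason[m1$nhit == 0 | m2$nhit == 0] <- "no_match"
  reason[!m1$ok_len | !m2$ok_len] <- "too_short"
  out <- pairs
  out$bc1 <- ifelse(is.na(reason), ref$barcodes[m1$hit], NA_character_)
  out$bc2 <- ifelse(is.na(reason), ref$barcodes[m2$hit], NA_character_)
  keep <- is.na(reason)
  out$seq1[keep] <- substr(pairs$seq1[keep], L + 1L, nchar(pairs$seq1[keep]))
  out$qual1[keep] <- substr(pairs$qual1[keep], L + 1L, nchar(pairs$qual1[keep]))
  out$seq2[keep] <- substr(pairs$seq2[keep], L + 1L, nchar(pairs$seq2[keep]))
  out$qual2[keep] <- substr(pairs$qual2[keep], L + 1L, nchar(pairs$qual2[keep]))
  out$rejected <- !keep
  out$reject_reason <- reason
  out
}

#' Trim a 3' sequencing adapter by exact suffix match
#'
#' Removes the longest 3' suffix of the read that exactly matches a prefix of
#' the adapter of length at least `min_match`; reads without such a suffix are
#' returned unchanged. Error-tolerant adapter alignment is deliberately not
#' attempted.
#'
#' @param seq,qual Character vectors of read sequences and Phred+33 quality
#'   strings (recycled together).
#' @param adapter Adapter sequence (read 3' ends run into its 5' end).
#' @param min_match Minimum suffix/prefix match length (>= 4, default 5).
#' @return List with trimmed `seq` and `qual` character vectors.
#' @export
trim_adapter <- function(seq, qual, adapter, min_match = 5L) {
  stopifnot(min_match >= 4)
  trim_one <- function(s) {
    n <- nchar(s)
    kmax <- min(n, nchar(adapter))
    if (kmax >= min_match) {
      for (k in kmax:min_match) {
        if (substr(s, n - k + 1L, n) == substr(adapter, 1L, k)) return(n - k)
      }
    }
    n
  }
  keep <- vapply(seq, trim_one, integer(1), USE.NAMES = FALSE)
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

#' Merge the overlapping ends of one read pair
#'
#' Mate 2 is reverse-complemented and every fragment layout giving an overlap
#' of at least `min_overlap` bases is scored by matching bases. The best
#' offset is accepted when its mismatch fraction is at most
#' `max_mismatch_rate`; within the overlap the higher-quality base wins and
#' keeps its quality (on agreement the maximum of the two qualities is kept,
#' the point of merging being improved base quality). The merge is flagged
#' `ambiguous` when a second offset scores at least 90% of the best offset's
#' match count — the signature of tandem repeats and microhomology at read
#' ends, consumed later by the merge-confound filter.
#'
#' @param seq1,qual1,seq2,qual2 One read pair (mate 2 in sequencing
#'   orientation).
#' @param min_overlap Minimum overlap length in bp (>= 10).
#' @param max_mismatch_rate Maximum mismatch fraction inside the overlap.
#' @return List with `merged` (logical), `seq`, `qual` (merged read, or `NULL`
#'   when not merged) and `record`, a one-row tibble with `merged`,
#'   `overlap_len`, `overlap_start_in_fragment` (0-based), `ambiguous`.
#' @export
merge_overlap <- function(seq1, qual1, seq2, qual2,
                          min_overlap = 10L, max_mismatch_rate = 0.1) {
  stopifnot(min_overlap >= 10)
  rc2 <- revcomp(seq2)
  rq2 <- rev_string(qual2)
  len1 <- nchar(seq1); len2 <- nchar(seq2)
  c1 <- strsplit(seq1, "")[[1]]
  c2 <- strsplit(rc2, "")[[1]]
  omax <- min(len1, len2)
  no_merge <- function() {
    list(merged = FALSE, seq = NULL, qual = NULL,
         record = tibble(merged = FALSE, overlap_len = 0L,
                         overlap_start_in_fragment = NA_integer_,
                         ambiguous = FALSE))
  }
  if (omax < min_overlap) return(no_merge())
  overlaps <- min_overlap:omax
  matches <- vapply(overlaps, function(o) {
    sum(c1[(len1 - o + 1L):len1] == c2[1:o])
  }, numeric(1))
  qualifying <- matches >= (1 - max_mismatch_rate) * overlaps
  if (!any(qualifying)) return(no_merge())
  best_i <- which(matches == max(matches[qualifying]) & qualifying)[1]
  o <- overlaps[best_i]
  # a merge is ambiguous when a second *qualifying* offset scores at least
  # 90% of the best offset's match count (repeat / microhomology signature);
  # non-qualifying offsets are chance matches, not merge alternatives
  ambiguous <- sum(qualifying & matches >= 0.9 * matches[best_i]) > 1L
  q1 <- phred_ints(qual1); q2 <- phred_ints(rq2)
  frag_len <- len1 + len2 - o
  ov1 <- (len1 - o + 1L):len1  # overlap indices in read 1
  ov2 <- 1:o                   # overlap indices in rc(read 2)
  agree <- c1[ov1] == c2[ov2]
  take2 <- !agree & q2[ov2] > q1[ov1]
  ov_base <- ifelse(take2, c2[ov2], c1[ov1])
  ov_q <- ifelse(agree, pmax(q1[ov1], q2[ov2]), ifelse(take2, q2[ov2], q1[ov1]))
  seq <- paste0(substr(seq1, 1L, len1 - o), paste(ov_base, collapse = ""),
                substr(rc2, o + 1L, len2))
  qual <- paste0(substr(qual1, 1L, len1 - o), phred_string(ov_q),
                 substr(rq2, o + 1L, len2))
  stopifnot(nchar(seq) == frag_len)
  list(merged = TRUE, seq = seq, qual = qual,
       record = tibble(merged = TRUE, overlap_len = as.integer(o),
                       overlap_start_in_fragment = as.integer(len1 - o),
                       ambiguous = ambiguous))
}

#' Preprocess a tibble of raw read pairs
#'
#' Chains barcode extraction, adapter trimming of both mates, and overlap
#' merging. Merged reads carry their barcodes in the read name as
#' `<id>:BC:<bc1>+<bc2>`, the convention consumed by the alignment adapter.
#'
#' @param pairs Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param barcodes A [barcode_ref()].
#' @param adapter Adapter sequence for 3' trimming.
#' @param min_match Minimum adapter match length.
#' @param min_overlap,max_mismatch_rate Merge parameters (see
#'   [merge_overlap()]).
#' @return Tibble with one row per input pair: `read_id`, `name`, `bc1`,
#'   `bc2`, `merged`, `overlap_len`, `overlap_start_in_fragment`, `ambiguous`,
#'   `seq`, `qual` (merged read; `NA` when unmerged), the trimmed mate columns,
#'   and rejection bookkeeping.
#' @export
preprocess_reads <- function(pairs, barcodes, adapter = tn5_adapter(),
                             min_match = 5L, min_overlap = 10L,
                             max_mismatch_rate = 0.1) {
  ex <- extract_barcodes(pairs, barcodes)
  keep <- !ex$rejected
  t1 <- trim_adapter(ex$seq1[keep], ex$qual1[keep], adapter, min_match)
  t2 <- trim_adapter(ex$seq2[keep], ex$qual2[keep], adapter, min_match)
  ex$seq1[keep] <- t1$seq; ex$qual1[keep] <- t1$qual
  ex$seq2[keep] <- t2$seq; ex$qual2[keep] <- t2$qual
  merged <- pmap(
    list(ex$seq1, ex$qual1, ex$seq2, ex$qual2, ex$rejected),
    function(s1, q1, s2, q2, rej) {
      if (rej) {
        return(list(merged = FALSE, seq = NA_character_, qual = NA_character_,
                    record = tibble(merged = FALSE, overlap_len = 0L,
                                    overlap_start_in_fragment = NA_integer_,
                                    ambiguous = FALSE)))
      }
      m <- merge_overlap(s1, q1, s2, q2, min_overlap, max_mismatch_rate)
      if (!m$merged) { m$seq <- NA_character_; m$qual <- NA_character_ }
      m
    }
  )
  rec <- list_rbind(map(merged, "record"))
  ex$merged <- rec$merged
  ex$overlap_len <- rec$overlap_len
  ex$overlap_start_in_fragment <- rec$overlap_start_in_fragment
  ex$ambiguous <- rec$ambiguous
  ex$seq <- map_chr(merged, function(m) m$seq %||% NA_character_)
  ex$qual <- map_chr(merged, function(m) m$qual %||% NA_character_)
  ex$name <- ifelse(ex$rejected, NA_character_,
                    paste0(ex$read_id, ":BC:", ex$bc1, "+", ex$bc2))
  ex
}

#' Standard Tn5 mosaic-end sequencing adapter
#'
#' The 19-bp mosaic-end sequence that Tn5-tagmented libraries read into at
#' short fragments.
#'
#' @return Character scalar.
#' @export
tn5_adapter <- function() "CTGTCTCTTATACACATCT"
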