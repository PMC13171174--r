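# In-code fixtures: tiny references and hand-built aligned reads.

# local copies of small sequence utilities so tests do not reach into the
# package's internals
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rev_string <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

fixture_reference <- function() {
  c(chr1 = paste0("ACGTACGTGG", "CAAATGGCTA", "GTTTTTTGCA", "ACGGCATCGA",
                  "TTACGGATCC", "GATCGATCGA", "TACGCATGCA", "GGCCGGCCAA",
                  "CTCTCTCTCT", "ACGGTCAGTT"),
    chrX = "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT")
}

# one aligned merged read covering [pos, pos + ref span)
fixture_read <- function(id, chrom, pos, cigar, seq, qual = NULL, mapq = 60L,
                         reverse = FALSE, bc1 = "AAAACCCC", bc2 = "GGGGTTTT",
                         merged = TRUE, overlap_start = NA_integer_,
                         overlap_end = NA_integer_, ambiguous = FALSE) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  tibble::tibble(read_id = id, chrom = chrom, pos = as.integer(pos),
                 mapq = as.integer(mapq), cigar = cigar, seq = seq,
                 qual = qual, reverse = reverse, bc1 = bc1, bc2 = bc2,
                 merged = merged, overlap_start = as.integer(overlap_start),
                 overlap_end = as.integer(overlap_end), ambiguous = ambiguous)
}

# a duplex family carrying one shared cigar/sequence per strand
fixture_family <- function(reference, chrom = "chr1", pos = 11L, flen = 60L,
                           n_plus = 3L, n_minus = 3L, cigar = NULL,
                           seq = NULL, bc1 = "AAAACCCC", bc2 = "GGGGTTTT") {
  contig <- reference[[chrom]]
  if (is.null(cigar)) cigar <- sprintf("%dM", flen)
  if (is.null(seq)) seq <- substr(contig, pos, pos + flen - 1L)
  rows <- list()
  for (j in seq_len(n_plus)) {
    rows[[length(rows) + 1L]] <- fixture_read(
      sprintf("f_p%d", j), chrom, pos, cigar, seq, reverse = FALSE,
      bc1 = bc1, bc2 = bc2)
  }
  for (j in seq_len(n_minus)) {
    rows[[length(rows) + 1L]] <- fixture_read(
      sprintf("f_m%d", j), chrom, pos, cigar, seq, reverse = TRUE,
      bc1 = bc2, bc2 = bc1)
  }
  dplyr::bind_rows(rows)
}

allele_keys <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
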