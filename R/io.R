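# Standard-format I/O. FASTA/FASTQ through Biostrings, BAM through Rsamtools
# (the simulator emits SAM text and converts), BED through rtracklayer,
# tables through readr. The VCF writer is a plain-text emitter for the
# package's candidate/call vocabulary.

#' Read a FASTQ pair into a read-pair tibble
#'
#' @param fq1,fq2 Paths to mate-1 and mate-2 FASTQ files (Phred+33).
#' @return Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_duplex_fastq <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  stopifnot(length(r1) == length(r2))
  id1 <- sub("\\s.*$", "", names(r1))
  tibble(read_id = id1,
         seq1 = unname(as.character(r1)),
         qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
         seq2 = unname(as.character(r2)),
         qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}

#' Write a FASTQ pair (or single merged FASTQ)
#'
#' @param ids,seqs,quals Read names, sequences, quality strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Write a reference genome as FASTA (with .fai index)
#'
#' @param reference Named character vector or DNAStringSet.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  x <- Biostrings::DNAStringSet(as_reference(reference))
  Biostrings::writeXStringSet(x, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

duplex_tag_defs <- c(XB = "Z", XC = "Z", XM = "i", XO = "i", XA = "i", XP = "i")

#' Write aligned duplex reads as SAM text
#'
#' Emits coordinate-sorted SAM with the duplex tags produced by the alignment
#' adapter: `XB`/`XC` (barcodes as sequenced from mate 1 / mate 2), `XM`
#' (1 = mates merged), `XO` (overlap length on the reference), `XA`
#' (1 = ambiguous merge), `XP` (0-based overlap start offset within the
#' fragment; together with `XO` this gives the overlap interval that the
#' merge-confound filter needs).
#'
#' @param reads Aligned read tibble (`read_id`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `reverse`, `bc1`, `bc2`, `merged`,
#'   `overlap_start`, `overlap_end`, `ambiguous`).
#' @param reference Reference genome (for `@SQ` header lines).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  reference <- as_reference(reference)
  reads <- arrange(as_tibble(reads), match(.data$chrom, names(reference)),
                   .data$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)),
             con)
  flag <- ifelse(reads$reverse, 16L, 0L)
  xo <- ifelse(is.na(reads$overlap_start), 0L,
               reads$overlap_end - reads$overlap_start + 1L)
  xp <- ifelse(is.na(reads$overlap_start), 0L,
               reads$overlap_start - reads$pos)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tXB:Z:%s\tXC:Z:%s\tXM:i:%d\tXO:i:%d\tXA:i:%d\tXP:i:%d",
    reads$read_id, flag, reads$chrom, reads$pos, reads$mapq, reads$cigar,
    reads$seq, reads$qual, reads$bc1, reads$bc2, as.integer(reads$merged),
    xo, as.integer(reads$ambiguous), xp)
  writeLines(lines, con)
  invisible(path)
}

#' Convert SAM text to an indexed BAM
#'
#' @param sam Path to SAM.
#' @param bam Output BAM path (without `.bam` suffix handling; default
#'   replaces the extension).
#' @return BAM path, invisibly.
#' @export
sam_to_bam <- function(sam, bam = sub("\\.sam$", ".bam", sam)) {
  dest <- sub("\\.bam$", "", bam)
  out <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  invisible(out)
}

#' Read aligned duplex reads from BAM
#'
#' Expects the tag contract documented in [write_sam()]. Secondary and
#' supplementary alignments are discarded.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @return Aligned read tibble compatible with [group_molecules()].
#' @export
read_duplex_bam <- function(bam) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = names(duplex_tag_defs),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  tg <- x$tag
  xo <- tg$XO %||% rep(0L, length(x$qname))
  xp <- tg$XP %||% rep(0L, length(x$qname))
  merged <- (tg$XM %||% rep(0L, length(x$qname))) == 1L
  ov_start <- ifelse(merged & xo > 0L, x$pos + xp, NA_integer_)
  tibble(
    read_id = x$qname,
    chrom = as.character(x$rname),
    pos = x$pos,
    mapq = x$mapq,
    cigar = x$cigar,
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    reverse = bitwAnd(x$flag, 16L) > 0L,
    bc1 = tg$XB, bc2 = tg$XC,
    merged = merged,
    overlap_start = as.integer(ov_start),
    overlap_end = as.integer(ifelse(is.na(ov_start), NA, ov_start + xo - 1L)),
    ambiguous = (tg$XA %||% rep(0L, length(x$qname))) == 1L
  )
}

#' Read a genome mask (BED of high-confidence regions)
#'
#' @param path BED path (0-based half-open).
#' @return `GRanges` of mask intervals.
#' @export
read_genome_mask <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read a population allele-frequency table
#'
#' Tab-delimited `chrom pos ref alt af` (gnomAD-style extract); `pos` is the
#' 1-based anchor of the left-normalized allele.
#'
#' @param path TSV path (may be gzipped).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
read_af_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    af = readr::col_double()))
}

#' Read / write a bulk evidence table
#'
#' @param path TSV path.
#' @param bulk A [bulk_evidence()] table.
#' @return `read_bulk_table()` returns a [bulk_evidence()] table.
#' @export
read_bulk_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    bulk_depth = readr::col_integer(), bulk_alt = readr::col_integer()))
  bulk_evidence(x, default_depth = 30L)
}

#' @rdname read_bulk_table
#' @export
write_bulk_table <- function(bulk, path) {
  readr::write_tsv(as_tibble(bulk), path)
  invisible(path)
}

vcf_header <- function(reference, threshold = NULL, single_track = FALSE) {
  reference <- as_reference(reference)
  c(
    "##fileformat=VCFv4.2",
    "##source=duplexcall",
    if (!is.null(threshold)) sprintf("##duplex_threshold=%s", format(threshold)),
    if (single_track) "##duplex_track=SINGLE_STRAND",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "##INFO=<ID=NT,Number=1,Type=Integer,Description=\"Total alternative-allele read support within the molecule\">",
    "##INFO=<ID=NP,Number=1,Type=Integer,Description=\"Plus-strand alternative-allele read support\">",
    "##INFO=<ID=NM,Number=1,Type=Integer,Description=\"Minus-strand alternative-allele read support\">",
    "##INFO=<ID=SD,Number=1,Type=String,Description=\"Strandedness of the call: DOUBLE (consensus from both strands) or SINGLE\">",
    "##INFO=<ID=MOL,Number=1,Type=String,Description=\"Molecule key (chrom:barcodes:fragment)\">",
    "##FILTER=<ID=germline,Description=\"Allele detected in matched bulk WGS\">",
    "##FILTER=<ID=low_bulk_depth,Description=\"Insufficient bulk depth to exclude germline origin\">",
    "##FILTER=<ID=merge_confound,Description=\"Indel support confined to ambiguous read-merge overlaps or repeat tract spanning a merge boundary\">",
    "##FILTER=<ID=near_germline,Description=\"Distinct germline indel within the adjacency window\">",
    "##FILTER=<ID=cutsite_inconsistent,Description=\"Barcode pair seen with inconsistent Tn5 cut sites (barcode collision)\">",
    "##FILTER=<ID=common_variant,Description=\"Population allele frequency at or above cutoff\">",
    "##FILTER=<ID=masked,Description=\"Outside the supplied high-confidence genome mask\">",
    "##FILTER=<ID=not_evaluable,Description=\"Merge metadata missing; merge-confound filter not evaluable (advisory)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
}

#' Write candidate or final calls as VCF 4.2
#'
#' Double-strand calls go to `path`; single-strand calls, when present, go to
#' a companion file with suffix `.single_strand.vcf`. Output is deterministic
#' (fixed sort order, no timestamps).
#'
#' @param calls Candidate tibble or [finalize_calls()] output.
#' @param reference Reference genome (for contig header lines).
#' @param path Output VCF path.
#' @param threshold Optional [call_threshold()] recorded in the header.
#' @return Named character vector of the file(s) written, invisibly.
#' @export
write_somatic_vcf <- function(calls, reference, path, threshold = NULL) {
  calls <- as_tibble(calls)
  if (!"FILTER" %in% names(calls)) {
    calls$FILTER <- ifelse(calls$filters == "", "PASS", calls$filters)
  }
  if (!"track" %in% names(calls)) {
    calls$track <- ifelse(calls$strandedness == "DOUBLE", "DOUBLE",
                          "SINGLE_STRAND")
  }
  emit <- function(x, p, single_track) {
    lines <- vcf_header(reference, threshold, single_track)
    if (nrow(x) > 0) {
      x <- arrange(x, match(.data$chrom, names(as_reference(reference))),
                   .data$pos, .data$ref, .data$alt, .data$molecule_id)
      info <- sprintf("NT=%d;NP=%d;NM=%d;SD=%s;MOL=%s", x$n_total, x$n_plus,
                      x$n_minus, x$strandedness, x$molecule_id)
      lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                                x$chrom, x$pos, x$ref, x$alt, x$FILTER, info))
    }
    writeLines(lines, p)
    p
  }
  out <- c(main = emit(calls[calls$track == "DOUBLE", , drop = FALSE], path,
                       FALSE))
  singles <- calls[calls$track == "SINGLE_STRAND", , drop = FALSE]
  if (nrow(singles) > 0) {
    sp <- sub("\\.vcf$", "", path)
    sp <- paste0(sp, ".single_strand.vcf")
    out <- c(out, single = emit(singles, sp, TRUE))
  }
  invisible(out)
}
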