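# Small shared helpers. Coordinates are 1-based inclusive inside the package;
# 0-based half-open appears only in BED parsing and fragment bookkeeping that
# mirrors BAM conventions.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rev_string <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

phred_ints <- function(qual) utf8ToInt(qual) - 33L

phred_string <- function(q) intToUtf8(as.integer(q) + 33L)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Is a contig name a sex chromosome?
#'
#' Matches `X`, `Y`, `chrX`, `chrY` (case-insensitive). Candidates on these
#' contigs are excluded from somatic calling.
#'
#' @param chrom Character vector of contig names.
#' @return Logical vector.
#' @export
is_sex_chrom <- function(chrom) {
  grepl("^(chr)?[XY]$", chrom, ignore.case = TRUE)
}

#' Coerce a reference genome to the internal representation
#'
#' The package works on a named character vector (one element per contig).
#' Accepts a `Biostrings::DNAStringSet`, a path to a FASTA file, or an
#' already-converted named character vector.
#'
#' @param x Reference genome in any accepted form.
#' @return Named character vector of contig sequences.
#' @export
as_reference <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) && is.null(names(x))) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x) && !is.null(names(x))) {
    return(x)
  }
  abort("reference must be a named character vector, DNAStringSet, or FASTA path")
}

ref_slice <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference)) abort(paste0("unknown contig: ", chrom))
  contig <- reference[[chrom]]
  if (start < 1 || end > nchar(contig)) abort("region outside reference")
  substr(contig, start, end)
}

# consecutive copies of `unit` in contig starting at 1-based position `start`
count_unit_copies <- function(contig, start, unit) {
  u <- nchar(unit)
  n <- nchar(contig)
  k <- 0L
  while (start + (k + 1L) * u - 1L <= n &&
         substr(contig, start + k * u, start + (k + 1L) * u - 1L) == unit) {
    k <- k + 1L
  }
  k
}
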