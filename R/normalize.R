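#' Left-normalize indel alleles against a reference
#'
#' Shifts each indel to its leftmost equivalent representation and reduces it
#' to the minimal VCF anchor form (`ref` and `alt` share their first base and
#' exactly one of them has length 1 for a simple indel). Consistent
#' normalization is what makes duplex candidates, bulk germline evidence and
#' population-AF lookups comparable.
#'
#' @param alleles Data frame with columns `chrom`, `pos` (1-based anchor),
#'   `ref`, `alt`.
#' @param reference Reference genome (see [as_reference()]).
#' @return The input tibble with `pos`, `ref`, `alt` normalized and derived
#'   columns `kind` ("INS"/"DEL") and `length` added.
#' @export
normalize_indels <- function(alleles, reference) {
  reference <- as_reference(reference)
  alleles <- as_tibble(alleles)
  norm <- pmap(
    list(alleles$chrom, alleles$pos, alleles$ref, alleles$alt),
    function(chrom, pos, ref, alt) normalize_indel(chrom, pos, ref, alt, reference)
  )
  alleles$pos <- map_int(norm, "pos")
  alleles$ref <- map_chr(norm, "ref")
  alleles$alt <- map_chr(norm, "alt")
  alleles$kind <- ifelse(nchar(alleles$alt) > nchar(alleles$ref), "INS", "DEL")
  alleles$length <- abs(nchar(alleles$alt) - nchar(alleles$ref))
  alleles
}

#' Left-normalize a single indel
#'
#' @inheritParams normalize_indels
#' @param chrom,pos,ref,alt One VCF-style allele.
#' @return List with elements `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_indel <- function(chrom, pos, ref, alt, reference) {
  reference <- as_reference(reference)
  contig <- reference[[chrom]]
  if (is.null(contig)) abort(paste0("unknown contig: ", chrom))
  if (ref == alt) abort("ref and alt are identical")
  if (substr(contig, pos, pos + nchar(ref) - 1L) != ref) {
    abort("allele inconsistent with reference")
  }
  # right-trim shared suffix, pulling in the preceding reference base whenever
  # an allele would otherwise empty; then left-trim shared prefix
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn == 0 || an == 0 || substr(ref, rn, rn) != substr(alt, an, an)) break
    if (rn == 1L || an == 1L) {
      if (pos == 1L) break
      pb <- substr(contig, pos - 1L, pos - 1L)
      ref <- paste0(pb, ref)
      alt <- paste0(pb, alt)
      pos <- pos - 1L
      rn <- rn + 1L; an <- an + 1L
    }
    ref <- substr(ref, 1L, rn - 1L)
    alt <- substr(alt, 1L, an - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

allele_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
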