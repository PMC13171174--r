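# 83-channel indel classification (COSMIC ID83 convention) and the
# cosine-similarity benchmarking layer built on it.

#' Canonical 83-channel indel classification scheme
#'
#' Returns the channel labels in canonical order. Labels follow the
#' `<size>:<Del|Ins>:<context>:<stratum>` convention: 1-bp indels are stratified
#' by the pyrimidine base (`C`/`T`) and homopolymer context, longer indels by
#' adjacent repeat-unit count (`R`) and deletions additionally by flanking
#' microhomology length (`M`). Size and strata are capped at 5 (i.e. "5+").
#'
#' @return Character vector of 83 channel labels.
#' @export
id83_channels <- function() {
  one_bp <- unlist(lapply(c("Del", "Ins"), function(k)
    unlist(lapply(c("C", "T"), function(b) sprintf("1:%s:%s:%d", k, b, 0:5)))))
  rep_del <- unlist(lapply(2:5, function(L) sprintf("%d:Del:R:%d", L, 0:5)))
  rep_ins <- unlist(lapply(2:5, function(L) sprintf("%d:Ins:R:%d", L, 0:5)))
  mh <- c(
    "2:Del:M:1",
    sprintf("3:Del:M:%d", 1:2),
    sprintf("4:Del:M:%d", 1:3),
    sprintf("5:Del:M:%d", 1:5)
  )
  c(one_bp, rep_del, rep_ins, mh)
}

#' Classify indels into the 83-channel spectrum
#'
#' Alleles must be left-normalized ([normalize_indels()]) and at least 50 bp of
#' reference context must be available on both sides of the event; a truncated
#' context window raises `context_unavailable`.
#'
#' @param alleles Data frame with `chrom`, `pos`, `ref`, `alt` (simple indels).
#' @param reference Reference genome (see [as_reference()]).
#' @return Input tibble with a `channel` column added.
#' @export
classify_indels <- function(alleles, reference) {
  reference <- as_reference(reference)
  alleles <- as_tibble(alleles)
  alleles$channel <- pmap_chr_safe(
    list(alleles$chrom, alleles$pos, alleles$ref, alleles$alt),
    function(chrom, pos, ref, alt) classify_indel(chrom, pos, ref, alt, reference)
  )
  alleles
}

pmap_chr_safe <- function(l, f) {
  vapply(seq_along(l[[1]]), function(i) {
    f(l[[1]][i], l[[2]][i], l[[3]][i], l[[4]][i])
  }, character(1))
}

#' Classify one indel
#'
#' @inheritParams classify_indels
#' @param chrom,pos,ref,alt One left-normalized simple indel.
#' @return Channel label (scalar character).
#' @export
classify_indel <- function(chrom, pos, ref, alt, reference) {
  reference <- as_reference(reference)
  contig <- reference[[chrom]]
  if (is.null(contig)) abort(paste0("unknown contig: ", chrom))
  is_del <- nchar(ref) > nchar(alt)
  event <- if (is_del) substr(ref, 2L, nchar(ref)) else substr(alt, 2L, nchar(alt))
  L <- nchar(event)
  if (min(nchar(ref), nchar(alt)) != 1L || L < 1L) {
    abort("not a simple anchored indel; normalize first")
  }
  if (pos - 50L < 1L || pos + nchar(ref) - 1L + 50L > nchar(contig)) {
    abort("context_unavailable")
  }
  size <- min(L, 5L)
  if (L == 1L) {
    base <- event
    if (base %in% c("A", "G")) base <- chartr("AG", "TC", base)
    # homopolymer length: existing copies of the base to the right of the
    # anchor (for a deletion this includes the deleted base itself)
    run <- count_unit_copies(contig, pos + 1L, event)
    stratum <- if (is_del) min(run, 6L) - 1L else min(run, 5L)
    return(sprintf("1:%s:%s:%d", if (is_del) "Del" else "Ins", base, stratum))
  }
  if (!is_del) {
    k <- count_unit_copies(contig, pos + 1L, event)
    return(sprintf("%d:Ins:R:%d", size, min(k, 5L)))
  }
  # deletion >= 2 bp: additional adjacent full copies downstream of the
  # deleted block (left-normalization rules out upstream copies)
  after <- pos + 1L + L
  k <- count_unit_copies(contig, after, event)
  if (k >= 1L) {
    return(sprintf("%d:Del:R:%d", size, min(k, 5L)))
  }
  mh <- 0L
  for (l in seq_len(L - 1L)) {
    if (substr(contig, after, after + l - 1L) == substr(event, 1L, l)) mh <- l
  }
  if (mh >= 1L) {
    return(sprintf("%d:Del:M:%d", size, min(mh, 5L)))
  }
  sprintf("%d:Del:R:0", size)
}

#' Build an 83-channel indel spectrum
#'
#' @param channels Character vector of channel labels (e.g. the `channel`
#'   column of [classify_indels()] output), or a data frame holding one.
#' @return A tibble of class `indel_spectrum` with columns `channel`
#'   (factor over the 83 canonical levels) and `count`.
#' @export
indel_spectrum <- function(channels) {
  if (is.data.frame(channels)) channels <- channels$channel
  levels <- id83_channels()
  bad <- setdiff(unique(channels), levels)
  if (length(bad) > 0) abort(paste0("unknown channel(s): ", paste(bad, collapse = ", ")))
  counts <- table(factor(channels, levels = levels))
  out <- tibble(channel = factor(levels, levels = levels),
                count = as.integer(counts))
  class(out) <- c("indel_spectrum", class(out))
  out
}

spectrum_counts <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("channel", "count") %in% names(x)))
    x <- x[match(id83_channels(), as.character(x$channel)), ]
    v <- x$count
    v[is.na(v)] <- 0
    return(as.numeric(v))
  }
  as.numeric(x)
}

#' Cosine similarity between two indel spectra
#'
#' Normalized dot product; 1 for identical shape, 0 for orthogonal spectra.
#' Scale-invariant, so raw counts and normalized frequencies give the same
#' value.
#'
#' @param s1,s2 `indel_spectrum` tibbles or plain non-negative numeric vectors
#'   of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(s1, s2) {
  v1 <- spectrum_counts(s1)
  v2 <- spectrum_counts(s2)
  stopifnot(length(v1) == length(v2))
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) abort("empty_spectrum")
  sum(v1 * v2) / (n1 * n2)
}

#' Bootstrap cosine similarities against reference and control spectra
#'
#' Resamples the observed calls with replacement and recomputes the cosine
#' similarity of the resampled spectrum against the reference spectrum and
#' against each (biologically unrelated) negative-control spectrum, reporting
#' percentile 95% confidence intervals. A call set genuinely drawn from the
#' reference spectrum should sit above the upper CI bound of every control.
#'
#' @param channels Per-call channel labels (vector or data frame with a
#'   `channel` column). At least 10 calls are required.
#' @param reference_spectrum `indel_spectrum` (or numeric vector) to benchmark
#'   against.
#' @param control_spectra Named list of control spectra (may be empty).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Tibble with one row per spectrum (`reference` first): `spectrum`,
#'   `observed`, `ci_lo`, `ci_hi`, `n_boot`.
#' @export
bootstrap_similarity <- function(channels, reference_spectrum,
                                 control_spectra = list(),
                                 n_boot = 1000, seed) {
  if (is.data.frame(channels)) channels <- as.character(channels$channel)
  channels <- as.character(channels)
  if (length(channels) < 10) abort("insufficient_calls")
  if (n_boot < 100) abort("n_boot must be >= 100")
  if (missing(seed)) abort("seed is required")
  targets <- c(list(reference = reference_spectrum), control_spectra)
  tvecs <- lapply(targets, spectrum_counts)
  obs <- vapply(tvecs, function(v) cosine_similarity(indel_spectrum(channels), v),
                numeric(1))
  sims <- with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      res <- sample(channels, length(channels), replace = TRUE)
      sp <- indel_spectrum(res)
      vapply(tvecs, function(v) cosine_similarity(sp, v), numeric(1))
    }, numeric(length(tvecs)))
  })
  sims <- matrix(sims, nrow = length(tvecs))
  tibble(
    spectrum = names(targets),
    observed = unname(obs),
    ci_lo = apply(sims, 1, quantile, probs = 0.025, names = FALSE),
    ci_hi = apply(sims, 1, quantile, probs = 0.975, names = FALSE),
    n_boot = as.integer(n_boot)
  )
}

#' Down-sample a dataset at the molecule level
#'
#' Retains each molecule independently with probability `fraction`, keeping the
#' duplex structure (both strands and all reads of a retained molecule) intact.
#' Used for sequencing-depth robustness experiments.
#'
#' @param reads Tibble carrying a `molecule_id` column (e.g. the output of
#'   [group_molecules()]), or any tibble with one row per molecule.
#' @param fraction Retention probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return The input tibble restricted to retained molecules.
#' @export
downsample_molecules <- function(reads, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!"molecule_id" %in% names(reads)) abort("reads must carry a molecule_id column")
  if (fraction == 1) return(reads)
  ids <- unique(reads$molecule_id)
  keep <- with_seed(as.integer(seed), runif(length(ids)) < fraction)
  dplyr::filter(reads, .data$molecule_id %in% ids[keep])
}

#' Write / read a spectrum as TSV
#'
#' Two columns: `channel`, `count`, in canonical channel order.
#'
#' @param spectrum `indel_spectrum` tibble.
#' @param path File path.
#' @return `read_spectrum()` returns an `indel_spectrum` tibble.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(tibble(channel = as.character(spectrum$channel),
                          count = spectrum$count), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    channel = readr::col_character(), count = readr::col_integer()
  ))
  sp <- indel_spectrum(rep(x$channel, x$count))
  sp
}
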