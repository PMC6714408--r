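#' Split overlapping CNV calls at all observed boundaries
#'
#' Implements the multi-sample segmentation step: within each chromosome,
#' every distinct call start and end observed in the cohort becomes a cut
#' point, and the union of call footprints is partitioned into maximal
#' intervals between consecutive cut points. Each resulting segment records
#' every sample's copy number over it (the copy number of the overlapping
#' call, or 2 where the sample has no call). Regions covered by no call
#' produce no segments. Coordinates are 1-based inclusive throughout;
#' segment length is `end - start + 1`.
#'
#' Because segments are the disjoint refinement of the calls, every call is
#' a union of whole segments and each sample's copy number is constant over
#' any segment.
#'
#' @param calls calls data.frame (`sample_id`, `chromosome`, `start`,
#'   `end`, `copy_number`).
#' @param sample_ids character vector of all cohort samples; must contain
#'   every sample appearing in `calls`. Samples with no calls get copy
#'   number 2 everywhere.
#' @return A `segment_matrix`: list with `segments` (data.frame
#'   `segment_id`, `chromosome`, `start`, `end`, `length`,
#'   `n_supporting_boundaries`), `cn` (integer matrix, samples x segments),
#'   `sample_ids`, and per-segment annotations `class`, `carrier_freq`,
#'   `del_carrier_freq`, `hwe_p`.
#' @examples
#' calls <- data.frame(sample_id = c("A", "B"), chromosome = "1",
#'                     start = c(100, 150), end = c(200, 250),
#'                     copy_number = c(1L, 1L))
#' sm <- segment_cnvs(calls, c("A", "B"))
#' sm$segments[, c("start", "end")]  # 100-149, 150-200, 201-250
#' @export
segment_cnvs <- function(calls, sample_ids = unique(calls$sample_id)) {
  if (!all(calls$sample_id %in% sample_ids))
    stop("sample_ids must contain every sample present in calls")
  if (nrow(calls) == 0)
    return(new_segment_matrix(empty_segments(), matrix(2L, length(sample_ids), 0),
                              sample_ids))
  if (any(calls$start > calls$end)) stop("call with start > end")
  if (any(calls$copy_number == 2L)) stop("calls must have copy_number != 2")

  gr <- GenomicRanges::GRanges(calls$chromosome,
                               IRanges::IRanges(calls$start, calls$end))
  seg <- GenomicRanges::disjoin(gr)
  seg <- GenomicRanges::sort(seg)

  hits <- GenomicRanges::findOverlaps(gr, seg)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  n_seg <- length(seg)
  cn <- matrix(2L, nrow = length(sample_ids), ncol = n_seg,
               dimnames = list(sample_ids, NULL))
  row_of <- match(calls$sample_id, sample_ids)
  for (k in seq_along(qi)) {
    r <- row_of[qi[k]]; s <- si[k]; v <- calls$copy_number[qi[k]]
    if (cn[r, s] != 2L && cn[r, s] != v)
      stop(sprintf(
        "conflicting overlapping calls for sample %s over %s:%d-%d (CN %d vs %d)",
        calls$sample_id[qi[k]],
        as.character(GenomicRanges::seqnames(seg)[s]),
        GenomicRanges::start(seg)[s], GenomicRanges::end(seg)[s],
        cn[r, s], v))
    cn[r, s] <- v
  }

  # boundaries supporting each segment: distinct call starts/ends coinciding
  # with the segment edges
  starts <- GenomicRanges::start(seg)
  ends <- GenomicRanges::end(seg)
  bnd_start <- paste(calls$chromosome, calls$start)
  bnd_end <- paste(calls$chromosome, calls$end)
  seg_chr <- as.character(GenomicRanges::seqnames(seg))
  n_bnd <- (paste(seg_chr, starts) %in% bnd_start) +
    (paste(seg_chr, ends) %in% bnd_end) +
    (paste(seg_chr, starts - 1L) %in% bnd_end) +
    (paste(seg_chr, ends + 1L) %in% bnd_start)

  segments <- data.frame(
    segment_id = sprintf("seg_%s_%d_%d", seg_chr, starts, ends),
    chromosome = seg_chr, start = starts, end = ends,
    length = ends - starts + 1L,
    n_supporting_boundaries = as.integer(n_bnd),
    stringsAsFactors = FALSE)
  colnames(cn) <- segments$segment_id
  new_segment_matrix(segments, cn, sample_ids)
}

empty_segments <- function() {
  data.frame(segment_id = character(0), chromosome = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             n_supporting_boundaries = integer(0), stringsAsFactors = FALSE)
}

new_segment_matrix <- function(segments, cn, sample_ids) {
  ns <- nrow(segments)
  cls <- character(ns); cf <- numeric(ns); dcf <- numeric(ns)
  hwe <- rep(NA_real_, ns)
  for (j in seq_len(ns)) {
    col <- cn[, j]
    cls[j] <- classify_segment(col)
    cf[j] <- carrier_frequency(col)
    dcf[j] <- deletion_carrier_frequency(col)
    if (cls[j] %in% c("deletion_only", "duplication_only"))
      hwe[j] <- hwe_test(col, cls[j])$p_value
  }
  structure(list(segments = segments, cn = cn, sample_ids = sample_ids,
                 class = cls, carrier_freq = cf, del_carrier_freq = dcf,
                 hwe_p = hwe),
            class = "segment_matrix")
}

#' @export
print.segment_matrix <- function(x, ...) {
  cat(sprintf("segment_matrix: %d segments x %d samples\n",
              nrow(x$segments), length(x$sample_ids)))
  if (nrow(x$segments)) {
    tab <- table(factor(x$class, levels = c("deletion_only",
                                            "duplication_only", "multi_class")))
    cat(sprintf("  deletion-only %d, duplication-only %d, multi-class %d\n",
                tab[1], tab[2], tab[3]))
  }
  invisible(x)
}

#' Classify a segment by the abnormal copy numbers it shows
#'
#' `deletion_only` if every abnormal copy number is below 2,
#' `duplication_only` if every abnormal copy number is above 2,
#' `multi_class` if both occur.
#'
#' @param cn_column integer copy numbers of all samples at one segment;
#'   must contain at least one value different from 2.
#' @return one of `"deletion_only"`, `"duplication_only"`, `"multi_class"`.
#' @export
classify_segment <- function(cn_column) {
  ab <- cn_column[cn_column != 2L]
  if (!length(ab)) stop("segment has no abnormal copy numbers")
  has_del <- any(ab < 2L); has_dup <- any(ab > 2L)
  if (has_del && has_dup) "multi_class"
  else if (has_del) "deletion_only"
  else "duplication_only"
}

#' Fraction of samples with abnormal copy number at a segment
#'
#' @param cn_column integer copy numbers of all samples at one segment.
#' @return fraction of samples with copy number different from 2.
#' @export
carrier_frequency <- function(cn_column) {
  if (!length(cn_column)) stop("empty copy-number column")
  mean(cn_column != 2L)
}

#' Fraction of samples carrying a deletion at a segment
#'
#' @param cn_column integer copy numbers of all samples at one segment.
#' @return fraction of samples with copy number below 2.
#' @export
deletion_carrier_frequency <- function(cn_column) {
  if (!length(cn_column)) stop("empty copy-number column")
  mean(cn_column < 2L)
}

#' Hardy-Weinberg test for a CNV segment
#'
#' Maps copy numbers to biallelic genotype counts and tests
#' Hardy-Weinberg equilibrium. For a deletion-only segment the deletion
#' allele `a` gives CN2 -> AA, CN1 -> Aa, CN0 -> aa; a duplication-only
#' segment is mapped symmetrically (CN2/CN3/CN4). Multi-class segments are
#' not tested unless `multi_class_as_deletion = TRUE`, in which case
#' duplication carriers are dropped and the deletion allele is tested.
#'
#' The default method is the exact conditional test: the sum of the
#' probabilities of all heterozygote counts no more probable than the one
#' observed, given the allele counts. A 1-df chi-square test is available
#' for speed.
#'
#' @param cn_column integer copy numbers of all samples at one segment.
#' @param class segment class from [classify_segment()].
#' @param method `"exact"` (default) or `"chi2"`.
#' @param multi_class_as_deletion test multi-class segments on the deletion
#'   allele after dropping CN > 2 carriers (reporting variant).
#' @return list of class `hwe_result`: `n_hom_ref`, `n_het`, `n_hom_alt`,
#'   `p_value`, `method`; `p_value` is `NA` for untested multi-class
#'   segments.
#' @export
hwe_test <- function(cn_column, class = classify_segment(cn_column),
                     method = c("exact", "chi2"),
                     multi_class_as_deletion = FALSE) {
  method <- match.arg(method)
  if (class == "multi_class") {
    if (!multi_class_as_deletion)
      return(structure(list(n_hom_ref = NA_integer_, n_het = NA_integer_,
                            n_hom_alt = NA_integer_, p_value = NA_real_,
                            method = "not_applicable"),
                       class = "hwe_result"))
    cn_column <- cn_column[cn_column <= 2L]
    class <- "deletion_only"
  }
  if (class == "deletion_only") {
    n_hom_ref <- sum(cn_column == 2L)
    n_het <- sum(cn_column == 1L)
    n_hom_alt <- sum(cn_column == 0L)
  } else {
    n_hom_ref <- sum(cn_column == 2L)
    n_het <- sum(cn_column == 3L)
    n_hom_alt <- sum(cn_column >= 4L)
  }
  p <- if (method == "exact") hwe_exact_p(n_hom_ref, n_het, n_hom_alt)
       else hwe_chi2_p(n_hom_ref, n_het, n_hom_alt)
  structure(list(n_hom_ref = n_hom_ref, n_het = n_het,
                 n_hom_alt = n_hom_alt, p_value = p, method = method),
            class = "hwe_result")
}

#' Exact conditional Hardy-Weinberg test from genotype counts
#'
#' Conditional on the observed allele counts, the probability of observing
#' `nAa` heterozygotes is
#' `P(nAa) = n! / (nAA! nAa! naa!) * 2^nAa * nA! na! / (2n)!` times the
#' number of allele arrangements; the p-value is the total probability of
#' all heterozygote counts whose probability does not exceed that of the
#' observed count. Computed with log-gamma arithmetic.
#'
#' @param nAA,nAa,naa genotype counts (all >= 0).
#' @return exact p-value in (0, 1]; 1 when only one genotype is present.
#' @export
hwe_exact_p <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  na <- nAa + 2 * naa            # minor-allele count (alt)
  if (n == 0 || na == 0 || na == 2 * n) return(1)
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    AA <- n - h - aa
    lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# 1-df chi-square HWE test (no continuity correction).
hwe_chi2_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  q <- (nAa + 2 * naa) / (2 * n)
  if (q == 0 || q == 1) return(1)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((c(nAA, nAa, naa) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Filter segments by carrier frequency and Hardy-Weinberg equilibrium
#'
#' Keeps the common segments: carrier frequency at least
#' `min_carrier_freq`, and, for deletion-only and duplication-only
#' segments, exact Hardy-Weinberg p strictly above `hwe_alpha` (segments
#' with p <= `hwe_alpha` are excluded as unreliable genotyping).
#' Multi-class segments are not subject to the HWE screen.
#'
#' @param sm a `segment_matrix` from [segment_cnvs()].
#' @param min_carrier_freq minimum abnormal-carrier fraction (default 0.05).
#' @param hwe_alpha HWE exclusion threshold (default 0.05).
#' @return the filtered `segment_matrix`, with a `filter_log` attribute
#'   recording each segment's decision and reason.
#' @export
filter_segments <- function(sm, min_carrier_freq = 0.05, hwe_alpha = 0.05) {
  stopifnot(inherits(sm, "segment_matrix"))
  freq_ok <- sm$carrier_freq >= min_carrier_freq
  hwe_ok <- sm$class == "multi_class" | (!is.na(sm$hwe_p) & sm$hwe_p > hwe_alpha)
  keep <- freq_ok & hwe_ok
  reason <- ifelse(keep, "kept",
                   ifelse(!freq_ok, "carrier_freq_below_threshold",
                          "hwe_violation"))
  log <- data.frame(segment_id = sm$segments$segment_id, kept = keep,
                    reason = reason, carrier_freq = sm$carrier_freq,
                    hwe_p = sm$hwe_p, class = sm$class,
                    stringsAsFactors = FALSE)
  out <- new_segment_matrix(sm$segments[keep, , drop = FALSE],
                            sm$cn[, keep, drop = FALSE], sm$sample_ids)
  attr(out, "filter_log") <- log
  out
}
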