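# Total rDNA copy-number estimation from sequencing coverage, and its
# correlation with methylation across samples.
#
# The estimator is a transparent coverage ratio: copies per diploid genome =
# 2 x (mean rDNA depth / mean single-copy background depth), with a
# whole-unit and an 18S-only variant. Background intervals are user-supplied
# (or simulated); no GC correction is applied.

#' Summarize coverage for copy-number estimation
#'
#' Mean depths are 1%-tail trimmed by default (multi-copy loci are prone to
#' alignment pileups); set `trim = 0` for plain means.
#'
#' @param sample_id Sample label.
#' @param rdna_depth Per-base depth over the rDNA unit (or a precomputed
#'   scalar mean).
#' @param background_depth Per-base depth over single-copy background
#'   intervals (or a scalar mean).
#' @param reference Optional [rdna_reference()]; when given together with
#'   per-base `rdna_depth`, the 18S interval mean is extracted from it.
#' @param s18_depth Optional explicit per-base depth (or scalar) over the 18S
#'   interval.
#' @param trim Fraction trimmed from each tail of per-base depths.
#' @return Object of class `coverage_summary` (`sample`, `mean_rdna`,
#'   `mean_18s`, `mean_background`, `n_background_bases`, `trim`).
#' @export
coverage_summary <- function(sample_id, rdna_depth, background_depth,
                             reference = NULL, s18_depth = NULL,
                             trim = 0.01) {
  if (any(rdna_depth < 0) || any(background_depth < 0))
    stop_rdnaepi("depths must be non-negative", "invalid_input")
  if (!length(background_depth))
    stop_rdnaepi("background intervals empty", "invalid_input")
  tmean <- function(x) if (length(x) == 1L) x else mean(x, trim = trim)
  mean_18s <- NA_real_
  if (!is.null(s18_depth)) {
    mean_18s <- tmean(s18_depth)
  } else if (!is.null(reference) && length(rdna_depth) > 1L) {
    iv <- region_interval(reference, "18S")
    mean_18s <- tmean(rdna_depth[iv[["start"]]:(iv[["end"]] - 1L)])
  }
  structure(list(sample = sample_id,
                 mean_rdna = tmean(rdna_depth),
                 mean_18s = mean_18s,
                 mean_background = tmean(background_depth),
                 n_background_bases = length(background_depth),
                 trim = trim),
            class = "coverage_summary")
}

#' Estimate rDNA copies per diploid genome
#'
#' `copies = 2 * mean(rDNA depth) / mean(background depth)`; the explicit
#' diploid factor matches the "copies per diploid genome" unit. The `18S-only`
#' variant ratios the highly conserved 18S interval instead of the whole unit
#' (robust to mapping-efficiency differences).
#'
#' @param coverage A [coverage_summary()].
#' @param variant `"whole-unit"` or `"18S-only"`.
#' @return List of class `cn_estimate` (`copies_per_diploid`, `variant`,
#'   `sample`).
#' @export
estimate_cn <- function(coverage, variant = c("whole-unit", "18S-only")) {
  variant <- match.arg(variant)
  num <- if (variant == "18S-only") coverage$mean_18s else coverage$mean_rdna
  if (is.na(num))
    stop_rdnaepi("18S depth unavailable in this coverage summary",
                 "invalid_input")
  if (!is.finite(coverage$mean_background) || coverage$mean_background <= 0)
    stop_rdnaepi("background depth must be positive", "zero_background")
  structure(list(copies_per_diploid = 2 * num / coverage$mean_background,
                 variant = variant, sample = coverage$sample),
            class = "cn_estimate")
}

#' Correlate copy number with methylation across samples
#'
#' Pearson correlation with two-sided p, computed (a) over all samples and (b)
#' over per-group means (one point per strain).
#'
#' @param samples Data frame with columns `cn`, `methylation` and optionally
#'   `group`.
#' @return List with `per_sample` and (when groups exist) `per_group`, each
#'   `(r, p, n)`.
#' @export
cn_methylation_correlation <- function(samples) {
  stopifnot(all(c("cn", "methylation") %in% names(samples)))
  one <- function(x, y, min_n) {
    if (length(x) < min_n)
      stop_rdnaepi(sprintf("need >= %d points", min_n), "insufficient_data")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) undefined_correlation()
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  out <- list(per_sample = one(samples$cn, samples$methylation, 3L))
  if ("group" %in% names(samples) &&
      length(unique(samples$group)) >= 3L) {
    gm <- stats::aggregate(samples[, c("cn", "methylation")],
                           by = list(group = samples$group), FUN = mean)
    out$per_group <- one(gm$cn, gm$methylation, 3L)
  }
  out
}
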