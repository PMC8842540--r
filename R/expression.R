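# rRNA allele-frequency computation, methylation-expression correlation,
# methylation-adjusted allele-frequency prediction, and haplotype
# representation enrichment in assay reads.

#' Alternative allele frequency
#'
#' @param ref_count,alt_count Read counts of the two compared alleles.
#' @param min_depth Minimum total depth (binomial SE <= ~0.11 at the default).
#' @return `alt / (ref + alt)`.
#' @export
aaf <- function(ref_count, alt_count, min_depth = 20L) {
  tot <- ref_count + alt_count
  if (any(tot < min_depth))
    stop_rdnaepi(sprintf("depth below min_depth = %d", min_depth),
                 "insufficient_depth")
  alt_count / tot
}

#' Methylation-adjusted allele frequency
#'
#' The allele frequency expected among expressed (unmethylated) copies when
#' methylated copies are ignored:
#' `f' = f (1 - m_alt) / (f (1 - m_alt) + (1 - f)(1 - m_ref))`.
#' Exact inverse-weighting identity: under hard silencing it equals the
#' expected rRNA allele frequency.
#'
#' @param f_alt DNA alternative allele frequency.
#' @param m_alt,m_ref Mean methylation of the alt / ref strata, in \[0, 1\].
#' @return Adjusted frequency (vectorized).
#' @export
adjust_aaf <- function(f_alt, m_alt, m_ref) {
  stopifnot(all(m_alt >= 0 & m_alt <= 1), all(m_ref >= 0 & m_ref <= 1),
            all(f_alt >= 0 & f_alt <= 1))
  num <- f_alt * (1 - m_alt)
  den <- num + (1 - f_alt) * (1 - m_ref)
  if (any(den == 0))
    stop_rdnaepi("both strata fully methylated: adjustment undefined",
                 "undefined_adjustment")
  num / den
}

#' Correlate methylation near an SNV with its expression representation
#'
#' Pearson correlation across samples of local DNA methylation against the
#' variant's rRNA frequency (or haplotype frequency). Each sample contributes
#' one point; a negative correlation is the silencing direction but is a
#' result, not an assumption.
#'
#' @param methylation Per-sample methylation values.
#' @param expression Matching rRNA allele (or haplotype) frequencies.
#' @return List (`r`, `p`, `n`).
#' @export
methylation_expression_correlation <- function(methylation, expression) {
  stopifnot(length(methylation) == length(expression))
  if (length(methylation) < 3L)
    stop_rdnaepi("need >= 3 samples", "insufficient_data")
  if (stats::sd(methylation) == 0 || stats::sd(expression) == 0)
    undefined_correlation()
  ct <- stats::cor.test(methylation, expression)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(methylation))
}

#' DNA-RNA allele-frequency correlation and its methylation adjustment
#'
#' Across samples: `r_raw` correlates DNA against RNA allele frequencies;
#' `r_adjusted` first replaces the DNA frequency by its methylation-adjusted
#' value ([adjust_aaf()]). Ignoring methylated copies should improve the
#' correlation when only unmethylated units are expressed.
#'
#' @param samples Data frame with columns `dna_aaf`, `rna_aaf`, `m_alt`,
#'   `m_ref` (one row per sample).
#' @return List of class `expression_linkage` (`r_raw`, `r_adjusted`,
#'   `delta_r`, `n`).
#' @export
correlation_improvement <- function(samples) {
  stopifnot(all(c("dna_aaf", "rna_aaf", "m_alt", "m_ref") %in% names(samples)))
  if (nrow(samples) < 3L)
    stop_rdnaepi("need >= 3 samples", "insufficient_data")
  adj <- adjust_aaf(samples$dna_aaf, samples$m_alt, samples$m_ref)
  if (stats::sd(samples$rna_aaf) == 0 || stats::sd(samples$dna_aaf) == 0 ||
      stats::sd(adj) == 0)
    undefined_correlation()
  r_raw <- stats::cor(samples$dna_aaf, samples$rna_aaf)
  r_adj <- stats::cor(adj, samples$rna_aaf)
  structure(list(r_raw = r_raw, r_adjusted = r_adj,
                 delta_r = r_adj - r_raw, n = nrow(samples)),
            class = "expression_linkage")
}

#' Haplotype representation enrichment in assay reads
#'
#' Ratio of the assay proportion to the background proportion per haplotype;
#' 1 means no enrichment. Descriptive by default; `test = TRUE` adds a
#' two-sided binomial test of the assay count against the background
#' proportion.
#'
#' @param assay_counts Named counts per haplotype in the assay.
#' @param background_counts Named counts per haplotype in the background
#'   (all labels of `assay_counts` must be present with positive counts).
#' @param test Add binomial-test p-values.
#' @return Data frame (`haplotype`, `ratio`, `assay_prop`,
#'   `background_prop`, and `p` when `test`).
#' @export
representation_enrichment <- function(assay_counts, background_counts,
                                      test = FALSE) {
  labs <- names(assay_counts)
  stopifnot(!is.null(labs), !is.null(names(background_counts)))
  bg <- background_counts[labs]
  if (any(is.na(bg)) || any(bg <= 0))
    stop_rdnaepi("zero/missing background count for a reported label",
                 "zero_background")
  ap <- assay_counts / sum(assay_counts)
  bp <- bg / sum(background_counts)
  out <- data.frame(haplotype = labs, ratio = as.numeric(ap / bp),
                    assay_prop = as.numeric(ap),
                    background_prop = as.numeric(bp),
                    stringsAsFactors = FALSE)
  if (test)
    out$p <- vapply(seq_along(labs), function(i)
      stats::binom.test(assay_counts[[i]], sum(assay_counts),
                        p = bp[[i]])$p.value, numeric(1))
  rownames(out) <- NULL
  out
}

#' Allele frequencies from a long count table
#'
#' Convenience for tables like the output of [simulate_rrna_counts()]:
#' per position, the frequency of each allele among all counted alleles.
#'
#' @param counts Data frame (`position`, `allele`, `count`).
#' @return Data frame (`position`, `allele`, `freq`, `total`).
#' @export
allele_frequencies <- function(counts) {
  stopifnot(all(c("position", "allele", "count") %in% names(counts)))
  out <- do.call(rbind, lapply(split(counts, counts$position), function(d) {
    data.frame(position = d$position, allele = d$allele,
               freq = d$count / sum(d$count), total = sum(d$count),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
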