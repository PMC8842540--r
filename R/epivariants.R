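# Epivariant detection: per-SNV Wilcoxon rank-sum tests on allele-stratified
# per-read methylation fractions, Benjamini-Hochberg FDR control, cross-strain
# sharing classification, and Ward clustering of samples by allele-frequency
# vectors.

#' Wilcoxon rank-sum test
#'
#' Exact enumeration of the permutation distribution when the pooled sample
#' size is at most `exact_max` and the values are untied; otherwise the normal
#' approximation with tie-corrected variance and continuity correction
#' (midranks for ties). Two-sided.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max Pooled-size ceiling for the exact test.
#' @return List (`U`, `p`): the rank-sum statistic (number of (x, y) pairs
#'   with x > y, ties counted half) and the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20L) {
  if (!length(x) || !length(y))
    stop_rdnaepi("both samples must be non-empty", "insufficient_data")
  tied <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exact_max && !tied
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, returned in input
#' order.
#'
#' @param p Numeric p-values in (0, 1\].
#' @return Numeric q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Detect epivariants from allele-stratified methylation
#'
#' For every SNV whose two compared alleles each carry at least `min_reads`
#' informative reads, tests the per-read methylation fractions of the
#' alternative against the reference allele with [wilcoxon_rank_sum()] and
#' adjusts across all tested SNVs (the FDR family is one sample). An SNV is
#' flagged an epivariant when `q < alpha`.
#'
#' @param asm_list List of `asm` objects (one per SNV), e.g. from
#'   [allele_specific_methylation_all()].
#' @param alpha FDR threshold.
#' @param min_reads Minimum informative reads per allele.
#' @return Data frame (`position`, `ref_allele`, `alt_allele`, `n_ref`,
#'   `n_alt`, `m_ref`, `m_alt`, `delta_m`, `U`, `p`, `q`, `flagged`); empty
#'   with a warning when nothing is testable.
#' @export
detect_epivariants <- function(asm_list, alpha = 0.01, min_reads = 10L) {
  rows <- lapply(asm_list, function(a) {
    n <- a$n_reads
    eligible <- names(n)[n >= min_reads]
    if (length(eligible) < 2L) return(NULL)
    ref <- a$alleles[1L]
    if (!(ref %in% eligible)) ref <- eligible[order(-n[eligible])][1L]
    alt <- setdiff(eligible, ref)[1L]
    xr <- a$strata[[ref]]
    xa <- a$strata[[alt]]
    w <- wilcoxon_rank_sum(xa, xr)
    data.frame(position = a$position, ref_allele = ref, alt_allele = alt,
               n_ref = length(xr), n_alt = length(xa),
               m_ref = mean(xr), m_alt = mean(xa),
               delta_m = mean(xa) - mean(xr),
               U = w$U, p = w$p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no SNV met the per-allele read threshold; nothing tested")
    return(data.frame(position = integer(0), ref_allele = character(0),
                      alt_allele = character(0), n_ref = integer(0),
                      n_alt = integer(0), m_ref = numeric(0),
                      m_alt = numeric(0), delta_m = numeric(0),
                      U = numeric(0), p = numeric(0), q = numeric(0),
                      flagged = logical(0)))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  res$flagged <- res$q < alpha
  res
}

#' Classify epivariant sharing across strains
#'
#' A position is `shared` when flagged with the same `delta_m` sign in at
#' least two strains, `strain-specific` when flagged in exactly one,
#' `conflict` when flagged with opposing signs (allelic methylation
#' differences need not be directionally consistent across strains), and
#' `absent` otherwise.
#'
#' @param results_by_strain Named list of [detect_epivariants()] data frames.
#' @return Data frame (`position`, `n_flagged`, `classification`,
#'   `strains_flagged`).
#' @export
classify_sharing <- function(results_by_strain) {
  if (length(results_by_strain) < 2L)
    stop_rdnaepi("need results from >= 2 strains", "insufficient_data")
  all_pos <- sort(unique(unlist(lapply(results_by_strain,
                                       function(d) d$position))))
  rows <- lapply(all_pos, function(p) {
    hits <- lapply(names(results_by_strain), function(s) {
      d <- results_by_strain[[s]]
      d <- d[d$position == p & d$flagged, , drop = FALSE]
      if (nrow(d)) data.frame(strain = s, sign = sign(d$delta_m[1L])) else NULL
    })
    hits <- do.call(rbind, hits)
    n <- if (is.null(hits)) 0L else nrow(hits)
    cls <- if (n == 0L) "absent"
    else if (n == 1L) "strain-specific"
    else if (length(unique(hits$sign)) == 1L) "shared"
    else "conflict"
    data.frame(position = p, n_flagged = n, classification = cls,
               strains_flagged = if (n) paste(hits$strain, collapse = ",")
               else "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster samples by allele-frequency vectors
#'
#' Ward linkage (`ward.D2`) on the Euclidean distance between per-sample
#' allele-frequency vectors over a shared position set.
#'
#' @param aaf Numeric matrix: rows = samples (named), columns = positions.
#' @return An [stats::hclust] tree.
#' @export
cluster_samples_by_aaf <- function(aaf) {
  aaf <- as.matrix(aaf)
  if (nrow(aaf) < 2L)
    stop_rdnaepi("need >= 2 samples to cluster", "insufficient_data")
  stats::hclust(stats::dist(aaf, method = "euclidean"), method = "ward.D2")
}

#' Write a sample dendrogram as Newick
#'
#' @param hc An [stats::hclust] tree (e.g. from [cluster_samples_by_aaf()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
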