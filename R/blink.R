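# Conversion-aware SNV genotyping of bisulfite reads and allele-stratified
# per-read CpG methylation.
#
# Bisulfite conversion turns unmethylated C into T on the converted strand, so
# on original-top (OT/CTOT) reads an observed T is compatible with both a true
# T and a converted C, and on original-bottom (OB/CTOB) reads (reported in
# top-strand orientation) an observed A is compatible with both a true A and a
# converted bottom-strand C, i.e. a top-strand G. Genotyping therefore applies
# a deterministic truth table per strand context; observations compatible with
# more than one allele of the site are ambiguous.

#' Genotype a bisulfite read base at an SNV
#'
#' All bases are in top-strand orientation. OT/CTOT contexts: observed C means
#' allele C; observed T means allele C iff C is an allele and T is not
#' (converted C), is ambiguous iff both C and T are alleles, else allele T;
#' G/A are read faithfully. OB/CTOB contexts mirror this with the G/A pair
#' confounded and C/T read faithfully. Any base falling outside the allele set
#' after this mapping is ambiguous.
#'
#' @param base Observed base(s) (`A`, `C`, `G`, `T`), top-strand orientation.
#' @param context Strand context(s): `OT`, `OB`, `CTOT`, `CTOB`.
#' @param alleles Character vector of the site's alleles (ref first by
#'   convention).
#' @return Character vector: the called allele or `"ambiguous"`.
#' @export
genotype_bs_read <- function(base, context, alleles) {
  stopifnot(length(base) == length(context) || length(context) == 1L)
  if (length(context) == 1L) context <- rep(context, length(base))
  alleles <- toupper(alleles)
  top_like <- context %in% c("OT", "CTOT")
  if (!all(top_like | context %in% c("OB", "CTOB")))
    stop_rdnaepi("context must be one of OT, OB, CTOT, CTOB",
                 "invalid_context")
  base <- toupper(base)
  call_one <- function(b, top) {
    if (top) {
      if (b == "T") {
        has_c <- "C" %in% alleles
        has_t <- "T" %in% alleles
        if (has_c && has_t) return("ambiguous")
        if (has_c) return("C")
        if (has_t) return("T")
        return("ambiguous")
      }
    } else {
      if (b == "A") {
        has_g <- "G" %in% alleles
        has_a <- "A" %in% alleles
        if (has_g && has_a) return("ambiguous")
        if (has_g) return("G")
        if (has_a) return("A")
        return("ambiguous")
      }
    }
    if (b %in% alleles) b else "ambiguous"
  }
  vapply(seq_along(base), function(i) call_one(base[i], top_like[i]),
         character(1))
}

#' Allele-stratified per-read methylation at an SNV
#'
#' Reads covering the SNV are genotyped with [genotype_bs_read()] and
#' partitioned by allele. Each read contributes its methylated-CpG fraction
#' over CpGs inside a window centered on the SNV, excluding CpGs whose C or G
#' position coincides with any panel SNV (so genotype never leaks into the
#' methylation signal); reads with fewer than `min_cpgs` covered window CpGs
#' are dropped. Allele frequencies are computed over informative
#' (unambiguous, CpG-sufficient) reads; ambiguous reads are counted
#' separately. The per-allele methylation `m_a` is the mean of per-read
#' fractions (the read is the independent unit for downstream rank tests).
#'
#' @param bs A `bs_obs` object.
#' @param position Panel SNV position (reference coordinate).
#' @param alleles Alleles at the site; defaults to the panel's.
#' @param panel An [snv_panel()] (CpG exclusion set); defaults to the
#'   observation's.
#' @param window Half-width in bp of the window around the SNV.
#' @param min_cpgs Minimum covered window CpGs per read.
#' @return Object of class `asm`: `position`, `alleles`, `window`,
#'   `strata` (named list allele -> numeric vector of per-read fractions),
#'   `n_ambiguous`, `f` (named allele frequencies), `m` (named mean
#'   fractions).
#' @export
allele_specific_methylation <- function(bs, position, alleles = NULL,
                                        panel = bs$panel, window = 200L,
                                        min_cpgs = 2L) {
  if (is.null(alleles)) alleles <- panel_alleles(panel, position)
  snv <- bs$snv_calls[bs$snv_calls$pos == position, , drop = FALSE]
  if (!nrow(snv))
    stop_rdnaepi(sprintf("no reads cover position %d", position),
                 "empty_result")
  ctx <- bs$reads$context[match(snv$read_id, bs$reads$read_id)]
  call <- genotype_bs_read(snv$base, ctx, alleles)

  # per-read methylated fraction over window CpGs not coinciding with any SNV
  cc <- bs$cpg_calls
  excl <- unique(c(panel$position, panel$position - 1L))
  in_win <- cc$pos >= position - window & cc$pos <= position + window &
    !(cc$pos %in% excl)
  cc <- cc[in_win & cc$read_id %in% snv$read_id, , drop = FALSE]
  n_cov <- table(cc$read_id)
  frac <- tapply(cc$state, cc$read_id, mean)
  ok_reads <- names(n_cov)[n_cov >= min_cpgs]

  keep <- snv$read_id %in% ok_reads
  call <- call[keep]
  rid <- snv$read_id[keep]
  if (!length(call))
    stop_rdnaepi(sprintf("no informative reads at position %d", position),
                 "empty_result")
  n_amb <- sum(call == "ambiguous")
  informative <- call != "ambiguous"
  strata <- lapply(stats::setNames(alleles, alleles), function(a)
    as.vector(frac[rid[informative & call == a]]))
  n_a <- vapply(strata, length, integer(1))
  f <- if (sum(n_a) > 0) n_a / sum(n_a) else n_a * NA_real_
  m <- vapply(strata, function(x) if (length(x)) mean(x) else NA_real_,
              numeric(1))
  structure(list(position = position, alleles = alleles,
                 window = as.integer(window), strata = strata,
                 n_reads = n_a, f = f, m = m, n_ambiguous = n_amb),
            class = "asm")
}

#' @export
print.asm <- function(x, ...) {
  cat(sprintf("allele-specific methylation at %d (window +/-%d bp, %d ambiguous)\n",
              x$position, x$window, x$n_ambiguous))
  print(data.frame(allele = x$alleles, n = x$n_reads,
                   f = round(x$f, 4), m = round(x$m, 4)))
  invisible(x)
}

#' @export
as.data.frame.asm <- function(x, ...) {
  data.frame(position = x$position, allele = x$alleles,
             n_reads = as.integer(x$n_reads), f = as.numeric(x$f),
             m = as.numeric(x$m), window = x$window,
             n_ambiguous = x$n_ambiguous, stringsAsFactors = FALSE)
}

#' Allele-stratified methylation for every panel SNV
#'
#' @param bs A `bs_obs`.
#' @param panel An [snv_panel()]; defaults to the observation's.
#' @param ... Passed to [allele_specific_methylation()].
#' @return Named list of `asm` objects (positions lacking informative reads
#'   are skipped with a warning).
#' @export
allele_specific_methylation_all <- function(bs, panel = bs$panel, ...) {
  out <- list()
  for (p in panel$position) {
    res <- tryCatch(allele_specific_methylation(bs, p, panel = panel, ...),
                    rdnaepi_error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("position %d skipped: %s", p, conditionMessage(res)))
    } else out[[as.character(p)]] <- res
  }
  out
}

#' Pooled methylation of an ASM result
#'
#' The mean per-read fraction over all stratified (informative) reads; equals
#' `sum(f_a * m_a)` exactly — a conservation identity used as an internal
#' consistency check.
#'
#' @param asm An `asm` object.
#' @return Scalar pooled mean fraction.
#' @export
asm_pooled_mean <- function(asm) {
  x <- unlist(asm$strata, use.names = FALSE)
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' SNV recovery of a WGS panel in bisulfite data
#'
#' An SNV is recovered when its alternative allele is observed unambiguously
#' in at least `min_reads` bisulfite reads. Also reports the per-position
#' difference between the bisulfite alternative allele frequency and an
#' optional WGS panel frequency column.
#'
#' @param panel An [snv_panel()], optionally with a numeric `aaf` column.
#' @param bs A `bs_obs`.
#' @param min_reads Minimum unambiguous alt reads.
#' @return List: `fraction` recovered, `per_snv` data.frame (`position`,
#'   `alt_reads`, `total_informative`, `aaf_bs`, `recovered`, `aaf_delta`).
#' @export
snv_recovery <- function(panel, bs, min_reads = 2L) {
  if (!nrow(panel))
    stop_rdnaepi("empty panel: recovered fraction undefined", "empty_panel")
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    p <- panel$position[i]
    alleles <- panel_alleles(panel, p)
    alt <- alleles[-1L]
    snv <- bs$snv_calls[bs$snv_calls$pos == p, , drop = FALSE]
    if (!nrow(snv))
      return(data.frame(position = p, alt_reads = 0L,
                        total_informative = 0L, aaf_bs = NA_real_,
                        recovered = FALSE))
    ctx <- bs$reads$context[match(snv$read_id, bs$reads$read_id)]
    call <- genotype_bs_read(snv$base, ctx, alleles)
    informative <- call != "ambiguous"
    alt_n <- sum(call %in% alt)
    tot <- sum(informative)
    data.frame(position = p, alt_reads = alt_n, total_informative = tot,
               aaf_bs = if (tot > 0) alt_n / tot else NA_real_,
               recovered = alt_n >= min_reads)
  })
  per <- do.call(rbind, rows)
  per$aaf_delta <- if ("aaf" %in% names(panel))
    per$aaf_bs - panel$aaf else NA_real_
  list(fraction = mean(per$recovered), per_snv = per)
}

#' Bisulfite conversion-efficiency QC
#'
#' Unconverted reads are not filtered; instead a QC statistic is reported:
#' among reads whose overall CpG methylation is low (from unmethylated units),
#' residual methylated calls are predominantly conversion failures, so the
#' mean unmethylated-call rate of those reads estimates the conversion
#' efficiency.
#'
#' @param bs A `bs_obs`.
#' @param low_cutoff Per-read mean methylation below which a read is treated
#'   as coming from an unmethylated unit.
#' @return Estimated conversion efficiency in \[0, 1\] (`NA` when no low-
#'   methylation read exists).
#' @export
conversion_qc <- function(bs, low_cutoff = 0.5) {
  cc <- bs$cpg_calls
  if (!nrow(cc)) return(NA_real_)
  by_read <- tapply(cc$state, cc$read_id, mean)
  lows <- by_read[by_read < low_cutoff]
  if (!length(lows)) return(NA_real_)
  unname(1 - mean(lows))
}
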