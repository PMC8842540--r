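# Life-stage dynamics: per-read methylation entropy (disorder), aging trends
# per haplotype stratum, the expected mirror correlation, and condition
# contrasts of ATA versus pooled non-ATA strata.

#' Per-read methylation Shannon entropy
#'
#' The binary entropy (bits) of the read's methylated-CpG fraction:
#' `H = -p log2 p - (1-p) log2 (1-p)` with `0 log 0 = 0`. Reads with fewer
#' than `min_cpgs` states are excluded (entropy of very few states is coarsely
#' quantized).
#'
#' @param states Binary 0/1 vector of CpG states of one read.
#' @param min_cpgs Minimum number of states.
#' @return Entropy in bits, or `NA_real_` for excluded reads.
#' @export
read_entropy <- function(states, min_cpgs = 4L) {
  states <- states[!is.na(states)]
  if (length(states) < min_cpgs) return(NA_real_)
  stopifnot(all(states %in% c(0, 1)))
  binary_entropy(mean(states))
}

#' Build per-read methylation records from bisulfite observations
#'
#' Each read becomes one record with its CpG-state counts and a haplotype
#' stratum derived from the alleles observed at the stratifying SNVs (for
#' short reads, the sites near the ITS2 variants): a read matching the ATA
#' allele at a stratifying position is `ATA`, one matching a non-ATA allele is
#' `non-ATA`, reads without an informative stratifying call are `unassigned`.
#'
#' @param bs A `bs_obs`.
#' @param strat_positions Reference coordinates of the stratifying SNVs.
#' @param ata_alleles Named character vector: ATA allele per stratifying
#'   position (names = positions).
#' @param panel An [snv_panel()]; defaults to the observation's.
#' @param sample_id,age,condition Metadata copied onto every record.
#' @return Data frame (`read_id`, `sample`, `stratum`, `n_meth`, `n_cpgs`,
#'   `states`, `age`, `condition`); `states` is the read's 0/1 string.
#' @export
read_methylation_records <- function(bs, strat_positions, ata_alleles,
                                     panel = bs$panel,
                                     sample_id = bs$reads$sample[1L],
                                     age = NA_real_,
                                     condition = NA_character_) {
  stopifnot(all(as.character(strat_positions) %in% names(ata_alleles)))
  calls <- bs$snv_calls[bs$snv_calls$pos %in% strat_positions, , drop = FALSE]
  stratum <- rep("unassigned", nrow(bs$reads))
  names(stratum) <- bs$reads$read_id
  if (nrow(calls)) {
    ctx <- bs$reads$context[match(calls$read_id, bs$reads$read_id)]
    for (i in seq_len(nrow(calls))) {
      p <- calls$pos[i]
      al <- panel_alleles(panel, p)
      g <- genotype_bs_read(calls$base[i], ctx[i], al)
      if (g == "ambiguous") next
      s <- if (g == ata_alleles[[as.character(p)]]) "ATA" else "non-ATA"
      prev <- stratum[[calls$read_id[i]]]
      stratum[[calls$read_id[i]]] <-
        if (prev == "unassigned" || prev == s) s else "unassigned"
    }
  }
  agg_n <- tapply(bs$cpg_calls$state, bs$cpg_calls$read_id, length)
  agg_m <- tapply(bs$cpg_calls$state, bs$cpg_calls$read_id, sum)
  agg_s <- tapply(bs$cpg_calls$state, bs$cpg_calls$read_id,
                  paste, collapse = "")
  idx <- match(bs$reads$read_id, names(agg_n))
  data.frame(read_id = bs$reads$read_id,
             sample = sample_id,
             stratum = unname(stratum),
             n_meth = as.integer(ifelse(is.na(idx), 0L, agg_m[idx])),
             n_cpgs = as.integer(ifelse(is.na(idx), 0L, agg_n[idx])),
             states = ifelse(is.na(idx), "", agg_s[idx]),
             age = age, condition = condition,
             stringsAsFactors = FALSE)
}

#' Mean per-read methylation disorder per sample and stratum
#'
#' @param records Data frame from [read_methylation_records()] (columns
#'   `sample`, `stratum`, `n_meth`, `n_cpgs`; `states` needed for the pattern
#'   method).
#' @param min_cpgs Minimum CpGs per eligible read.
#' @param method `"read"` (default): mean binary entropy of per-read
#'   methylated fractions. `"pattern"`: per-CpG Shannon entropy (bits) of the
#'   distribution of non-overlapping 4-CpG epiallele patterns
#'   (epipolymorphism-style alternative).
#' @return Data frame (`sample`, `stratum`, `disorder`, `n_reads`,
#'   `n_excluded`). Strata with zero eligible reads are omitted with a
#'   warning.
#' @export
sample_disorder <- function(records, min_cpgs = 4L,
                            method = c("read", "pattern")) {
  method <- match.arg(method)
  if (!nrow(records)) stop_rdnaepi("no records", "insufficient_data")
  groups <- split(records, list(records$sample, records$stratum), drop = TRUE)
  rows <- lapply(groups, function(g) {
    ok <- g$n_cpgs >= min_cpgs
    base <- data.frame(sample = g$sample[1L], stratum = g$stratum[1L],
                       n_reads = sum(ok), n_excluded = sum(!ok),
                       stringsAsFactors = FALSE)
    if (!sum(ok)) return(cbind(base, disorder = NA_real_))
    if (method == "read") {
      h <- binary_entropy(g$n_meth[ok] / g$n_cpgs[ok])
      cbind(base, disorder = mean(h))
    } else {
      blocks <- unlist(lapply(g$states[ok], function(s) {
        n4 <- nchar(s) %/% 4L
        if (!n4) return(character(0))
        substring(s, 4L * seq_len(n4) - 3L, 4L * seq_len(n4))
      }))
      if (!length(blocks)) return(cbind(base, disorder = NA_real_))
      pr <- table(blocks) / length(blocks)
      cbind(base, disorder = -sum(pr * log2(pr)) / 4)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dropped <- out$n_reads == 0L
  if (any(dropped))
    warning("strata without eligible reads omitted: ",
            paste(paste(out$sample[dropped], out$stratum[dropped], sep = "/"),
                  collapse = ", "))
  out <- out[!dropped, c("sample", "stratum", "disorder", "n_reads",
                         "n_excluded")]
  rownames(out) <- NULL
  out
}

#' Age trend of a per-sample quantity
#'
#' Pearson correlation and least-squares slope of the values on age.
#'
#' @param values Per-sample numeric values.
#' @param ages Matching ages (months).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List (`r`, `slope`, `p`, `n`).
#' @export
age_trend <- function(values, ages, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(ages))
  if (length(values) < 3L)
    stop_rdnaepi("need >= 3 samples", "insufficient_data")
  if (stats::sd(ages) == 0 || stats::sd(values) == 0)
    undefined_correlation()
  ct <- stats::cor.test(values, ages, method = method, exact = FALSE)
  fit <- stats::lm(values ~ ages)
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2L]),
       p = ct$p.value, n = length(values))
}

#' Expected mirror correlation for the ATA stratum
#'
#' The correlation with age that the ATA stratum would show if it lost
#' methylation at the same rate as the non-ATA strata gain it: the
#' hypothetical series is `clip(baseline - (x_i - ref), 0, 1)` with `ref` the
#' mean of the youngest-age group. When no clipping occurs this equals exactly
#' the negated non-ATA age correlation.
#'
#' @param nonata_values Per-sample non-ATA methylation values.
#' @param ages Matching ages.
#' @param ata_baseline ATA methylation level anchoring the mirror.
#' @return List (`r_expected`, `clipped`, `hypothetical`).
#' @export
expected_mirror_correlation <- function(nonata_values, ages, ata_baseline) {
  stopifnot(length(nonata_values) == length(ages))
  ref <- mean(nonata_values[ages == min(ages)])
  raw <- ata_baseline - (nonata_values - ref)
  h <- pmin(1, pmax(0, raw))
  if (stats::sd(h) == 0)
    undefined_correlation("mirror series constant after clipping")
  list(r_expected = stats::cor(h, ages),
       clipped = any(raw != h),
       hypothetical = h)
}

#' Condition contrast of methylation per haplotype stratum
#'
#' Reads are pooled into `ATA` and `non-ATA` strata (every labeled non-ATA
#' stratum combined; `unassigned` dropped). Per stratum and non-control
#' condition: the difference of mean per-read methylated fractions
#' (treatment - control) and the Wilcoxon rank-sum p-value on the read
#' fractions.
#'
#' @param records Data frame from [read_methylation_records()] with a
#'   `condition` column.
#' @param control Control condition label.
#' @param min_cpgs Minimum CpGs per read.
#' @return Data frame (`condition`, `stratum`, `delta_m`, `p`, `n_treat`,
#'   `n_control`).
#' @export
condition_contrast <- function(records, control, min_cpgs = 1L) {
  if (!control %in% records$condition)
    stop_rdnaepi(sprintf("control condition '%s' absent", control),
                 "invalid_config")
  rec <- records[records$stratum != "unassigned" &
                   records$n_cpgs >= min_cpgs, , drop = FALSE]
  rec$stratum2 <- ifelse(rec$stratum == "ATA", "ATA", "non-ATA")
  rec$frac <- rec$n_meth / rec$n_cpgs
  conds <- setdiff(unique(rec$condition), control)
  if (!length(conds))
    stop_rdnaepi("need >= 2 conditions with eligible reads",
                 "insufficient_data")
  rows <- list()
  for (cond in conds) {
    for (s in c("ATA", "non-ATA")) {
      tr <- rec$frac[rec$condition == cond & rec$stratum2 == s]
      ctl <- rec$frac[rec$condition == control & rec$stratum2 == s]
      if (!length(tr) || !length(ctl)) next
      w <- wilcoxon_rank_sum(tr, ctl)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, stratum = s,
                   delta_m = mean(tr) - mean(ctl), p = w$p,
                   n_treat = length(tr), n_control = length(ctl),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
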