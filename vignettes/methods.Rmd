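---
title: "Methods: rDNA haplotypes, allele-specific methylation and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rDNA haplotypes, allele-specific methylation and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaepi)
```

## The model

Ribosomal DNA (rDNA) is a multi-copy locus: each genome carries on the order
of a hundred near-identical tandem copies of a ~15 kb 45S unit. Copies are
similar but not identical — a panel of intra-unit SNVs partitions them into a
small number of *haplotypes* — and each copy independently carries an
epigenetic state, classically bimodal: CpG-dense units are either almost fully
methylated (silenced) or almost fully unmethylated (active).

`rdnaepi` models and analyses three data modalities over a single-unit
reference coordinate system (see `rdna_reference()`; TSS-relative labels skip
zero, so `-104` is 104 bp upstream of the first transcribed base):

* **Long reads** spanning one or more concatenated units. Reads are segmented
  modulo the unit length (`segment_units()`), each covered unit is genotyped
  at the SNV panel, and per-unit genotypes drive haplotype discovery and
  assignment.
* **Bisulfite short reads**, where C→T (or G→A, depending on strand context)
  conversion confounds genotyping. Conversion-aware calls
  (`genotype_bs_read()`) stratify reads by allele before computing per-read
  methylation (`allele_specific_methylation()`).
* **rRNA reads**, whose allele frequencies reflect which DNA copies are
  transcriptionally active, linking methylation to expression
  (`adjust_aaf()`, `correlation_improvement()`).

A seeded simulator (`simulation_config()`, `simulate_ground_truth()` and the
`simulate_*` family) generates all three modalities from a known array, so
every estimator in the package is testable against planted truth.

## Haplotype discovery and assignment

Per-unit genotypes are clustered with average-linkage hierarchical clustering
on a missing-aware normalized Hamming distance: the distance between two units
is the mismatch fraction over panel positions observed in both, and pairs
sharing fewer than `min_shared` positions get distance 1.

The number of haplotypes is chosen by maximum mean silhouette width, with one
robustness refinement: units carrying several genotyping errors detach from
the tree *above* the true between-haplotype merge heights, so a naive
`cutree(k)` spends its first cuts isolating noise. `discover_haplotypes()`
therefore scans cut levels, sets aside clusters smaller than
`max(3, 1% of units)` as outliers, scores the silhouette on the retained
units, and reports the retained-cluster count (bounded to 2–8). The first
maximum wins, keeping the choice deterministic.

Assignment (`assign_haplotype()`) scores the fraction of observed
discriminating sites matching each consensus; exact ties and scores below
`min_score` (default 0.6) yield `"unassigned"` rather than an arbitrary call.
Co-localization (`colocalization()`) then asks, for reads covering at least
two assigned units, what fraction of a read's units share each haplotype —
under perfect within-read homogeneity the row-normalized matrix is the
identity on its diagonal.

## Bisulfite genotyping and allele-specific methylation

On original-top (OT/CTOT) contexts an observed T at a C/x SNV may be a
converted C; on original-bottom (OB/CTOB) contexts an observed A may be a
converted G. `genotype_bs_read()` enumerates, per allele and context, the set
of observable bases; a read is assigned an allele only when exactly one
allele is compatible, otherwise it is `"ambiguous"`. This rule is verified in
the test suite against a full 4-context × 12-allele-pair × 4-base enumeration
oracle and a strand-complementation symmetry property.

`allele_specific_methylation()` computes per-read CpG methylation fractions
in a window around the SNV (the SNV-overlapping CpG and its immediate
neighbor are excluded, since the variant itself perturbs the dinucleotide),
requiring `min_cpgs` (default 2) informative CpGs per read. By construction
the pooled mean equals the allele-frequency-weighted sum of stratum means,
`sum(f_a * m_a)`, an identity the tests check to 1e-12.

## Epivariant detection

`detect_epivariants()` compares the two allele strata of per-read methylation
fractions at each panel SNV with a Wilcoxon rank-sum test
(`wilcoxon_rank_sum()`: exact enumeration when the pooled sample is untied
and has at most 20 observations, normal approximation with tie correction
and continuity correction otherwise; two-sided), then applies
Benjamini–Hochberg FDR (`bh_fdr()`) across the per-sample family of testable
SNVs, flagging q < alpha (default 0.01). Positions with fewer than
`min_reads` (default 10) reads per allele are not tested. The calibration
and power of this procedure were validated on simulated nulls (bimodal
per-read fractions with equal mixing in both strata) and planted effects;
with a mean stratum difference of 0.5 and 30 reads per allele the empirical
power is 1.

## Copy number

`estimate_cn()` converts the ratio of rDNA coverage to single-copy background
coverage into copies per diploid genome, `2 * depth_rdna / depth_background`,
using lightly trimmed mean depths (1% by default) for outlier robustness. Two variants are
provided: *whole-unit* (coding span) and *18S-only* (coverage restricted to
the annotated 18S interval); on simulated tracks both recover the planted
copy number within 5% and agree with each other.

## Methylation disorder and aging dynamics

Per-read methylation disorder is the binary entropy of the read's methylation
fraction (`read_entropy()`; `H(3/4) ≈ 0.8113` for a 4-CpG read with 3
methylated). This *binary* (fraction-based) entropy deliberately ignores the
CpG ordering; `sample_disorder(..., method = "pattern")` offers the
complementary block-transition view. Reads are stratified into ATA /
non-ATA / unassigned by the stratifying SNV alleles; age trends are per-sample
stratum means regressed on age (`age_trend()`). In simulations with an aging
effect confined to non-ATA units, non-ATA methylation and disorder rise with
age while the ATA stratum stays flat. `expected_mirror_correlation()`
encodes the bookkeeping consequence of a fixed total: if the ATA fraction is
`baseline - nonata` (unclipped), its age correlation is exactly `-r`.

## Methylation-adjusted allele frequency

If only unmethylated copies transcribe, an alternative allele at DNA
frequency `f` with allele-specific methylation `m_alt`, `m_ref` is expected
at rRNA frequency

`adjust_aaf(f, m_alt, m_ref) = f (1 - m_alt) / (f (1 - m_alt) + (1 - f)(1 - m_ref))`

— e.g. `adjust_aaf(0.5, 0.8, 0) = 1/6`. `correlation_improvement()` compares
the correlation of observed rRNA AAFs with raw DNA AAFs versus adjusted
expectations across samples; under silencing the adjusted correlation
dominates.

## The simulator: scope and limits

`simulate_ground_truth()` draws a tandem array whose haplotype sequence is a
first-order Markov chain with neighbor concordance `rho` (stationary over
the four toy haplotypes ATA/ATG/CCA/CTA), assigns each unit an all-or-none
methylation state by haplotype-specific probabilities, then derives per-CpG
states with symmetric noise `cpg_noise`. Long reads cover geometric unit
counts with per-site genotype and methylation-call error; bisulfite reads
have strand contexts, conversion failures and per-CpG noise; rRNA counts
weight units by `1 - methylation`; coverage tracks are Poisson. Aging
cohorts (`simulate_aging_cohort()`) add a linear methylation drift restricted
to non-ATA units.

Limits are deliberate: there is no sequence-level read simulation (reads are
site-call tables, not FASTQ), no IGS/intergenic model beyond a background
coverage length, no inter-unit recombination, and the all-or-none unit state
plus symmetric noise is the simplest generator of the observed bimodality.
All randomness flows through named sub-streams of a single seed, so any
pipeline run is reproducible byte-for-byte (`run_pipeline()` manifests
record a config hash and no timestamps).

## Numerical conventions

* Unit-mean methylation calls at probability scale are binarized at 0.5
  before bimodality and entropy computations.
* Bimodality is the fraction of assigned, sufficiently covered units with
  unit-mean methylation at most 0.2 or at least 0.8.
* Parameter-recovery checks on stochastic simulations average 8 replicate
  arrays: a single ~150-unit array's realized stratum methylation has
  SD ≈ 0.05 from the unit-level Bernoulli draws alone, so the mean over
  replicates — not one draw — is the estimand compared within ±0.05.
* Classed conditions (`invalid_config`, `insufficient_data`,
  `empty_result`, ...) separate user errors from degenerate data throughout.

## Worked example

```{r example}
ref <- toy_rdna_reference()
panel <- toy_snv_panel(ref)
truth <- simulate_ground_truth(simulation_config(seed = 1L), ref)
obs <- simulate_long_reads(truth, panel, n_reads = 300L)
defs <- discover_haplotypes(obs, naming_positions = toy_naming_positions())
defs$labels
asg <- assign_haplotypes(obs, defs)
mean(asg$label == asg$true_haplotype)

bs <- simulate_bisulfite_reads(truth, panel, depth = 40)
asm <- allele_specific_methylation(bs, tss_to_ref(6007L, ref$tss))
asm$m          # per-allele mean methylation
asm_pooled_mean(asm)
```
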