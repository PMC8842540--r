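# rdnaepi

Genetic and epigenetic analysis of multi-copy ribosomal DNA (rDNA).

Mammalian genomes carry ~100–200 near-identical tandem copies of the 45S rDNA
unit. Copies differ at a small panel of intra-unit SNVs — partitioning them
into *haplotypes* — and each copy carries its own, typically all-or-none, CpG
methylation state. `rdnaepi` provides:

* **Haplotypes** — segment long reads into unit copies, discover haplotypes by
  average-linkage clustering of per-unit genotypes with silhouette-based model
  selection, assign units, and measure within-read haplotype co-localization
  and per-haplotype methylation profiles.
* **Bisulfite-aware genotyping ("blink")** — conversion-aware SNV calls on
  bisulfite reads (a T on the top strand may be a converted C), then
  allele-stratified per-read methylation around each SNV.
* **Epivariants** — SNVs whose two alleles differ in methylation, detected by
  Wilcoxon rank-sum tests under Benjamini–Hochberg FDR control, with
  cross-strain sharing classification and sample clustering.
* **Copy number** — coverage-ratio estimates (whole-unit and 18S-only
  variants) of rDNA copies per diploid genome.
* **Dynamics** — per-read methylation entropy, sample-level disorder, aging
  trends and the ATA / non-ATA dichotomy.
* **Expression** — rRNA alternative-allele frequencies and a
  methylation-adjusted expected AAF linking methylation to transcription.
* **Simulator + CLI** — a fully seeded generator for arrays, long reads,
  bisulfite reads, rRNA counts, coverage and aging cohorts, plus `run_*`
  pipeline stages with byte-reproducible outputs and manifests.

See the `methods` vignette (`vignettes/methods.Rmd`) for the statistical
details and parameter rationale.

## Worked example

Simulate an rDNA array, recover its haplotype structure from long reads, and
measure allele-specific methylation from bisulfite reads:

```r
library(rdnaepi)

ref   <- toy_rdna_reference()          # bundled ~15 kb synthetic unit
panel <- toy_snv_panel(ref)            # 12-SNV haplotype panel
truth <- simulate_ground_truth(simulation_config(seed = 1L), ref)

# long reads -> haplotype discovery and assignment
obs  <- simulate_long_reads(truth, panel, n_reads = 300L)
defs <- discover_haplotypes(obs, naming_positions = toy_naming_positions())
defs$labels
#> [1] "ATG" "CCA" "CTA" "ATA"
asg <- assign_haplotypes(obs, defs)
mean(asg$label == asg$true_haplotype)  # includes partial, unassigned units
#> [1] 0.7583445
mean(asg$label[asg$completeness >= 0.95] ==
     asg$true_haplotype[asg$completeness >= 0.95])
#> [1] 1

# bisulfite reads -> allele-stratified methylation at a stratifying SNV
bs  <- simulate_bisulfite_reads(truth, panel, depth = 40)
asm <- allele_specific_methylation(bs, tss_to_ref(6007L, ref$tss))
asm$m                                  # ATA-specific A allele is methylated
#>         A         G
#> 0.7212121 0.0781250
asm_pooled_mean(asm)                   # equals sum(f * m) exactly
#> [1] 0.3401235
```

The same analyses run as pipeline stages writing TSV/JSON outputs with
deterministic manifests:

```r
run_pipeline("out_dir", seed = 1L)     # simulate -> haplotype -> asm ->
                                       # epivar -> cn -> report
```

## License

MIT (see `LICENSE`).
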