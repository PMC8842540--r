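test_that("simulation_config validates probabilities", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(neighbor_concordance = 1.2),
               class = "invalid_config")
  expect_error(simulation_config(cpg_noise = -0.1), class = "invalid_config")
  expect_error(simulation_config(aging_drift = -1), class = "invalid_config")
})

test_that("simulate_array honors the Markov neighbor model", {
  ref <- fx_reference()
  # rho = 1, one cluster: a single haplotype throughout
  t1 <- simulate_array(simulation_config(n_clusters = 1L,
                                         units_per_cluster = 10L,
                                         neighbor_concordance = 1,
                                         seed = 5L), ref)
  expect_equal(nrow(t1$units), 10L)
  expect_length(unique(t1$units$haplotype), 1L)
  # rho = 0: neighbors never repeat (next label uniform over the others)
  t0 <- simulate_array(simulation_config(n_clusters = 1L,
                                         units_per_cluster = 500L,
                                         neighbor_concordance = 0,
                                         seed = 5L), ref)
  h <- t0$units$haplotype
  expect_identical(sum(h[-1] == h[-length(h)]), 0L)
  # zero units: empty truth
  t_empty <- simulate_array(simulation_config(n_clusters = 0L,
                                              units_per_cluster = 10L), ref)
  expect_equal(nrow(t_empty$units), 0L)
})

test_that("stationary label frequencies are uniform (symmetric kernel)", {
  t <- simulate_array(simulation_config(n_clusters = 1L,
                                        units_per_cluster = 10000L,
                                        neighbor_concordance = 0.5,
                                        seed = 8L), fx_reference())
  freq <- table(t$units$haplotype) / 10000
  # autocorrelation of the chain at rho=0.5 is 1/3; effective n ~ 5000,
  # 3 MC SE ~ 0.019
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("simulate_methylation produces the bimodal unit model", {
  cfg <- simulation_config(n_clusters = 1L, units_per_cluster = 50L, seed = 3L)
  truth <- simulate_array(cfg, fx_reference())
  all1 <- simulate_methylation(truth, pi = c(ATA = 1, ATG = 1, CCA = 1,
                                             CTA = 1), eps = 0)
  expect_true(all(all1$meth == 1L))
  all0 <- simulate_methylation(truth, pi = c(ATA = 0, ATG = 0, CCA = 0,
                                             CTA = 0), eps = 0)
  expect_true(all(all0$meth == 0L))
  expect_error(simulate_methylation(truth, pi = c(ATA = 1)),
               class = "invalid_config")
})

test_that("per-unit methylation mean matches its closed form", {
  pi0 <- 0.6
  eps <- 0.05
  cfg <- simulation_config(n_clusters = 1L, units_per_cluster = 2000L,
                           seed = 21L)
  truth <- simulate_array(cfg, fx_reference())
  truth <- simulate_methylation(truth,
                                pi = c(ATA = pi0, ATG = pi0, CCA = pi0,
                                       CTA = pi0), eps = eps)
  expected <- pi0 * (1 - eps) + (1 - pi0) * eps
  # dominated by the unit-level Bernoulli: 3 SE ~ 3*sqrt(.24/2000) ~ 0.033
  expect_lt(abs(mean(truth$meth) - expected), 0.033)
})

test_that("simulate_long_reads is error-free when told to be", {
  truth <- fx_truth(7L)
  obs <- simulate_long_reads(truth, fx_panel(), n_reads = 50L,
                             genotype_error = 0, meth_call_error = 0,
                             seed = 1L)
  defs <- toy_haplotype_definitions()
  for (i in seq_len(nrow(obs$units))) {
    g <- obs$genotypes[i, ]
    cov <- !is.na(g)
    truth_g <- defs$consensus[obs$units$true_haplotype[i], names(g)[cov]]
    expect_identical(unname(g[cov]), unname(truth_g))
  }
  expect_true(all(obs$units$completeness >= 0 & obs$units$completeness <= 1))
  expect_true(all(obs$units$ordinal >= 1L))
})

test_that("genotype miscall rate matches genotype_error", {
  obs <- simulate_long_reads(fx_truth(7L), fx_panel(), n_reads = 800L,
                             genotype_error = 0.05, meth_call_error = 0,
                             seed = 2L)
  defs <- toy_haplotype_definitions()
  truth_g <- defs$consensus[obs$units$true_haplotype, colnames(obs$genotypes)]
  cov <- !is.na(obs$genotypes)
  rate <- mean(obs$genotypes[cov] != truth_g[cov])
  se <- sqrt(0.05 * 0.95 / sum(cov))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("single-unit reads have one observation each", {
  obs <- simulate_long_reads(fx_truth(7L), fx_panel(), n_reads = 40L,
                             unit_count_probs = 1, seed = 3L)
  expect_true(all(table(obs$units$read_id) == 1L))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 11L)
  ref <- fx_reference()
  expect_identical(simulate_ground_truth(cfg, ref),
                   simulate_ground_truth(cfg, ref))
  truth <- simulate_ground_truth(cfg, ref)
  expect_identical(simulate_long_reads(truth, fx_panel(), n_reads = 30L),
                   simulate_long_reads(truth, fx_panel(), n_reads = 30L))
  expect_identical(simulate_bisulfite_reads(truth, fx_panel(), depth = 3),
                   simulate_bisulfite_reads(truth, fx_panel(), depth = 3))
  # distinct streams from one seed
  expect_false(identical(
    simulate_bisulfite_reads(truth, fx_panel(), depth = 3, stream = "a")$reads,
    simulate_bisulfite_reads(truth, fx_panel(), depth = 3, stream = "b")$reads))
})

test_that("perfect conversion reports unit states faithfully", {
  cfg <- simulation_config(n_clusters = 1L, units_per_cluster = 20L, seed = 9L)
  truth <- simulate_array(cfg, fx_reference())
  meth1 <- simulate_methylation(truth, pi = c(ATA = 1, ATG = 1, CCA = 1,
                                              CTA = 1), eps = 0)
  bs1 <- simulate_bisulfite_reads(meth1, fx_panel(), depth = 2,
                                  conversion_rate = 1, conversion_failure = 0)
  expect_true(all(bs1$cpg_calls$state == 1L))
  meth0 <- simulate_methylation(truth, pi = c(ATA = 0, ATG = 0, CCA = 0,
                                              CTA = 0), eps = 0)
  bs0 <- simulate_bisulfite_reads(meth0, fx_panel(), depth = 2,
                                  conversion_rate = 1, conversion_failure = 0)
  expect_true(all(bs0$cpg_calls$state == 0L))
  expect_error(simulate_bisulfite_reads(meth0, fx_panel(), read_length = 1L),
               class = "invalid_config")
})

test_that("bisulfite CpG methylation fraction tracks the truth mean", {
  truth <- fx_truth(42L)
  bs <- fx_bs(42L)
  expect_lt(abs(mean(bs$cpg_calls$state) - mean(truth$meth)), 0.05)
})

test_that("rRNA counts follow the expression weight law", {
  truth <- fx_truth(42L)
  panel <- fx_panel()
  depth <- 20000L
  counts <- simulate_rrna_counts(truth, panel, depth = depth, seed = 5L)
  w <- 1 - rowMeans(truth$meth)
  defs <- truth$config$haplotypes
  for (p in panel$position[c(1, 5, 12)]) {
    alt <- panel_alleles(panel, p)[2]
    unit_allele <- defs$consensus[truth$units$haplotype, as.character(p)]
    expected <- sum(w[unit_allele == alt]) / sum(w)
    d <- counts[counts$position == p, ]
    got <- sum(d$count[d$allele == alt]) / sum(d$count)
    se <- sqrt(expected * (1 - expected) / depth)
    expect_lt(abs(got - expected), 3 * se + 1e-9)
  }
})

test_that("uniform weights make rRNA match DNA allele frequencies", {
  cfg <- simulation_config(n_clusters = 2L, units_per_cluster = 60L,
                           seed = 13L)
  truth <- simulate_array(cfg, fx_reference())
  truth <- simulate_methylation(truth, pi = c(ATA = 0, ATG = 0, CCA = 0,
                                              CTA = 0), eps = 0)
  panel <- fx_panel()
  rna <- simulate_rrna_counts(truth, panel, depth = 30000L, seed = 2L)
  dna <- dna_allele_counts(truth, panel)
  p <- panel$position[1]
  alt <- panel_alleles(panel, p)[2]
  f_rna <- with(rna[rna$position == p, ], sum(count[allele == alt]) /
                  sum(count))
  f_dna <- with(dna[dna$position == p, ], sum(count[allele == alt]) /
                  sum(count))
  expect_lt(abs(f_rna - f_dna), 3 * sqrt(0.25 / 30000))
})

test_that("fully methylated alt units are silenced in rRNA", {
  cfg <- simulation_config(n_clusters = 10L, units_per_cluster = 10L,
                           seed = 17L)
  truth <- simulate_array(cfg, fx_reference())
  expect_true(all(c("ATA", "ATG", "CCA", "CTA") %in% truth$units$haplotype))
  # non-ATA (alt carriers at ITS2 positions) fully methylated, ATA unmethylated
  truth <- simulate_methylation(truth, pi = c(ATA = 0, ATG = 1, CCA = 1,
                                              CTA = 1), eps = 0)
  counts <- simulate_rrna_counts(truth, fx_panel(), depth = 5000L, seed = 3L)
  p <- tss_to_ref(6007L, fx_reference()$tss)
  d <- counts[counts$position == p, ]
  expect_identical(sum(d$count[d$allele == "G"]), 0L)

  all_meth <- simulate_methylation(truth, pi = c(ATA = 1, ATG = 1, CCA = 1,
                                                 CTA = 1), eps = 0)
  expect_error(simulate_rrna_counts(all_meth, fx_panel()),
               class = "zero_weight")
})

test_that("aging cohort drifts only the non-ATA strata", {
  cfg <- simulation_config(n_clusters = 6L, units_per_cluster = 25L,
                           seed = 19L, cpg_noise = 0.01)
  ref <- fx_reference()
  ages <- c(3, 12, 24)
  # delta = 0: identical to base truth
  c0 <- simulate_aging_cohort(ages, cfg, ref, delta = 0)
  expect_identical(c0[[1]]$truth$meth, c0[[3]]$truth$meth)
  # delta > 0: ATA rows untouched, non-ATA gain matches the closed form
  delta <- 0.01
  ch <- simulate_aging_cohort(ages, cfg, ref, delta = delta)
  base <- simulate_ground_truth(cfg, ref)
  ata <- base$units$haplotype == "ATA"
  expect_gt(sum(ata), 0L)
  for (i in seq_along(ages)) {
    m <- ch[[i]]$truth$meth
    expect_identical(m[ata, ], base$meth[ata, ])
    non <- m[!ata, ]
    base_non <- mean(base$meth[!ata, ])
    expected <- base_non + (1 - base_non) * min(1, delta * ages[i])
    se <- sqrt(0.25 / length(non))
    expect_lt(abs(mean(non) - expected), 3 * se + 0.01)
  }
  expect_error(simulate_aging_cohort(numeric(0), cfg, ref),
               class = "invalid_config")
  expect_error(simulate_aging_cohort(c(3, -1), cfg, ref),
               class = "invalid_config")
})

test_that("coverage simulation hits its Poisson means", {
  cov <- simulate_coverage(cn = 150, background_depth = 10,
                           unit_length = 15000L, background_length = 20000L,
                           seed = 23L)
  expect_length(cov$rdna_depth, 15000L)
  # mean rdna depth = 10 * 150 / 2 = 750; 3 SE of a Poisson mean
  expect_lt(abs(mean(cov$rdna_depth) - 750), 3 * sqrt(750 / 15000))
  expect_lt(abs(mean(cov$background_depth) - 10), 3 * sqrt(10 / 20000))
})

test_that("simulate_read_fractions matches its mixture expectation", {
  set.seed(31)
  x <- simulate_read_fractions(20000L, pi = 0.3, n_cpg = 8L, eps = 0.02)
  expected <- 0.3 * 0.98 + 0.7 * 0.02
  expect_lt(abs(mean(x) - expected), 3 * sqrt(0.25 / 20000) + 0.005)
  expect_true(all(x >= 0 & x <= 1))
})
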