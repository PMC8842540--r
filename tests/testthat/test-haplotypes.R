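toy_defs <- function() toy_haplotype_definitions()

test_that("haplotype_defs infers discriminating positions", {
  cons <- matrix(c("A", "A", "C", "G", "T", "T"), nrow = 2, byrow = FALSE,
                 dimnames = list(c("h1", "h2"), c("10", "20", "30")))
  d <- haplotype_defs(cons)
  expect_identical(d$discriminating, "20")
  rownames(cons) <- c("h1", "h1")
  expect_error(haplotype_defs(cons), class = "invalid_defs")
})

test_that("genotype_dist is a missing-aware normalized Hamming distance", {
  g <- rbind(c("A", "C", "G", "T"),
             c("A", "C", "G", "T"),
             c("A", "C", "G", "A"),
             c("T", "G", "C", "A"),
             c("A", NA, NA, NA))
  colnames(g) <- as.character(1:4)
  d <- as.matrix(rdnaepi:::genotype_dist(g, min_shared = 1L))
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 0.25)   # one mismatch over four shared sites
  expect_equal(d[1, 4], 1)
  expect_equal(d[1, 5], 0)      # single shared site, matching
  # with min_shared = 3 the sparse unit is pushed to distance 1
  d3 <- as.matrix(rdnaepi:::genotype_dist(g, min_shared = 3L))
  expect_equal(d3[1, 5], 1)
  expect_equal(d3[1, 3], 0.25)
})

test_that("discover_haplotypes recovers the truth from error-free reads", {
  truth <- fx_truth(42L)
  obs <- simulate_long_reads(truth, fx_panel(), n_reads = 250L,
                             genotype_error = 0, meth_call_error = 0,
                             seed = 6L)
  defs <- discover_haplotypes(obs, naming_positions = toy_naming_positions())
  expect_setequal(defs$labels, c("ATA", "ATG", "CCA", "CTA"))
  toy <- toy_defs()
  expect_identical(defs$consensus[toy$labels, colnames(toy$consensus)],
                   toy$consensus)
  cl <- attr(defs, "cluster")
  expect_length(cl, sum(obs$units$completeness >= 0.95))
  expect_true(all(cl %in% c(defs$labels, "outlier")))
  # fixed k gives the same consensus
  defs4 <- discover_haplotypes(obs, k = 4L,
                               naming_positions = toy_naming_positions())
  expect_setequal(defs4$labels, toy$labels)
})

test_that("discover_haplotypes handles matrix input and size-ordered labels", {
  toy <- toy_defs()
  g <- toy$consensus[c(rep("ATA", 12), rep("CCA", 8)), ]
  rownames(g) <- NULL
  defs <- discover_haplotypes(g)
  expect_identical(defs$labels, c("H1", "H2"))
  expect_identical(unname(defs$consensus["H1", ]),
                   unname(toy$consensus["ATA", ]))
  expect_identical(unname(defs$consensus["H2", ]),
                   unname(toy$consensus["CCA", ]))
  expect_error(discover_haplotypes(g[1, , drop = FALSE]),
               class = "insufficient_data")
  expect_error(discover_haplotypes(g, naming_positions = c(1L, 2L)),
               class = "invalid_config")
})

test_that("discover_haplotypes degenerate paths: k = 1 and identical units", {
  toy <- toy_defs()
  g <- toy$consensus[rep("ATG", 5), ]
  rownames(g) <- NULL
  d1 <- discover_haplotypes(g, k = 1L)
  expect_identical(unname(d1$consensus[1, ]), unname(toy$consensus["ATG", ]))
  # identical vectors with automatic k collapse to one cluster
  auto <- discover_haplotypes(g)
  expect_length(auto$labels, 1L)
})

test_that("assign_haplotype scores matching fractions and abstains on ties", {
  toy <- toy_defs()
  a <- assign_haplotype(toy$consensus["CTA", ], toy)
  expect_identical(a$label, "CTA")
  expect_equal(a$score, 1)
  # all discriminating sites missing: unassigned with NA score
  g_na <- setNames(rep(NA_character_, ncol(toy$consensus)),
                   colnames(toy$consensus))
  a_na <- assign_haplotype(g_na, toy)
  expect_identical(a_na$label, "unassigned")
  expect_true(is.na(a_na$score))
  # exact tie between two definitions is never broken arbitrarily
  cons <- matrix(c("A", "A", "C", "C"), nrow = 2, byrow = TRUE,
                 dimnames = list(c("h1", "h2"), c("10", "20")))
  tie <- assign_haplotype(c(`10` = "A", `20` = "C"), haplotype_defs(cons))
  expect_identical(tie$label, "unassigned")
  expect_equal(tie$score, 0.5)
  # best score below min_score abstains
  g1 <- toy$consensus["ATA", ]
  g1[1] <- "T"
  low <- assign_haplotype(g1, toy, min_score = 0.95)
  expect_identical(low$label, "unassigned")
  expect_lt(low$score, 0.95)
})

test_that("assign_haplotypes appends label and score to the units table", {
  obs <- simulate_long_reads(fx_truth(42L), fx_panel(), n_reads = 40L,
                             genotype_error = 0, meth_call_error = 0,
                             seed = 2L)
  asg <- assign_haplotypes(obs, toy_defs())
  expect_identical(nrow(asg), nrow(obs$units))
  expect_true(all(c("label", "score") %in% names(asg)))
  full <- asg$completeness >= 0.95
  expect_identical(asg$label[full], asg$true_haplotype[full])
})

test_that("haplogroup extracts the leading allele letter", {
  expect_identical(haplogroup(c("ATA", "CCA", "CTA", "ATG")),
                   c("A", "C", "C", "A"))
  expect_error(haplogroup("unassigned"), class = "unknown_label")
  expect_error(haplogroup("X"), class = "unknown_label")
})

test_that("colocalization matches a hand-computed example", {
  asg <- data.frame(
    read_id = c("r1", "r1", "r1", "r2", "r2", "r3", "r3"),
    label = c("ATA", "ATA", "CCA", "ATA", "unassigned", "CCA", "CCA"),
    stringsAsFactors = FALSE)
  cm <- colocalization(asg)
  expect_identical(rownames(cm$matrix), c("ATA", "CCA"))
  expect_identical(colnames(cm$matrix), c("ATA", "CCA", "unassigned"))
  # r2 has a single assigned unit and is excluded
  expect_identical(unname(cm$support), c(1L, 2L))
  expect_equal(unname(cm$matrix["ATA", ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(cm$matrix["CCA", ]), c(1 / 3, 2 / 3, 0))
  expect_equal(unname(rowSums(cm$matrix)), c(1, 1))
  # no informative read: NA rows, zero support
  single <- data.frame(read_id = c("r1", "r1"),
                       label = c("ATA", "unassigned"))
  cm0 <- colocalization(single, labels = c("ATA", "CCA"))
  expect_true(all(is.na(cm0$matrix)))
  expect_identical(unname(cm0$support), c(0L, 0L))
})

test_that("colocalization diagonal dominates under strong clustering", {
  truth <- simulate_ground_truth(
    simulation_config(neighbor_concordance = 1, seed = 15L), fx_reference())
  obs <- simulate_long_reads(truth, fx_panel(), n_reads = 300L,
                             genotype_error = 0, meth_call_error = 0,
                             seed = 3L)
  asg <- assign_haplotypes(obs, toy_defs())
  # rho = 1: within a cluster every unit shares one haplotype, so over
  # assigned units each row's mass sits on its diagonal
  cm <- colocalization(asg[asg$label != "unassigned", ])
  d <- diag(cm$matrix[, rownames(cm$matrix), drop = FALSE])
  expect_true(all(d[cm$support > 0] == 1))
})

test_that("methylation_profile computes window means and bimodality", {
  ref <- fx_reference()
  cpgpos <- c(1000L, 2000L, 3000L, 14500L)  # last lies beyond the 3'ETS end
  meth <- matrix(c(1L, 1L, 1L, 0L,
                   0L, 0L, 0L, 1L,
                   1L, 0L, 1L, 0L,
                   1L, 1L, 1L, 1L),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(NULL, as.character(cpgpos)))
  obs <- structure(list(meth = meth, reference = ref), class = "unit_obs")
  asg <- data.frame(label = c("ATA", "ATA", "CCA", "unassigned"))
  mp <- methylation_profile(obs, asg)
  ata <- mp$profile[mp$profile$haplotype == "ATA", ]
  expect_equal(ata$mean_meth[ata$pos == 1000L], 0.5)
  expect_identical(ata$n[ata$pos == 1000L], 2L)
  expect_false(14500L %in% mp$profile$pos)
  expect_equal(sort(mp$unit_means$unit_mean),
               sort(c(1, 0, 2 / 3, 1)))
  # unassigned unit excluded from bimodality; CCA unit (2/3) is intermediate
  expect_equal(mp$bimodality, 2 / 3)
  expect_equal(unname(mp$bimodality_by_haplotype["ATA"]), 1)
  expect_equal(unname(mp$bimodality_by_haplotype["CCA"]), 0)
})

test_that("methylation_profile binarizes probability calls and skips NAs", {
  ref <- fx_reference()
  meth <- matrix(c(0.7, 0.3, 0.9,
                   NA, 1, 1),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("1000", "2000", "3000")))
  obs <- structure(list(meth = meth, reference = ref), class = "unit_obs")
  asg <- data.frame(label = c("ATA", "ATA"))
  mp <- methylation_profile(obs, asg)
  expect_equal(mp$unit_means$unit_mean, c(2 / 3, 1))
  expect_identical(mp$unit_means$n_cpgs, c(3L, 2L))
  p <- mp$profile
  expect_identical(p$n[p$pos == 1000L], 1L)
})

test_that("predict_haplogroup_aggregate pools the A strata", {
  agg <- predict_haplogroup_aggregate(0.3, 0.8, 0.1, 0.2)
  expect_equal(agg$f_a, 0.4)
  expect_equal(agg$m_a, (0.3 * 0.8 + 0.1 * 0.2) / 0.4)
  expect_error(predict_haplogroup_aggregate(0, 0.5, 0, 0.5),
               class = "undefined_aggregate")
  expect_error(predict_haplogroup_aggregate(-0.1, 0.5, 0.2, 0.5),
               class = "invalid_input")
})

test_that("segment_units folds concatenated coordinates modulo the unit", {
  ref <- fx_reference()
  L <- ref$unit_length
  span_len <- 14400L - 1L
  # one segment across the junction of copies 1 and 2
  sg <- data.frame(read_id = "r1", start = 14000L, end = L + 1001L)
  res <- segment_units(sg, ref)
  expect_identical(res$unit_copy, c(1L, 2L))
  expect_identical(res$ordinal, c(1L, 2L))
  expect_identical(res$cov_start, c(14000L, 1L))
  expect_identical(res$cov_end, c(L + 1L, 1001L))
  expect_equal(res$completeness, c((14400 - 14000) / span_len,
                                   1000 / span_len))
  # a full unit has completeness 1
  full <- segment_units(data.frame(read_id = "r2", start = 1L, end = L + 1L),
                        ref)
  expect_equal(full$completeness, 1)
})

test_that("segment_units skips gaps and merges split sub-segments", {
  ref <- fx_reference()
  L <- ref$unit_length
  gap <- segment_units(data.frame(read_id = "r1",
                                  start = c(1L, 2L * L + 1L),
                                  end = c(5001L, 2L * L + 1001L)), ref)
  expect_identical(gap$unit_copy, c(1L, 3L))
  expect_identical(gap$ordinal, c(1L, 2L))
  hull <- segment_units(data.frame(read_id = "r1",
                                   start = c(1L, 3001L),
                                   end = c(2001L, 4001L)), ref)
  expect_identical(nrow(hull), 1L)
  expect_identical(hull$cov_start, 1L)
  expect_identical(hull$cov_end, 4001L)
  expect_warning(
    bad <- segment_units(data.frame(read_id = "r1",
                                    start = c(1L, 1001L),
                                    end = c(2001L, 3001L)), ref),
    "contradictory")
  expect_identical(nrow(bad), 0L)
})
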