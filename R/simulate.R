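# Synthetic tandem rDNA arrays and derived datasets: long-read unit
# observations, bisulfite short reads, rRNA allele counts, coverage tracks and
# aging cohorts. The generator reproduces the statistical structure the
# analyses assume: haplotypes arranged in chromosomal clusters with neighbor
# concordance, unit-level bimodal CpG methylation with haplotype-dependent
# methylated fractions, strand-aware bisulfite conversion, expression weighted
# toward unmethylated units, and age-dependent methylation gain restricted to
# non-ATA haplotypes.
#
# All randomness flows from a single integer seed; each dataset draws from its
# own stream derived via derive_seed(seed, dataset_name), so datasets are
# reproducible independently of generation order.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analyses target: four chromosomal
#' clusters of 38 units (~152 copies per diploid), strong neighbor concordance,
#' and per-haplotype methylated fractions with ATA predominantly methylated
#' (~75%) and the others largely unmethylated.
#'
#' @param n_clusters Number of chromosomal rDNA clusters.
#' @param units_per_cluster Units per cluster.
#' @param haplotypes A [haplotype_defs()] object (consensus alleles of each
#'   haplotype at the panel positions).
#' @param neighbor_concordance Probability `rho` that the next unit in a
#'   cluster repeats the previous haplotype (first-order Markov chain; with
#'   probability `1 - rho` the label is uniform over the other labels).
#' @param methylated_fraction Named per-haplotype probabilities `pi_h` that a
#'   unit is in the methylated state.
#' @param cpg_noise Per-CpG flip probability `eps` away from the unit state.
#' @param conversion_rate Probability an unmethylated C reads as T after
#'   bisulfite conversion.
#' @param conversion_failure Probability a methylated C reads as T.
#' @param base_error Sequencing miscall probability (uniform over the other
#'   three bases).
#' @param aging_drift Per-month per-CpG methylation-gain probability `delta`
#'   applied to non-ATA units in aging cohorts.
#' @param seed Master integer seed.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_clusters = 4L,
                              units_per_cluster = 38L,
                              haplotypes = toy_haplotype_definitions(),
                              neighbor_concordance = 0.9,
                              methylated_fraction = c(ATA = 0.75, ATG = 0.05,
                                                      CCA = 0.15, CTA = 0.05),
                              cpg_noise = 0.02,
                              conversion_rate = 0.99,
                              conversion_failure = 0.005,
                              base_error = 0.002,
                              aging_drift = 0.01,
                              seed = 1L) {
  probs <- c(neighbor_concordance, methylated_fraction, cpg_noise,
             conversion_rate, conversion_failure, base_error)
  if (any(probs < 0 | probs > 1))
    stop_rdnaepi("all probabilities must lie in [0, 1]", "invalid_config")
  if (aging_drift < 0)
    stop_rdnaepi("aging_drift must be non-negative", "invalid_config")
  structure(list(n_clusters = as.integer(n_clusters),
                 units_per_cluster = as.integer(units_per_cluster),
                 haplotypes = haplotypes,
                 neighbor_concordance = neighbor_concordance,
                 methylated_fraction = methylated_fraction,
                 cpg_noise = cpg_noise,
                 conversion_rate = conversion_rate,
                 conversion_failure = conversion_failure,
                 base_error = base_error,
                 aging_drift = aging_drift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the haplotype arrangement of a tandem array
#'
#' Within each cluster, haplotype labels follow a first-order Markov chain:
#' the cluster-initial unit is uniform over labels; each subsequent unit
#' repeats its neighbor with probability `rho`, otherwise it is uniform over
#' the other labels.
#'
#' @param config A [simulation_config()].
#' @param reference An [rdna_reference()] (carried along for downstream
#'   dataset generation).
#' @return Object of class `rdna_truth`: `units` data.frame (`unit_id`,
#'   `cluster`, `index`, `haplotype`), `meth` (filled by
#'   [simulate_methylation()]), `cpg_pos`, `reference`, `config`.
#' @export
simulate_array <- function(config, reference = toy_rdna_reference()) {
  labels <- config$haplotypes$labels
  rho <- config$neighbor_concordance
  n <- config$n_clusters * config$units_per_cluster
  units <- if (n == 0L) {
    data.frame(unit_id = integer(0), cluster = integer(0), index = integer(0),
               haplotype = character(0), stringsAsFactors = FALSE)
  } else {
    hap <- with_seed(derive_seed(config$seed, "array"), {
      unlist(lapply(seq_len(config$n_clusters), function(cl) {
        h <- character(config$units_per_cluster)
        h[1L] <- sample(labels, 1L)
        if (config$units_per_cluster > 1L)
          for (i in 2L:config$units_per_cluster) {
            h[i] <- if (length(labels) == 1L || stats::runif(1) < rho) h[i - 1L]
                    else sample(setdiff(labels, h[i - 1L]), 1L)
          }
        h
      }))
    })
    data.frame(unit_id = seq_len(n),
               cluster = rep(seq_len(config$n_clusters),
                             each = config$units_per_cluster),
               index = rep(seq_len(config$units_per_cluster),
                           config$n_clusters),
               haplotype = hap, stringsAsFactors = FALSE)
  }
  structure(list(units = units, meth = NULL,
                 cpg_pos = reference$cpg_index,
                 reference = reference, config = config),
            class = "rdna_truth")
}

#' @export
print.rdna_truth <- function(x, ...) {
  cat(sprintf("rDNA array truth: %d units in %d clusters; methylation %s\n",
              nrow(x$units), length(unique(x$units$cluster)),
              if (is.null(x$meth)) "unset" else "set"))
  invisible(x)
}

#' Simulate per-unit bimodal CpG methylation states
#'
#' Each unit is "methylated" with its haplotype's probability `pi_h`; within a
#' methylated unit each CpG is 1 with probability `1 - eps`, within an
#' unmethylated unit with probability `eps`. This produces the unit-level
#' bimodality (units near fully methylated or fully unmethylated) that the
#' downstream analyses assume.
#'
#' @param truth An `rdna_truth` from [simulate_array()].
#' @param pi Named per-haplotype methylated fractions (defaults to the
#'   config's).
#' @param eps Per-CpG flip probability (defaults to the config's).
#' @return The truth with `meth` (units x CpGs 0/1 matrix) and
#'   `unit_methylated` filled.
#' @export
simulate_methylation <- function(truth, pi = NULL, eps = NULL) {
  cfg <- truth$config
  if (is.null(pi)) pi <- cfg$methylated_fraction
  if (is.null(eps)) eps <- cfg$cpg_noise
  labs <- unique(truth$units$haplotype)
  if (!all(labs %in% names(pi)))
    stop_rdnaepi(sprintf("methylated_fraction missing label(s): %s",
                         paste(setdiff(labs, names(pi)), collapse = ",")),
                 "invalid_config")
  n_units <- nrow(truth$units)
  n_cpg <- length(truth$cpg_pos)
  with_seed(derive_seed(cfg$seed, "methylation"), {
    p_unit <- unname(pi[truth$units$haplotype])
    m_unit <- stats::rbinom(n_units, 1L, p_unit)
    p_cpg <- ifelse(m_unit == 1L, 1 - eps, eps)
    meth <- matrix(stats::rbinom(n_units * n_cpg, 1L, rep(p_cpg, n_cpg)),
                   nrow = n_units, ncol = n_cpg,
                   dimnames = list(NULL, as.character(truth$cpg_pos)))
    truth$meth <- meth
    truth$unit_methylated <- m_unit
  })
  truth
}

#' Simulate a seeded ground-truth array in one call
#'
#' @inheritParams simulate_array
#' @return An `rdna_truth` with methylation states filled.
#' @export
simulate_ground_truth <- function(config = simulation_config(),
                                  reference = toy_rdna_reference()) {
  simulate_methylation(simulate_array(config, reference))
}

# consensus allele of a haplotype at panel positions ------------------------
hap_alleles <- function(defs, labels, positions) {
  defs$consensus[labels, as.character(positions), drop = FALSE]
}

#' Simulate long-read unit observations
#'
#' Each read covers a contiguous run of units from a random cluster and
#' offset; the first and last covered unit are truncated at a random offset
#' (completeness < 1), interior units are complete. Observed bases at panel
#' positions are miscalled with probability `genotype_error` (uniform over the
#' other three bases); per-CpG methylation calls are flipped with probability
#' `meth_call_error`.
#'
#' @param truth An `rdna_truth` with methylation states.
#' @param panel An [snv_panel()].
#' @param n_reads Number of reads.
#' @param unit_count_probs Distribution of the number of units per read
#'   (probabilities for 1, 2, ... units).
#' @param genotype_error Per-site miscall probability.
#' @param meth_call_error Per-CpG call flip probability.
#' @param seed Integer seed (defaults to the truth config's).
#' @return Object of class `unit_obs`: `units` data.frame (`read_id`,
#'   `ordinal`, `unit_id`, `true_haplotype`, `cov_start`, `cov_end`,
#'   `completeness`), `genotypes` (character matrix, observations x panel
#'   positions, NA = missing), `meth` (0/1 matrix, observations x CpGs, NA =
#'   uncovered).
#' @export
simulate_long_reads <- function(truth, panel,
                                n_reads = 500L,
                                unit_count_probs = c(.30, .25, .20, .15,
                                                     .07, .03),
                                genotype_error = 0.05,
                                meth_call_error = 0.05,
                                seed = NULL) {
  if (is.null(truth$meth))
    stop_rdnaepi("truth has no methylation states; run simulate_methylation()",
                 "invalid_truth")
  if (is.null(seed)) seed <- truth$config$seed
  ref <- truth$reference
  L <- ref$unit_length
  cpg <- truth$cpg_pos
  defs <- truth$config$haplotypes
  span <- coding_span(ref)
  span_len <- span[2L] - span[1L]

  with_seed(derive_seed(seed, "long_reads"), {
    rows <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      cl <- sample.int(truth$config$n_clusters, 1L)
      in_cl <- truth$units[truth$units$cluster == cl, , drop = FALSE]
      k <- sample.int(length(unit_count_probs), 1L, prob = unit_count_probs)
      start_idx <- sample.int(nrow(in_cl), 1L)
      idx <- start_idx:min(nrow(in_cl), start_idx + k - 1L)
      k <- length(idx)
      cov_start <- rep(1L, k)
      cov_end <- rep(L + 1L, k)  # half-open unit-local coverage
      # terminal truncation: read begins/ends inside its terminal units
      cov_start[1L] <- sample.int(L, 1L)
      cov_end[k] <- sample.int(L, 1L) + 1L
      if (k == 1L && cov_end[1L] <= cov_start[1L]) {
        tmp <- cov_start[1L]
        cov_start[1L] <- cov_end[1L] - 1L
        cov_end[1L] <- tmp + 1L
      }
      rows[[r]] <- data.frame(read_id = sprintf("read_%05d", r),
                              ordinal = seq_len(k),
                              unit_id = in_cl$unit_id[idx],
                              true_haplotype = in_cl$haplotype[idx],
                              cov_start = cov_start, cov_end = cov_end,
                              stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, rows)
    ov <- function(a, b) pmax(0L, pmin(obs$cov_end, b) - pmax(obs$cov_start, a))
    obs$completeness <- ov(span[1L], span[2L]) / span_len

    n_obs <- nrow(obs)
    unit_row <- match(obs$unit_id, truth$units$unit_id)
    # genotypes at covered panel positions, with miscalls
    true_g <- hap_alleles(defs, obs$true_haplotype, panel$position)
    covered_g <- outer(obs$cov_start, panel$position, `<=`) &
      outer(obs$cov_end, panel$position, `>`)
    g <- true_g
    err <- matrix(stats::runif(length(g)) < genotype_error, nrow = n_obs)
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      wrong <- vapply(g[err], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      g[err] <- wrong
    }
    g[!covered_g] <- NA_character_
    dimnames(g) <- list(NULL, as.character(panel$position))

    # methylation calls at covered CpGs, with flips
    covered_c <- outer(obs$cov_start, cpg, `<=`) &
      outer(obs$cov_end, cpg + 1L, `>`)
    m <- truth$meth[unit_row, , drop = FALSE]
    flip <- matrix(stats::runif(length(m)) < meth_call_error, nrow = n_obs)
    m <- abs(m - as.integer(flip))
    m[!covered_c] <- NA_integer_
    dimnames(m) <- list(NULL, as.character(cpg))

    structure(list(units = obs, genotypes = g, meth = m,
                   panel = panel, reference = ref),
              class = "unit_obs")
  })
}

# half-open coding-unit span: everything up to the IGS (or the whole unit)
coding_span <- function(reference) {
  r <- reference$regions
  i <- match("IGS", r$name)
  end <- if (is.na(i)) reference$unit_length + 1L else r$start[i]
  c(1L, end)
}

#' Simulate bisulfite-converted short reads
#'
#' Reads sample units uniformly; each read is assigned an original-top (OT) or
#' original-bottom (OB) conversion context with equal probability. On the
#' converted strand, cytosines read as T with probability `conversion_rate`
#' when the underlying state is unmethylated and `conversion_failure` when
#' methylated; non-CpG cytosines are always treated as unmethylated. SNV bases
#' pass through sequencing error and the same conversion rules; all bases are
#' reported in top-strand orientation.
#'
#' @param truth An `rdna_truth` with methylation states.
#' @param panel An [snv_panel()].
#' @param depth Mean per-base coverage over the unit.
#' @param read_length Read length in bases (>= 2).
#' @param conversion_rate,conversion_failure,base_error Override the config.
#' @param sample_id Sample label carried into the output.
#' @param seed Integer seed (defaults to the truth config's).
#' @param stream Name of the RNG stream (vary to draw independent datasets
#'   from one seed).
#' @return Object of class `bs_obs`: `reads` data.frame (`read_id`,
#'   `sample`, `unit_id`, `true_haplotype`, `start`, `end`, `context`),
#'   `snv_calls` (`read_id`, `pos`, `base`), `cpg_calls` (`read_id`, `pos`,
#'   `state` 1 = methylated).
#' @export
simulate_bisulfite_reads <- function(truth, panel,
                                     depth = 100,
                                     read_length = 150L,
                                     conversion_rate = NULL,
                                     conversion_failure = NULL,
                                     base_error = NULL,
                                     sample_id = "s1",
                                     seed = NULL,
                                     stream = "bisulfite") {
  if (read_length < 2L)
    stop_rdnaepi("read_length must be >= 2", "invalid_config")
  if (is.null(truth$meth))
    stop_rdnaepi("truth has no methylation states; run simulate_methylation()",
                 "invalid_truth")
  cfg <- truth$config
  if (is.null(conversion_rate)) conversion_rate <- cfg$conversion_rate
  if (is.null(conversion_failure)) conversion_failure <- cfg$conversion_failure
  if (is.null(base_error)) base_error <- cfg$base_error
  if (is.null(seed)) seed <- cfg$seed
  ref <- truth$reference
  L <- ref$unit_length
  cpg <- truth$cpg_pos
  defs <- cfg$haplotypes
  n_reads <- max(1L, round(depth * L / read_length))

  with_seed(derive_seed(seed, stream), {
    unit_row <- sample.int(nrow(truth$units), n_reads, replace = TRUE)
    start <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    end <- start + as.integer(read_length)           # half-open
    context <- sample(c("OT", "OB"), n_reads, replace = TRUE)
    reads <- data.frame(read_id = sprintf("%s_bs_%06d", sample_id,
                                          seq_len(n_reads)),
                        sample = sample_id,
                        unit_id = truth$units$unit_id[unit_row],
                        true_haplotype = truth$units$haplotype[unit_row],
                        start = start, end = end, context = context,
                        stringsAsFactors = FALSE)

    # --- SNV base readout (top-strand orientation) ---
    snv_calls <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      p <- panel$position[i]
      cov <- which(start <= p & p < end)
      if (!length(cov)) return(NULL)
      true <- hap_alleles(defs, reads$true_haplotype[cov], p)[, 1L]
      base <- true
      err <- stats::runif(length(cov)) < base_error
      if (any(err)) {
        bs <- c("A", "C", "G", "T")
        base[err] <- vapply(base[err], function(b)
          sample(setdiff(bs, b), 1L), character(1))
      }
      # conversion: panel positions never overlap a CpG in the bundled
      # reference; treat SNV cytosines as unmethylated context
      ot <- context[cov] == "OT"
      conv_c <- ot & base == "C" & stats::runif(length(cov)) < conversion_rate
      conv_g <- !ot & base == "G" & stats::runif(length(cov)) < conversion_rate
      base[conv_c] <- "T"
      base[conv_g] <- "A"
      data.frame(read_id = reads$read_id[cov], pos = p, base = base,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(snv_calls))
      snv_calls <- data.frame(read_id = character(0), pos = integer(0),
                              base = character(0), stringsAsFactors = FALSE)

    # --- CpG methylation readout (read's strand) ---
    # a CpG is readable when both its C and G are inside the read
    lo <- findInterval(start - 1L, cpg) + 1L
    hi <- findInterval(end - 1L, cpg + 1L)  # cpg p usable iff p + 1 <= end - 1
    n_per <- pmax(0L, hi - lo + 1L)
    ridx <- rep.int(seq_len(n_reads), n_per)
    cidx <- unlist(lapply(seq_len(n_reads), function(i)
      if (n_per[i] > 0L) lo[i]:hi[i] else integer(0)), use.names = FALSE)
    if (length(ridx)) {
      state_true <- truth$meth[cbind(unit_row[ridx], cidx)]
      keep_c <- ifelse(state_true == 1L, 1 - conversion_failure,
                       1 - conversion_rate)
      called_meth <- as.integer(stats::runif(length(ridx)) < keep_c)
      cpg_calls <- data.frame(read_id = reads$read_id[ridx],
                              pos = cpg[cidx],
                              state = called_meth,
                              stringsAsFactors = FALSE)
    } else {
      cpg_calls <- data.frame(read_id = character(0), pos = integer(0),
                              state = integer(0), stringsAsFactors = FALSE)
    }

    structure(list(reads = reads, snv_calls = snv_calls,
                   cpg_calls = cpg_calls, panel = panel, reference = ref),
              class = "bs_obs")
  })
}

#' Simulate rRNA allele counts
#'
#' Each rRNA read is drawn from a unit with weight `1 - mean(unit CpG
#' methylation)` (graded silencing of methylated units); the allele at each
#' panel SNV is taken from the source unit's haplotype.
#'
#' @param truth An `rdna_truth` with methylation states.
#' @param panel An [snv_panel()].
#' @param depth Number of rRNA reads to draw per SNV.
#' @param seed Integer seed (defaults to the truth config's).
#' @return Data frame (`position`, `allele`, `count`).
#' @export
simulate_rrna_counts <- function(truth, panel, depth = 1000L, seed = NULL) {
  if (is.null(truth$meth))
    stop_rdnaepi("truth has no methylation states", "invalid_truth")
  if (is.null(seed)) seed <- truth$config$seed
  w <- 1 - rowMeans(truth$meth)
  if (all(w <= 0))
    stop_rdnaepi("all units fully methylated: zero expression weight",
                 "zero_weight")
  defs <- truth$config$haplotypes
  with_seed(derive_seed(seed, "rrna"), {
    src <- sample.int(nrow(truth$units), depth, replace = TRUE, prob = w)
    alle <- hap_alleles(defs, truth$units$haplotype[src], panel$position)
    out <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      tab <- table(alle[, i])
      data.frame(position = panel$position[i],
                 allele = names(tab), count = as.integer(tab),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' DNA allele counts implied by the array composition
#'
#' @param truth An `rdna_truth`.
#' @param panel An [snv_panel()].
#' @return Data frame (`position`, `allele`, `count`) of unit counts per
#'   allele.
#' @export
dna_allele_counts <- function(truth, panel) {
  defs <- truth$config$haplotypes
  alle <- hap_alleles(defs, truth$units$haplotype, panel$position)
  out <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    tab <- table(alle[, i])
    data.frame(position = panel$position[i],
               allele = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate an aging cohort
#'
#' For each sample of age `a` months, CpGs of non-ATA units independently gain
#' methylation with probability `min(1, delta * a)`; ATA units are left
#' unchanged. Optionally generates bisulfite reads per sample.
#'
#' @param ages Numeric vector of ages in months (one sample per entry).
#' @param config A [simulation_config()]; its `aging_drift` is `delta` unless
#'   overridden.
#' @param reference An [rdna_reference()].
#' @param panel An [snv_panel()]; required when `depth > 0`.
#' @param delta Per-month per-CpG gain probability.
#' @param depth Bisulfite coverage per sample (0 = truth only).
#' @param read_length Bisulfite read length.
#' @param ata_label Label of the haplotype exempt from drift.
#' @return List of per-sample lists (`sample`, `age`, `truth`, `bs`).
#' @export
simulate_aging_cohort <- function(ages, config = simulation_config(),
                                  reference = toy_rdna_reference(),
                                  panel = NULL,
                                  delta = NULL, depth = 0,
                                  read_length = 150L,
                                  ata_label = "ATA") {
  if (!length(ages)) stop_rdnaepi("ages must be non-empty", "invalid_config")
  if (any(ages < 0)) stop_rdnaepi("ages must be non-negative", "invalid_config")
  if (is.null(delta)) delta <- config$aging_drift
  base <- simulate_ground_truth(config, reference)
  non_ata <- base$units$haplotype != ata_label
  lapply(seq_along(ages), function(i) {
    sid <- sprintf("age%g_s%02d", ages[i], i)
    truth_i <- base
    if (delta > 0 && any(non_ata)) {
      p <- min(1, delta * ages[i])
      truth_i$meth[non_ata, ] <- with_seed(
        derive_seed(config$seed, paste0("aging_", sid)), {
          m <- base$meth[non_ata, , drop = FALSE]
          gain <- matrix(stats::rbinom(length(m), 1L, p), nrow = nrow(m))
          pmax(m, gain)
        })
    }
    bs <- NULL
    if (depth > 0) {
      if (is.null(panel)) stop_rdnaepi("panel required when depth > 0",
                                       "invalid_config")
      bs <- simulate_bisulfite_reads(truth_i, panel, depth = depth,
                                     read_length = read_length,
                                     sample_id = sid,
                                     seed = config$seed,
                                     stream = paste0("bs_", sid))
    }
    list(sample = sid, age = ages[i], truth = truth_i, bs = bs)
  })
}

#' Simulate coverage tracks for copy-number estimation
#'
#' Per-base depths are Poisson: the rDNA unit at `background_depth * cn / 2`
#' (each diploid genome carries `cn` unit copies against a 2-copy background),
#' single-copy background intervals at `background_depth`.
#'
#' @param cn True copies per diploid genome.
#' @param background_depth Mean background depth.
#' @param unit_length Length of the rDNA unit track.
#' @param background_length Length of the background track.
#' @param seed Integer seed.
#' @return List with numeric vectors `rdna_depth` and `background_depth`.
#' @export
simulate_coverage <- function(cn = 150, background_depth = 10,
                              unit_length = 15000L,
                              background_length = 20000L, seed = 1L) {
  with_seed(derive_seed(seed, "coverage"), {
    list(rdna_depth = stats::rpois(unit_length, background_depth * cn / 2),
         background_depth = stats::rpois(background_length, background_depth))
  })
}

#' Draw read-level methylation fractions from the bimodal unit model
#'
#' Convenience generator used for calibration studies of the epivariant test:
#' each read comes from a methylated unit with probability `pi` and reports
#' `n_cpg` CpG calls at per-CpG fidelity `1 - eps`.
#'
#' @param n Number of reads.
#' @param pi Probability a read's unit is methylated.
#' @param n_cpg CpG calls per read.
#' @param eps Per-CpG flip probability.
#' @return Numeric vector of per-read methylated fractions.
#' @export
simulate_read_fractions <- function(n, pi, n_cpg = 8L, eps = 0.02) {
  state <- stats::rbinom(n, 1L, pi)
  p <- ifelse(state == 1L, 1 - eps, eps)
  stats::rbinom(n, n_cpg, p) / n_cpg
}
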