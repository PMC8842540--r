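# Haplotype discovery, assignment, co-localization and methylation profiles
# from long-read unit observations.
#
# Units are clustered on a missing-aware normalized Hamming distance between
# genotype vectors (average-linkage agglomerative clustering; k chosen by
# maximum mean silhouette unless supplied). Assignment scores a unit's
# genotype against each consensus over the discriminating positions; multiple
# sites are always used because no single position is strictly
# haplotype-specific.

#' Haplotype definitions
#'
#' @param consensus Character matrix: rows = haplotype labels, columns =
#'   reference positions (as character names), entries = consensus alleles.
#' @param discriminating Positions (column names) that differ between at least
#'   two haplotypes; defaults to all columns that do.
#' @return Object of class `haplotype_defs` with fields `labels`, `consensus`,
#'   `discriminating`.
#' @export
haplotype_defs <- function(consensus, discriminating = NULL) {
  stopifnot(is.matrix(consensus), !is.null(rownames(consensus)),
            !is.null(colnames(consensus)))
  if (anyDuplicated(rownames(consensus)))
    stop_rdnaepi("haplotype labels must be unique", "invalid_defs")
  if (is.null(discriminating)) {
    varies <- apply(consensus, 2, function(a) length(unique(a[!is.na(a)])) > 1L)
    discriminating <- colnames(consensus)[varies]
  }
  structure(list(labels = rownames(consensus),
                 consensus = consensus,
                 discriminating = as.character(discriminating)),
            class = "haplotype_defs")
}

#' @export
print.haplotype_defs <- function(x, ...) {
  cat(sprintf("haplotype definitions: %s over %d positions (%d discriminating)\n",
              paste(x$labels, collapse = ", "), ncol(x$consensus),
              length(x$discriminating)))
  invisible(x)
}

# missing-aware normalized Hamming distance between genotype vectors;
# pairs with fewer than min_shared co-observed sites get distance 1 to avoid
# spurious merging of sparsely covered units
genotype_dist <- function(g, min_shared = 3L) {
  obs <- (!is.na(g)) * 1
  shared <- obs %*% t(obs)
  matches <- matrix(0, nrow(g), nrow(g))
  for (b in c("A", "C", "G", "T")) {
    ind <- (!is.na(g) & g == b) * 1
    matches <- matches + ind %*% t(ind)
  }
  d <- 1 - matches / pmax(shared, 1)
  d[shared < min_shared] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}

#' Discover haplotypes from long-read genotype vectors
#'
#' Average-linkage agglomerative clustering on a missing-aware normalized
#' Hamming distance. The number of haplotypes is chosen by maximum mean
#' silhouette over `k = 2..8` unless supplied. Because units carrying several
#' genotyping errors detach from the tree above the true between-haplotype
#' merge heights, cut levels deeper than the reported `k` are searched and
#' clusters smaller than `min_cluster_frac` of the units are set aside as
#' outliers before the silhouette is scored: `k` counts (and the consensus is
#' built from) the retained clusters only. The consensus is the majority
#' allele per cluster and position; positions whose consensus differs between
#' any two clusters become discriminating. Labels are rendered from the
#' consensus alleles at `naming_positions` when given, else `H1..Hk` (largest
#' cluster first).
#'
#' @param obs A `unit_obs` object (or a genotype matrix with position column
#'   names; completeness filtering then requires `completeness`).
#' @param k Number of haplotypes; `NULL` = silhouette selection.
#' @param completeness_min Minimum unit completeness for inclusion (partial
#'   units yield missing-heavy vectors that distort clustering).
#' @param naming_positions Reference coordinates whose consensus alleles spell
#'   the haplotype label.
#' @param min_shared Minimum co-observed sites for a finite distance.
#' @param min_cluster_frac Clusters below this fraction of units (floor: 3
#'   units) are treated as outliers during automatic selection.
#' @return A [haplotype_defs()]; attribute `"cluster"` holds per-unit cluster
#'   labels in filtered-unit order (`"outlier"` for units set aside),
#'   `"silhouette"` the best mean silhouette per reported k.
#' @export
discover_haplotypes <- function(obs, k = NULL, completeness_min = 0.95,
                                naming_positions = NULL, min_shared = 3L,
                                min_cluster_frac = 0.01) {
  g <- if (inherits(obs, "unit_obs")) {
    keep <- obs$units$completeness >= completeness_min
    obs$genotypes[keep, , drop = FALSE]
  } else as.matrix(obs)
  if (nrow(g) < 2L)
    stop_rdnaepi("need >= 2 units at the completeness threshold",
                 "insufficient_data")
  n <- nrow(g)
  d <- genotype_dist(g, min_shared)
  sil <- NULL
  if (max(d) == 0) {                      # all vectors identical
    cl <- rep(1L, n)
  } else if (is.null(k)) {
    hc <- stats::hclust(d, method = "average")
    dm <- as.matrix(d)
    min_size <- max(3L, ceiling(min_cluster_frac * n))
    kmax <- 8L
    per_k <- stats::setNames(rep(NA_real_, kmax - 1L), 2:kmax)
    best_s <- -Inf
    best_cl <- NULL
    for (cut in 2:min(3L * kmax, n - 1L)) {
      cl_cut <- stats::cutree(hc, k = cut)
      big <- as.integer(names(which(table(cl_cut) >= min_size)))
      kbig <- length(big)
      if (kbig < 2L || kbig > kmax) next
      retained <- cl_cut %in% big
      s <- mean(cluster::silhouette(
        as.integer(factor(cl_cut[retained])),
        dmatrix = dm[retained, retained, drop = FALSE])[, "sil_width"])
      # splitting a zero-diameter cluster yields 0/0 widths; not a candidate
      if (is.na(s)) next
      kc <- as.character(kbig)
      if (is.na(per_k[[kc]]) || s > per_k[[kc]]) per_k[[kc]] <- s
      if (s > best_s) {                   # first max wins: deterministic
        best_s <- s
        best_cl <- cl_cut
      }
    }
    if (is.null(best_cl))
      stop_rdnaepi("no partition with >= 2 clusters above the size floor",
                   "insufficient_data")
    sil <- per_k[!is.na(per_k)]
    cl <- best_cl
    big <- as.integer(names(which(table(cl) >= min_size)))
    cl[!(cl %in% big)] <- 0L              # outliers
  } else if (k == 1L) {
    cl <- rep(1L, n)
  } else {
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, k = k)
  }
  # majority-allele consensus per cluster (outlier units excluded)
  ids <- setdiff(sort(unique(cl)), 0L)
  cons <- t(vapply(ids, function(ci) {
    apply(g[cl == ci, , drop = FALSE], 2, function(a) {
      a <- a[!is.na(a)]
      if (!length(a)) return(NA_character_)
      tab <- sort(table(a), decreasing = TRUE)
      names(tab)[1L]
    })
  }, character(ncol(g))))
  colnames(cons) <- colnames(g)
  # label rendering
  if (!is.null(naming_positions)) {
    key <- as.character(naming_positions)
    if (!all(key %in% colnames(cons)))
      stop_rdnaepi("naming positions absent from genotype matrix",
                   "invalid_config")
    labels <- apply(cons[, key, drop = FALSE], 1, paste, collapse = "")
    if (anyDuplicated(labels))
      labels <- make.unique(labels, sep = "_")
  } else {
    ord <- order(-as.integer(table(factor(cl, levels = ids))))
    labels <- character(length(ids))
    labels[ord] <- paste0("H", seq_along(ids))
  }
  rownames(cons) <- labels
  defs <- haplotype_defs(cons)
  unit_label <- labels[match(cl, ids)]
  unit_label[cl == 0L] <- "outlier"
  attr(defs, "cluster") <- unit_label
  attr(defs, "silhouette") <- sil
  defs
}

#' Assign a haplotype label to genotype vectors
#'
#' Picks the definition maximizing the fraction of matching non-missing
#' discriminating sites; ties or a best score below `min_score` yield
#' `"unassigned"` (never an arbitrary choice, to avoid biasing
#' co-localization diagonals).
#'
#' @param genotypes Named character vector (positions as names), or a matrix
#'   with position column names (one row per unit).
#' @param defs A [haplotype_defs()].
#' @param min_score Minimum matching fraction for an assignment.
#' @return Data frame (`label`, `score`); `score` is `NA` when no
#'   discriminating site was observed.
#' @export
assign_haplotype <- function(genotypes, defs, min_score = 0.6) {
  if (is.null(dim(genotypes)))
    genotypes <- matrix(genotypes, nrow = 1L,
                        dimnames = list(NULL, names(genotypes)))
  if (!length(defs$labels))
    stop_rdnaepi("no haplotype definitions", "invalid_defs")
  disc <- intersect(defs$discriminating, colnames(genotypes))
  n <- nrow(genotypes)
  if (!length(disc))
    return(data.frame(label = rep("unassigned", n), score = NA_real_,
                      stringsAsFactors = FALSE))
  g <- genotypes[, disc, drop = FALSE]
  cons <- defs$consensus[, disc, drop = FALSE]
  out_label <- character(n)
  out_score <- numeric(n)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    ok <- !is.na(gi)
    if (!any(ok)) {
      out_label[i] <- "unassigned"
      out_score[i] <- NA_real_
      next
    }
    frac <- vapply(defs$labels, function(lab) {
      cc <- cons[lab, ok]
      usable <- !is.na(cc)
      if (!any(usable)) return(NA_real_)
      mean(gi[ok][usable] == cc[usable])
    }, numeric(1))
    if (all(is.na(frac))) {
      out_label[i] <- "unassigned"
      out_score[i] <- NA_real_
      next
    }
    best <- max(frac, na.rm = TRUE)
    winners <- which(!is.na(frac) & frac == best)
    out_score[i] <- best
    out_label[i] <- if (length(winners) != 1L || best < min_score)
      "unassigned" else defs$labels[winners]
  }
  data.frame(label = out_label, score = out_score, stringsAsFactors = FALSE)
}

#' Assign haplotypes to all units of a `unit_obs`
#'
#' @param obs A `unit_obs`.
#' @param defs A [haplotype_defs()].
#' @param min_score See [assign_haplotype()].
#' @return The `units` data.frame with `label` and `score` columns appended.
#' @export
assign_haplotypes <- function(obs, defs, min_score = 0.6) {
  a <- assign_haplotype(obs$genotypes, defs, min_score)
  cbind(obs$units, a, stringsAsFactors = FALSE)
}

#' Haplogroup of a haplotype label
#'
#' The coarse A/C grouping given by the first letter of the label (the allele
#' at the promoter-proximal naming position).
#'
#' @param label Haplotype label(s).
#' @param groups Valid haplogroup letters.
#' @return Character vector of haplogroups.
#' @export
haplogroup <- function(label, groups = c("A", "C")) {
  first <- substr(label, 1L, 1L)
  bad <- !(first %in% groups) | nchar(label) < 2L
  if (any(bad))
    stop_rdnaepi(sprintf("no haplogroup for label(s): %s",
                         paste(unique(label[bad]), collapse = ", ")),
                 "unknown_label")
  first
}

#' Within-read haplotype co-localization matrix
#'
#' Only reads with at least two assigned units contribute. For row `h`, over
#' the reads containing at least one unit of `h`, each cell is the mean
#' per-read proportion of units assigned to the column label; all units in the
#' read are counted, focal units included, so rows sum to 1 over the columns
#' (which include `"unassigned"`).
#'
#' @param assignments Data frame with columns `read_id` and `label`
#'   (e.g. from [assign_haplotypes()]).
#' @param labels Column/row order; defaults to the sorted labels present.
#' @return List of class `coloc_matrix`: `matrix` (rows = haplotypes, columns
#'   = haplotypes + `"unassigned"`), `support` (reads per row).
#' @export
colocalization <- function(assignments, labels = NULL) {
  stopifnot(all(c("read_id", "label") %in% names(assignments)))
  if (is.null(labels))
    labels <- sort(setdiff(unique(assignments$label), "unassigned"))
  cols <- c(labels, "unassigned")
  by_read <- split(assignments$label, assignments$read_id)
  multi <- by_read[vapply(by_read, function(l)
    sum(l != "unassigned") >= 2L, logical(1))]
  mat <- matrix(NA_real_, length(labels), length(cols),
                dimnames = list(labels, cols))
  support <- stats::setNames(integer(length(labels)), labels)
  if (length(multi)) {
    props <- t(vapply(multi, function(l) {
      tab <- table(factor(l, levels = cols))
      as.numeric(tab) / length(l)
    }, numeric(length(cols))))
    colnames(props) <- cols
    for (h in labels) {
      rows <- vapply(multi, function(l) h %in% l, logical(1))
      support[h] <- sum(rows)
      if (support[h] > 0L) mat[h, ] <- colMeans(props[rows, , drop = FALSE])
    }
  }
  structure(list(matrix = mat, support = support), class = "coloc_matrix")
}

#' @export
print.coloc_matrix <- function(x, ...) {
  cat("haplotype co-localization (row: read contains >= 1 such unit)\n")
  print(round(x$matrix, 3))
  cat("support:", paste(names(x$support), x$support, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Per-haplotype CpG methylation profiles and unit bimodality
#'
#' Methylation calls are binarized at `prob_threshold`. Per haplotype and CpG,
#' the mean call; per unit, the mean over covered CpGs inside the window; the
#' bimodality fraction B is the share of units with unit mean <= 0.2 or
#' >= 0.8.
#'
#' @param obs A `unit_obs`.
#' @param assignments Output of [assign_haplotypes()] (row-aligned with
#'   `obs$units`).
#' @param reference An [rdna_reference()]; defaults to the observation's.
#' @param window TSS-relative window `c(from, to_region)` where `to_region`
#'   may be a region name whose end closes the window; default -1000 up to the
#'   end of the 3'ETS.
#' @param prob_threshold Binarization threshold for probability calls.
#' @return List: `profile` (data.frame haplotype, pos, mean_meth, n),
#'   `unit_means` (data.frame label, unit_mean, n_cpgs), `bimodality`
#'   (overall B), `bimodality_by_haplotype`.
#' @export
methylation_profile <- function(obs, assignments, reference = obs$reference,
                                window = list(-1000, "3'ETS"),
                                prob_threshold = 0.5) {
  lo <- tss_to_ref(window[[1L]], reference$tss)
  hi <- if (is.character(window[[2L]]))
    region_interval(reference, window[[2L]])[["end"]]
  else tss_to_ref(window[[2L]], reference$tss)
  cpg <- as.integer(colnames(obs$meth))
  in_win <- cpg >= lo & cpg < hi
  m <- obs$meth[, in_win, drop = FALSE]
  storage.mode(m) <- "double"
  m[!is.na(m)] <- as.numeric(m[!is.na(m)] >= prob_threshold)
  lab <- assignments$label
  labs <- setdiff(sort(unique(lab)), "unassigned")
  profile <- do.call(rbind, lapply(labs, function(h) {
    rows <- lab == h
    if (!any(rows)) return(NULL)
    sub <- m[rows, , drop = FALSE]
    data.frame(haplotype = h, pos = cpg[in_win],
               mean_meth = colMeans(sub, na.rm = TRUE),
               n = as.integer(colSums(!is.na(sub))), stringsAsFactors = FALSE)
  }))
  rownames(profile) <- NULL
  covered <- as.integer(rowSums(!is.na(m)))
  unit_mean <- rowMeans(m, na.rm = TRUE)
  keep <- covered > 0L
  if (!all(labs %in% lab[keep]))
    warning("haplotype(s) without covered units omitted from unit means: ",
            paste(setdiff(labs, lab[keep]), collapse = ", "))
  unit_means <- data.frame(label = lab[keep], unit_mean = unit_mean[keep],
                           n_cpgs = covered[keep], stringsAsFactors = FALSE)
  bim <- function(x) if (!length(x)) NA_real_ else
    mean(x <= 0.2 | x >= 0.8)
  assigned <- unit_means$label != "unassigned"
  list(profile = profile,
       unit_means = unit_means,
       bimodality = bim(unit_means$unit_mean[assigned]),
       bimodality_by_haplotype = vapply(
         labs, function(h) bim(unit_means$unit_mean[unit_means$label == h]),
         numeric(1)))
}

#' Aggregate A-haplogroup frequency and methylation prediction
#'
#' Combines the ATA and ATG strata into the "A" haplogroup: the aggregate
#' frequency is the sum, the aggregate methylation the frequency-weighted
#' mean.
#'
#' @param f_ata,m_ata Frequency and methylation of the ATA stratum.
#' @param f_atg,m_atg Frequency and methylation of the ATG stratum.
#' @return List (`f_a`, `m_a`).
#' @export
predict_haplogroup_aggregate <- function(f_ata, m_ata, f_atg, m_atg) {
  if (any(c(f_ata, f_atg) < 0))
    stop_rdnaepi("frequencies must be non-negative", "invalid_input")
  tot <- f_ata + f_atg
  if (any(tot == 0))
    stop_rdnaepi("aggregate undefined: f_ata + f_atg = 0",
                 "undefined_aggregate")
  list(f_a = tot, m_a = (f_ata * m_ata + f_atg * m_atg) / tot)
}

#' Fold concatenated-reference alignment segments into unit observations
#'
#' Alignments against a reference of back-to-back rDNA units are folded modulo
#' the unit length: one observation per distinct unit copy touched, ordered by
#' read position, with completeness computed over the coding-unit span. Split
#' alignments with gaps leave the skipped unit copies absent. Overlapping
#' (contradictory) segments for one unit copy cause that unit to be dropped
#' with a warning.
#'
#' @param segments Data frame (`read_id`, `start`, `end`): half-open 1-based
#'   intervals on the concatenated reference.
#' @param reference An [rdna_reference()].
#' @return Data frame (`read_id`, `unit_copy`, `ordinal`, `cov_start`,
#'   `cov_end`, `completeness`) with unit-local half-open coverage.
#' @export
segment_units <- function(segments, reference) {
  stopifnot(all(c("read_id", "start", "end") %in% names(segments)))
  L <- reference$unit_length
  span <- coding_span(reference)
  span_len <- span[2L] - span[1L]
  out <- lapply(split(segments, segments$read_id), function(sg) {
    pieces <- do.call(rbind, lapply(seq_len(nrow(sg)), function(i) {
      s <- sg$start[i]; e <- sg$end[i]
      stopifnot(s >= 1, e > s)
      first <- (s - 1L) %/% L
      last <- (e - 2L) %/% L
      do.call(rbind, lapply(first:last, function(u) {
        cs <- max(s, u * L + 1L) - u * L
        ce <- min(e, (u + 1L) * L + 1L) - u * L
        data.frame(read_id = sg$read_id[1L], unit_copy = u + 1L,
                   cov_start = cs, cov_end = ce, seg = i,
                   stringsAsFactors = FALSE)
      }))
    }))
    keep <- lapply(split(pieces, pieces$unit_copy), function(p) {
      if (nrow(p) > 1L) {
        o <- order(p$cov_start)
        p <- p[o, , drop = FALSE]
        if (any(p$cov_start[-1L] < p$cov_end[-nrow(p)])) {
          warning(sprintf("read %s: contradictory segments for unit copy %d; dropped",
                          p$read_id[1L], p$unit_copy[1L]))
          return(NULL)
        }
        # non-overlapping sub-segments of one unit: take the covering hull
        p <- data.frame(read_id = p$read_id[1L], unit_copy = p$unit_copy[1L],
                        cov_start = min(p$cov_start), cov_end = max(p$cov_end),
                        seg = p$seg[1L], stringsAsFactors = FALSE)
      }
      p
    })
    do.call(rbind, keep)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(read_id = character(0), unit_copy = integer(0),
                      ordinal = integer(0), cov_start = integer(0),
                      cov_end = integer(0), completeness = numeric(0)))
  res <- res[order(res$read_id, res$unit_copy), , drop = FALSE]
  res$ordinal <- stats::ave(res$unit_copy, res$read_id,
                            FUN = seq_along)
  ov <- pmax(0L, pmin(res$cov_end, span[2L]) - pmax(res$cov_start, span[1L]))
  res$completeness <- ov / span_len
  res$seg <- NULL
  rownames(res) <- NULL
  res[, c("read_id", "unit_copy", "ordinal", "cov_start", "cov_end",
          "completeness")]
}
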