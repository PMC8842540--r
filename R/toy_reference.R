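# Bundled synthetic ("toy") rDNA unit reference and SNV panel.
#
# A deterministic ~15-kb unit with plausible region boundaries and a 10-SNV
# panel defining four haplotypes named, by the alleles at TSS-relative
# positions -104 / 8063 / 12736, "ATA", "ATG", "CCA" and "CTA". Real
# references (e.g. the public mouse or human rDNA sequences) are
# user-supplied via read_rdna_reference(); everything here is synthetic and
# exists so that all analyses and tests run without downloads.

TOY_SEED <- 104729L
TOY_UNIT_LENGTH <- 15000L
TOY_TSS <- 1001L

# TSS-relative half-open region intervals of the toy unit (chosen so that the
# canonical panel positions fall in the fields where such variants are
# described: 6007/6832 in ITS2, 8063/9005/12376/12736 in 28S).
toy_regions_tss <- function() {
  data.frame(
    name  = c("promoter", "5'ETS", "18S", "ITS1", "5.8S", "ITS2", "28S",
              "3'ETS", "IGS"),
    start = c(-1000L, 1L, 4008L, 5878L, 5920L, 5990L, 6935L, 12800L, 13400L),
    end   = c(0L, 4008L, 5878L, 5920L, 5990L, 6935L, 12800L, 13400L, 14001L),
    strand = "+",
    stringsAsFactors = FALSE)
}

# Haplotype consensus alleles at the toy panel positions (TSS-relative keys).
# Every pair of haplotypes differs at >= 5 of the 12 positions, keeping the
# between-haplotype genotype distance (>= 5/12) well above the expected
# within-haplotype distance under per-site genotyping error, so clustering
# and multi-site assignment remain identifiable.
toy_consensus_tss <- function() {
  pos <- c(-104L, 2500L, 3300L, 3800L, 6007L, 6832L, 8063L, 9005L, 10500L,
           11000L, 12376L, 12736L)
  m <- rbind(
    ATA = c("A", "T", "G", "G", "A", "A", "T", "C", "A", "C", "G", "A"),
    ATG = c("A", "T", "G", "G", "G", "G", "T", "C", "G", "C", "T", "G"),
    CCA = c("C", "G", "A", "G", "G", "G", "C", "T", "A", "C", "G", "A"),
    CTA = c("C", "G", "A", "C", "G", "G", "T", "T", "G", "A", "T", "A"))
  colnames(m) <- as.character(pos)
  m
}

#' Bundled toy rDNA unit reference
#'
#' A deterministic synthetic ~15-kb unit (fixed internal seed) with a 1-kb
#' upstream flank (TSS at 1001), annotated regions, and reference alleles
#' equal to the ATA haplotype at the toy panel positions. Panel positions are
#' flanked by T on both sides so that no CpG overlaps an SNV under any allele.
#'
#' @return An [rdna_reference()].
#' @export
toy_rdna_reference <- function() {
  cons <- toy_consensus_tss()
  pos_ref <- tss_to_ref(as.integer(colnames(cons)), TOY_TSS)
  bases <- with_seed(TOY_SEED, sample(c("A", "C", "G", "T"), TOY_UNIT_LENGTH,
                                      replace = TRUE,
                                      prob = c(.28, .22, .22, .28)))
  # plant reference (ATA) alleles with T flanks: "TxT" can never create a CpG
  # whichever allele x takes
  bases[pos_ref] <- cons["ATA", ]
  bases[pos_ref - 1L] <- "T"
  bases[pos_ref + 1L] <- "T"
  regions <- toy_regions_tss()
  regions$start <- tss_to_ref(regions$start, TOY_TSS)
  # half-open ends: a TSS-relative end label k means "up to but excluding k";
  # the promoter row ends at the TSS itself
  at_tss <- regions$end == 0L
  regions$end[!at_tss] <- tss_to_ref(regions$end[!at_tss], TOY_TSS)
  regions$end[at_tss] <- TOY_TSS
  rdna_reference(paste(bases, collapse = ""), TOY_TSS, regions)
}

#' Toy SNV panel matching [toy_rdna_reference()]
#'
#' @param reference Optionally a prebuilt [toy_rdna_reference()] (saves
#'   recomputation).
#' @return An [snv_panel()] of 12 biallelic entries, all flagged
#'   discriminating.
#' @export
toy_snv_panel <- function(reference = toy_rdna_reference()) {
  cons <- toy_consensus_tss()
  pos_ref <- tss_to_ref(as.integer(colnames(cons)), TOY_TSS)
  ref <- cons["ATA", ]
  alt <- apply(cons, 2, function(a) {
    others <- setdiff(unique(a), a[["ATA"]])
    paste(others, collapse = ",")
  })
  snv_panel(pos_ref, ref, alt, reference, discriminating = TRUE)
}

#' Toy haplotype definitions
#'
#' Consensus alleles of the four toy haplotypes at the toy panel positions,
#' keyed by reference coordinate.
#'
#' @return A [haplotype_defs()] object with labels ATA, ATG, CCA, CTA.
#' @export
toy_haplotype_definitions <- function() {
  cons <- toy_consensus_tss()
  colnames(cons) <- as.character(tss_to_ref(as.integer(colnames(cons)),
                                            TOY_TSS))
  haplotype_defs(cons)
}

#' Reference coordinates of the toy haplotype naming positions
#'
#' The three positions whose alleles spell the haplotype label
#' (TSS-relative -104, 8063 and 12736).
#'
#' @return Integer vector of length 3 (reference coordinates).
#' @export
toy_naming_positions <- function() {
  tss_to_ref(c(-104L, 8063L, 12736L), TOY_TSS)
}
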