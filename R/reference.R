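# Reference model of a single 45S rDNA coding unit: sequence, coordinate
# conventions, region annotations, CpG indexing and SNV panel i/o.
#
# Conventions: internal coordinates are 1-based on the unit reference; region
# intervals are half-open [start, end). TSS-relative labels (e.g. -104) are
# used only at i/o boundaries; they have no zero, so +1 is the first
# transcribed base and -1 the base immediately upstream.

#' Construct an rDNA unit reference
#'
#' @param sequence Single nucleotide string over \{A,C,G,T,N\}.
#' @param tss_position 1-based reference coordinate of the first transcribed
#'   base (+1 in TSS-relative labels). The transcription start offset of public
#'   rDNA references is assembly-specific and must be supplied.
#' @param regions Data frame with columns `name`, `start`, `end` (half-open,
#'   1-based) and optionally `strand`. Typical names: promoter, 5'ETS, 18S,
#'   ITS1, 5.8S, ITS2, 28S, 3'ETS, IGS.
#' @return An object of class `rdna_reference` with fields `sequence`,
#'   `unit_length`, `tss`, `regions` and `cpg_index` (sorted 1-based positions
#'   of the C of each CpG dinucleotide).
#' @export
rdna_reference <- function(sequence, tss_position, regions) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop_rdnaepi("sequence contains characters outside {A,C,G,T,N}",
                 "invalid_sequence")
  n <- nchar(sequence)
  stopifnot(is.numeric(tss_position), tss_position >= 1, tss_position <= n)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (any(regions$start < 1 | regions$end > n + 1 | regions$start >= regions$end))
    stop_rdnaepi("region intervals must be half-open within [1, unit_length]",
                 "invalid_region")
  structure(list(sequence = sequence,
                 unit_length = n,
                 tss = as.integer(tss_position),
                 regions = regions,
                 cpg_index = find_cpgs(sequence)),
            class = "rdna_reference")
}

#' @export
print.rdna_reference <- function(x, ...) {
  cat(sprintf("rDNA unit reference: %d bp, TSS at %d, %d CpGs, %d regions\n",
              x$unit_length, x$tss, length(x$cpg_index), nrow(x$regions)))
  invisible(x)
}

#' Locate CpG dinucleotides
#'
#' Returns the 1-based positions p with `sequence[p..p+1] == "CG"`. N bases
#' never form CpGs.
#'
#' @param sequence Nucleotide string.
#' @return Sorted integer vector (possibly empty).
#' @export
find_cpgs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 2L) return(integer(0))
  b <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  which(b[-length(b)] == "C" & b[-1L] == "G")
}

#' Convert TSS-relative labels to reference coordinates (and back)
#'
#' TSS-relative labels skip zero: `+1` is the TSS base itself, `-1` the base
#' immediately upstream. `k >= +1` maps to `tss + k - 1`; `k <= -1` maps to
#' `tss + k`.
#'
#' @param k Signed TSS-relative position(s); never 0.
#' @param tss 1-based reference coordinate of the TSS.
#' @return 1-based reference coordinate(s).
#' @export
tss_to_ref <- function(k, tss) {
  if (any(k == 0)) stop_rdnaepi("TSS-relative coordinates have no zero",
                                "invalid_coordinate")
  as.integer(ifelse(k >= 1, tss + k - 1, tss + k))
}

#' @rdname tss_to_ref
#' @param pos 1-based reference coordinate(s).
#' @export
ref_to_tss <- function(pos, tss) {
  as.integer(ifelse(pos >= tss, pos - tss + 1, pos - tss))
}

#' Look up the annotated region containing a position
#'
#' @param reference An [rdna_reference()].
#' @param pos Reference coordinate(s).
#' @return Character vector of region names (`NA` where unannotated).
#' @export
region_of <- function(reference, pos) {
  r <- reference$regions
  vapply(pos, function(p) {
    hit <- which(r$start <= p & p < r$end)
    if (length(hit)) r$name[hit[1L]] else NA_character_
  }, character(1))
}

#' Interval of a named region
#'
#' @param reference An [rdna_reference()].
#' @param name Region name.
#' @return `c(start, end)` half-open.
#' @export
region_interval <- function(reference, name) {
  r <- reference$regions
  i <- match(name, r$name)
  if (is.na(i)) stop_rdnaepi(sprintf("unknown region '%s'", name),
                             "unknown_region")
  c(start = r$start[i], end = r$end[i])
}

# SNV panel -------------------------------------------------------------------

#' Construct an SNV panel
#'
#' @param position 1-based reference coordinates (unique, within the unit).
#' @param ref Reference alleles (must match the reference sequence).
#' @param alt List (or comma-separated strings) of alternative alleles.
#' @param reference An [rdna_reference()] for validation and TSS labels.
#' @param discriminating Logical flag per entry marking haplotype-defining
#'   positions (default `FALSE`; haplotype discovery can override).
#' @return Object of class `snv_panel`: a data.frame with columns `position`,
#'   `tss_label`, `ref`, `alt` (comma-separated) and `discriminating`.
#' @export
snv_panel <- function(position, ref, alt, reference,
                      discriminating = FALSE) {
  position <- as.integer(position)
  if (anyDuplicated(position))
    stop_rdnaepi("panel positions must be unique", "invalid_panel")
  if (any(position < 1 | position > reference$unit_length))
    stop_rdnaepi("panel positions outside the unit", "invalid_panel")
  if (is.list(alt)) alt <- vapply(alt, paste, character(1), collapse = ",")
  seq_base <- if (length(position))
    substring(reference$sequence, position, position) else character(0)
  bad <- which(seq_base != toupper(ref))
  if (length(bad))
    stop_rdnaepi(sprintf(
      "ref allele mismatch at position %s (panel %s, reference %s)",
      paste(position[bad], collapse = ","),
      paste(ref[bad], collapse = ","),
      paste(seq_base[bad], collapse = ",")), "ref_mismatch")
  out <- data.frame(position = position,
                    tss_label = ref_to_tss(position, reference$tss),
                    ref = toupper(ref),
                    alt = toupper(alt),
                    discriminating = rep_len(discriminating, length(position)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snv_panel", "data.frame")
  out
}

#' Alleles observed at a panel position
#'
#' @param panel An [snv_panel()].
#' @param position Reference coordinate present in the panel.
#' @return Character vector `c(ref, alt...)`.
#' @export
panel_alleles <- function(panel, position) {
  i <- match(position, panel$position)
  if (is.na(i)) stop_rdnaepi(sprintf("position %d not in panel", position),
                             "unknown_position")
  c(panel$ref[i], strsplit(panel$alt[i], ",", fixed = TRUE)[[1]])
}

#' Read an SNV panel from VCF
#'
#' One panel entry per VCF record on the unit contig; multi-allelic ALTs are
#' preserved. REF alleles are checked against the reference sequence.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param reference An [rdna_reference()].
#' @return An [snv_panel()].
#' @export
read_snv_panel <- function(path, reference) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_rdnaepi(
                  sprintf("failed to parse VCF '%s': %s", path,
                          conditionMessage(e)), "vcf_parse_error"))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single record: the fixed fields drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(snv_panel(integer(0), character(0), character(0), reference))
  snv_panel(position = as.integer(fix$POS),
            ref = fix$REF, alt = fix$ALT,
            reference = reference)
}

#' Read a unit reference from FASTA
#'
#' @param fasta Path to a single-record FASTA file.
#' @param tss_position See [rdna_reference()].
#' @param regions Region data.frame, or a path to a 4-column TSV
#'   (name, start, end, strand).
#' @return An [rdna_reference()].
#' @export
read_rdna_reference <- function(fasta, tss_position, regions) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L)
    stop_rdnaepi("expected a single-record FASTA unit reference",
                 "invalid_fasta")
  if (is.character(regions) && length(regions) == 1L)
    regions <- utils::read.table(regions, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  rdna_reference(as.character(seqs[[1L]]), tss_position, regions)
}
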