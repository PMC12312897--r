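#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   DNAString reverseComplement pairwiseAlignment IUPAC_CODE_MAP
#'   alignedPattern alignedSubject
#' @importFrom S4Vectors DataFrame
NULL

#' MarkerBundle: packaged reference frames, sites, haplotype definitions,
#' allele catalog and primers
#'
#' Central reference container consumed by every typing stage. Holds the COI
#' and Tpi reference coordinate frames, the diagnostic site table
#' (mCOI1164D/mCOI1287R and the eight gTpi sites), the COIB and TpiE4
#' haplotype definitions, the TpiI4a200 allele catalog, primer metadata and
#' the intron/catalog window coordinates. Constructed by [loadBundle()] or
#' [defaultBundle()]; validity checking enumerates every violation rather
#' than stopping at the first.
#'
#' @slot frames [Biostrings::DNAStringSet] of unambiguous reference frames
#'   (\code{COI}, \code{TpiGenomic}).
#' @slot frameInfo data.frame with \code{frame_id}, \code{gene_offset},
#'   \code{origin_note}.
#' @slot sites data.frame of diagnostic sites: \code{site_id},
#'   \code{frame_id}, \code{position} (1-based in frame), \code{allowed}
#'   (string of allowed bases), \code{role}.
#' @slot haplotypes long-format data.frame of haplotype definitions:
#'   \code{label}, \code{marker}, \code{strain}, \code{site_id}, \code{base}.
#' @slot catalog [Biostrings::DNAStringSet] of full TpiI4a200 alleles
#'   (catalog window of the Tpi frame).
#' @slot catalogInfo data.frame with \code{label} and \code{provenance}.
#' @slot extrapolated [Biostrings::DNAStringSet] of sequences known only
#'   from heterozygote superpositions (AfrRa3), kept outside the
#'   deconvolution catalog.
#' @slot primers data.frame: \code{name}, \code{seq}, \code{frame_id},
#'   \code{direction}, \code{name_position}.
#' @slot windows named integer vector of window coordinates
#'   (\code{tpi_intron_window_start/end}, \code{tpi_catalog_window_start/end}).
#' @export
setClass("MarkerBundle", representation(
  frames = "DNAStringSet",
  frameInfo = "data.frame",
  sites = "data.frame",
  haplotypes = "data.frame",
  catalog = "DNAStringSet",
  catalogInfo = "data.frame",
  extrapolated = "DNAStringSet",
  primers = "data.frame",
  windows = "integer"))

#' AnchoredSequence: an amplicon mapped onto its reference frame
#'
#' Result of [anchorSequence()]. Bases are the (uppercased, possibly
#' IUPAC-ambiguous) query bases in frame orientation; \code{refPos} gives the
#' 1-based reference position of each base, with \code{NA} marking insertions
#' relative to the frame (recorded but never position-numbered).
#'
#' @slot frameId character frame identifier.
#' @slot bases character vector of single-letter base calls.
#' @slot refPos integer vector parallel to \code{bases}; strictly increasing
#'   over its non-NA entries.
#' @slot orientation \code{"forward"} or \code{"reverse_complemented"}.
#' @slot anchorMethod \code{"primer"} or \code{"alignment"}.
#' @slot flags character vector of quality flags.
#' @export
setClass("AnchoredSequence", representation(
  frameId = "character",
  bases = "character",
  refPos = "integer",
  orientation = "character",
  anchorMethod = "character",
  flags = "character"))

#' SpecimenSet: specimen metadata joined to marker sequences
#'
#' @slot metadata data.frame with one row per specimen (specimen_id, country,
#'   site, year, month, host_plant, host_class, sex, method, join flags).
#' @slot sequences named list of [Biostrings::DNAStringSet], one element per
#'   marker (\code{COIB}, \code{Tpi}), names within each set are specimen ids.
#' @export
setClass("SpecimenSet", representation(
  metadata = "data.frame",
  sequences = "list"))

#' SyntheticCohort: a generated cohort with its ground-truth ledger
#'
#' @slot specimens [SpecimenSet] of emitted sequences and metadata.
#' @slot ledger data.frame of per-specimen ground truth (sex, Z alleles,
#'   strain genotype, mito haplotype, injected-novel flag, diagnostic-site
#'   error count).
#' @slot config the [scenarioConfig()] list the cohort was generated from.
#' @export
setClass("SyntheticCohort", representation(
  specimens = "SpecimenSet",
  ledger = "data.frame",
  config = "list"))

#' CollectionProfile: haplotype/strain frequency vectors for one collection
#'
#' @slot key named character vector identifying the collection
#'   (e.g. country, year).
#' @slot nSpecimens integer number of specimens in the group.
#' @slot coibCounts named integer counts over COIB labels.
#' @slot tpiStrainCounts named integer counts over C/R/H/unresolved.
#' @slot intronCounts named integer counts over intron haplotype labels.
#' @export
setClass("CollectionProfile", representation(
  key = "character",
  nSpecimens = "integer",
  coibCounts = "integer",
  tpiStrainCounts = "integer",
  intronCounts = "integer"))

setMethod("show", "MarkerBundle", function(object) {
  cat("MarkerBundle\n")
  cat("  frames:   ", paste(names(object@frames), collapse = ", "), "\n")
  cat("  sites:    ", nrow(object@sites), "diagnostic sites\n")
  cat("  haplotype definitions:",
      length(unique(object@haplotypes$label)), "labels\n")
  cat("  catalog:  ", length(object@catalog), "TpiI4a200 alleles\n")
  cat("  primers:  ", paste(object@primers$name, collapse = ", "), "\n")
})

setMethod("show", "AnchoredSequence", function(object) {
  covered <- range(object@refPos, na.rm = TRUE)
  cat("AnchoredSequence on", object@frameId,
      sprintf("[%d..%d]", covered[1], covered[2]),
      "| orientation:", object@orientation,
      "| method:", object@anchorMethod, "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "SpecimenSet", function(object) {
  cat("SpecimenSet:", nrow(object@metadata), "specimens;",
      "markers:", paste(names(object@sequences), collapse = ", "), "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@ledger), "specimens,",
      length(unique(object@ledger$collection)), "collections\n")
})

setMethod("show", "CollectionProfile", function(object) {
  cat("CollectionProfile",
      paste(names(object@key), object@key, sep = "=", collapse = " "),
      sprintf("(n=%d)\n", object@nSpecimens))
})
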