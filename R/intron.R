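## intron_catalog: extract the TpiI4a200 haplotype string, match against the
## catalog, and register novel variants under a singleton re-verification
## policy (a variant seen once stays provisional until a second observation
## or an explicit confirmation, mirroring repeat PCR + re-sequencing).

#' Extract the TpiI4a200 intron segment from an anchored Tpi sequence
#'
#' Returns the ungapped query subsequence aligned to the packaged intron
#' window (the first ~60\% of intron 4, reference coordinates from
#' [intronWindow()]); indels relative to the reference are preserved as
#' sequence-length differences.
#'
#' @param anchored an [AnchoredSequence] on the Tpi frame.
#' @param bundle a [MarkerBundle].
#' @return character DNA string.
#' @export
extractIntronSegment <- function(anchored, bundle) {
  win <- intronWindow(bundle)
  seg <- .window_sequence(anchored, win)
  if (is.null(seg))
    stop("intron_uncovered: anchored sequence does not span the intron window [",
         win[1], ", ", win[2], "]", call. = FALSE)
  seg
}

# intron part of a catalog-window sequence (no anchoring needed: catalog
# entries are laid out on the catalog window)
.intron_from_window_seq <- function(seq, bundle) {
  cw <- catalogWindow(bundle)
  iw <- intronWindow(bundle)
  substring(seq, iw[1] - cw[1] + 1L, iw[2] - cw[1] + 1L)
}

# deterministic identifier for a novel haplotype string: 24-bit polynomial
# rolling hash (exact in double arithmetic), rendered as 6 hex digits
.novel_id <- function(seq) {
  h <- 0
  for (b in utf8ToInt(toupper(seq))) h <- (h * 131 + b) %% 16777216
  sprintf("NOVEL-%06X", h)
}

#' Create an empty intron run tally
#'
#' The tally accumulates support counts for catalog and novel haplotypes
#' over one analysis run.
#'
#' @return an environment holding counts and novel sequences.
#' @export
newRunTally <- function() {
  e <- new.env(parent = emptyenv())
  e$counts <- integer(0)
  e$novel_seqs <- character(0)
  e
}

#' Match an intron segment against the catalog or register it as novel
#'
#' Matching is exact string equality after uppercasing: the study treats any
#' repeat-confirmed variation as a distinct haplotype, so no mismatch
#' tolerance is applied. Novel labels are deterministic functions of the
#' sequence. A novel haplotype is \code{provisional} until its support count
#' reaches \code{minSupport} (default 2, the in-silico analog of repeat PCR
#' amplification) or \code{confirmed = TRUE} is supplied.
#'
#' @param segment intron DNA string (unambiguous; ambiguous input is
#'   deferred with a flag).
#' @param catalog named character vector or DNAStringSet of catalog intron
#'   strings.
#' @param runTally environment from [newRunTally()]; updated in place.
#' @param minSupport confirmations required for a novel haplotype.
#' @param confirmed external confirmation (models re-sequencing).
#' @param specimen_id id carried through.
#' @return data.frame row: specimen_id, intron_label, matched
#'   (exact/novel/deferred), support_count, status.
#' @export
matchOrRegister <- function(segment, catalog, runTally,
                            minSupport = 2L, confirmed = FALSE,
                            specimen_id = NA_character_) {
  segment <- toupper(segment)
  if (nchar(segment) == 0) stop("empty intron segment", call. = FALSE)
  if (grepl("[^ACGT]", segment))
    return(data.frame(specimen_id = specimen_id, intron_label = NA_character_,
                      matched = "deferred", support_count = 0L,
                      status = "ambiguous_deferred", stringsAsFactors = FALSE))
  cat_chr <- toupper(as.character(catalog))
  hit <- match(segment, cat_chr)
  if (!is.na(hit)) {
    lab <- names(catalog)[hit]
    runTally$counts[lab] <- sum(runTally$counts[lab], 1L, na.rm = TRUE)
    return(data.frame(specimen_id = specimen_id, intron_label = lab,
                      matched = "exact",
                      support_count = unname(runTally$counts[lab]),
                      status = "confirmed", stringsAsFactors = FALSE))
  }
  lab <- .novel_id(segment)
  runTally$counts[lab] <- sum(runTally$counts[lab], 1L, na.rm = TRUE)
  runTally$novel_seqs[lab] <- segment
  n <- unname(runTally$counts[lab])
  status <- if (confirmed || n >= minSupport) "confirmed" else "provisional"
  data.frame(specimen_id = specimen_id, intron_label = lab, matched = "novel",
             support_count = n, status = status, stringsAsFactors = FALSE)
}

#' Census a set of intron segments against a catalog
#'
#' Runs [matchOrRegister()] over all segments with one shared tally, then
#' revisits novel calls so that every observation of a haplotype whose final
#' support reached \code{minSupport} is reported confirmed.
#'
#' @param segments named character vector of intron strings (names are
#'   specimen/allele ids).
#' @param catalog catalog intron strings.
#' @param minSupport see [matchOrRegister()].
#' @return list: \code{calls} data.frame, \code{tally} (final counts),
#'   \code{novel} named character vector of novel sequences.
#' @export
intronCensus <- function(segments, catalog, minSupport = 2L) {
  tally <- newRunTally()
  if (length(segments) == 0)
    return(list(calls = data.frame(specimen_id = character(0),
                                   intron_label = character(0),
                                   matched = character(0),
                                   support_count = integer(0),
                                   status = character(0)),
                tally = tally$counts, novel = tally$novel_seqs))
  calls <- do.call(rbind, Map(function(s, id)
    matchOrRegister(s, catalog, tally, minSupport = minSupport,
                    specimen_id = id),
    segments, names(segments)))
  rownames(calls) <- NULL
  novel <- calls$matched == "novel"
  final_n <- tally$counts[calls$intron_label[novel]]
  calls$support_count[novel] <- unname(final_n)
  calls$status[novel] <- ifelse(final_n >= minSupport, "confirmed",
                                "provisional")
  list(calls = calls, tally = tally$counts, novel = tally$novel_seqs)
}

#' Novel-haplotype registry as appendable FASTA text
#'
#' @param census result of [intronCensus()].
#' @return character vector of FASTA lines (empty when no novels).
#' @export
novelRegistryFasta <- function(census) {
  if (length(census$novel) == 0) return(character(0))
  as.vector(rbind(paste0(">", names(census$novel)), unname(census$novel)))
}
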