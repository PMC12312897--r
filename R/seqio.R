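## seqio_anchor: read specimen sequences + metadata, orient and anchor each
## amplicon onto its reference frame, extract per-site base calls.

.meta_required <- c("specimen_id", "country", "site", "year")
.meta_optional <- c("month", "host_plant", "host_class", "sex", "method")

#' Construct a SpecimenSet from in-memory parts
#'
#' @param metadata data.frame with at least specimen_id, country, site, year.
#' @param sequences named list of named character vectors or DNAStringSets,
#'   one element per marker (\code{COIB}, \code{Tpi}).
#' @return a [SpecimenSet].
#' @export
SpecimenSet <- function(metadata, sequences = list()) {
  sequences <- lapply(sequences, function(s) {
    s <- if (is(s, "DNAStringSet")) s else DNAStringSet(toupper(s))
    s
  })
  new("SpecimenSet", metadata = as.data.frame(metadata), sequences = sequences)
}

#' @rdname SpecimenSet
#' @param x a SpecimenSet.
#' @export
specimenMeta <- function(x) x@metadata

#' @rdname SpecimenSet
#' @param marker marker name.
#' @export
specimenSeqs <- function(x, marker) x@sequences[[marker]]

.validate_metadata <- function(meta, yearRange) {
  errs <- character(0)
  miss <- setdiff(.meta_required, names(meta))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in .meta_optional) if (!col %in% names(meta)) meta[[col]] <- NA
  if (anyDuplicated(meta$specimen_id))
    errs <- c(errs, paste("duplicate specimen_id:",
                          paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
                                collapse = ", ")))
  meta$sex <- ifelse(is.na(meta$sex) | meta$sex == "", "unknown", meta$sex)
  meta$method <- ifelse(is.na(meta$method) | meta$method == "", "unknown",
                        meta$method)
  meta$host_class <- ifelse(is.na(meta$host_class) | meta$host_class == "",
                            "unknown", meta$host_class)
  # pheromone traps use female sex attractant: catches are males
  trap <- meta$method == "pheromone_trap"
  bad_trap <- trap & meta$sex == "female"
  if (any(bad_trap))
    errs <- c(errs, paste("pheromone_trap specimens recorded as female:",
                          paste(meta$specimen_id[bad_trap], collapse = ", ")))
  meta$sex[trap & meta$sex == "unknown"] <- "male"
  yr <- suppressWarnings(as.integer(meta$year))
  bad_year <- is.na(yr) | yr < yearRange[1] | yr > yearRange[2]
  if (any(bad_year))
    errs <- c(errs, paste("collection year outside plausible range:",
                          paste(meta$specimen_id[bad_year], collapse = ", ")))
  if (length(errs))
    stop("metadata validation failed:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  meta
}

#' Read specimen sequences and metadata
#'
#' FASTA headers follow the convention \code{>SPECIMEN|MARKER} with marker
#' one of \code{COIB}, \code{Tpi}. Lowercase bases are accepted and
#' uppercased. Specimens present in only one of the two inputs are retained
#' and flagged (\code{no_metadata} / \code{no_sequence}) with a warning.
#'
#' @param fastaPaths character vector of FASTA files.
#' @param metadataPath TSV with columns specimen_id, country, site, year and
#'   optionally month, host_plant, host_class, sex, method.
#' @param yearRange plausible collection-year range.
#' @return a [SpecimenSet]; metadata gains a \code{join_flag} column.
#' @export
readSpecimens <- function(fastaPaths, metadataPath,
                          yearRange = c(1990L, 2035L)) {
  seqs <- list()
  for (f in fastaPaths) {
    xs <- tryCatch(readDNAStringSet(f),
                   error = function(e) stop("unparseable FASTA ", f, ": ",
                                            conditionMessage(e), call. = FALSE))
    hdr <- strsplit(names(xs), "|", fixed = TRUE)
    bad <- which(lengths(hdr) < 2)
    if (length(bad))
      stop("FASTA record ", bad[1], " in ", f,
           " lacks the SPECIMEN|MARKER header convention", call. = FALSE)
    for (i in seq_along(xs)) {
      sp <- hdr[[i]][1]; mk <- hdr[[i]][2]
      if (!is.null(seqs[[mk]]) && sp %in% names(seqs[[mk]]))
        stop("duplicate record for specimen ", sp, " marker ", mk, call. = FALSE)
      seqs[[mk]] <- c(seqs[[mk]],
                      stats::setNames(toupper(as.character(xs[[i]])), sp))
    }
  }
  meta <- .read_tsv(metadataPath)
  meta <- .validate_metadata(meta, yearRange)
  seq_ids <- unique(unlist(lapply(seqs, names), use.names = FALSE))
  only_seq <- setdiff(seq_ids, meta$specimen_id)
  only_meta <- setdiff(meta$specimen_id, seq_ids)
  meta$join_flag <- ""
  if (length(only_meta)) {
    warning("specimens with metadata but no sequence: ",
            paste(only_meta, collapse = ", "))
    meta$join_flag[meta$specimen_id %in% only_meta] <- "no_sequence"
  }
  if (length(only_seq)) {
    warning("specimens with sequence but no metadata: ",
            paste(only_seq, collapse = ", "))
    add <- meta[rep(NA_integer_, length(only_seq)), , drop = FALSE]
    add$specimen_id <- only_seq
    add$join_flag <- "no_metadata"
    add$sex <- "unknown"; add$method <- "unknown"; add$host_class <- "unknown"
    rownames(add) <- NULL
    meta <- rbind(meta, add)
  }
  SpecimenSet(meta, lapply(seqs, DNAStringSet))
}

## ---- anchoring -------------------------------------------------------------

# mismatch count of `pat` against `s` at offset `at` (1-based); subject
# ambiguity codes count as matches when the primer base is in the expansion
.primer_mismatches <- function(pat, s, at) {
  n <- nchar(pat)
  if (at < 1 || at + n - 1 > nchar(s)) return(Inf)
  p <- strsplit(pat, "")[[1]]
  q <- strsplit(substring(s, at, at + n - 1), "")[[1]]
  ok <- q %in% rownames(.iupac_tabs$compat) & p %in% c("A", "C", "G", "T")
  m <- logical(n)
  m[ok] <- .iupac_tabs$compat[cbind(q[ok], p[ok])]
  sum(!m)
}

.find_primer <- function(pat, s, maxMismatch) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                   Biostrings::DNAString(s),
                                   max.mismatch = maxMismatch, fixed = FALSE)
  if (length(hits) == 0) return(NULL)
  starts <- Biostrings::start(hits)
  mm <- vapply(starts, function(a) .primer_mismatches(pat, s, a), numeric(1))
  best <- which.min(mm)
  list(start = starts[best], mismatches = mm[best])
}

# identity of query vs frame under an ungapped mapping starting at ref
# position `anchor` for query position 1
.ungapped_identity <- function(q, frame_chars, anchor) {
  n <- nchar(q)
  qc <- strsplit(q, "")[[1]]
  refpos <- anchor + seq_len(n) - 1L
  keep <- refpos >= 1L & refpos <= length(frame_chars)
  if (!any(keep)) return(0)
  qk <- qc[keep]; rk <- frame_chars[refpos[keep]]
  ok <- qk %in% rownames(.iupac_tabs$compat)
  m <- logical(length(qk))
  m[ok] <- .iupac_tabs$compat[cbind(qk[ok], rk[ok])]
  mean(m)
}

#' Orient and anchor an amplicon onto its reference frame
#'
#' Orientation is chosen by the best primer match (at most \code{maxMismatch}
#' mismatches) on either strand; primer-anchored reads are mapped without
#' gaps when that mapping reaches \code{identityThreshold}, otherwise (and
#' when no primer is found) a global-in-query alignment against the frame's
#' amplicon region is used. Reference positions are 1-based; insertions
#' relative to the frame are retained with \code{NA} positions. Primer-covered
#' positions are trimmed from the anchored region by default.
#'
#' @param seq DNA string (IUPAC ambiguity codes permitted).
#' @param marker \code{"COIB"} or \code{"Tpi"}.
#' @param bundle a [MarkerBundle].
#' @param maxMismatch primer mismatch tolerance (default 2).
#' @param minLength minimum usable sequence length (default 150).
#' @param identityThreshold identity below which anchoring fails (default 0.8).
#' @param trimPrimers drop primer-covered positions from the anchoring
#'   (default TRUE).
#' @return an [AnchoredSequence].
#' @export
anchorSequence <- function(seq, marker, bundle, maxMismatch = 2L,
                           minLength = 150L, identityThreshold = 0.8,
                           trimPrimers = TRUE) {
  seq <- toupper(gsub("[^A-Za-z]", "", seq))
  if (nchar(seq) < minLength)
    stop("sequence shorter than minimum length ", minLength, call. = FALSE)
  frame_id <- markerFrame(marker)
  frame <- as.character(bundle@frames[[frame_id]])
  frame_chars <- strsplit(frame, "")[[1]]
  region <- ampliconRegion(bundle, frame_id)
  pr <- bundle@primers[bundle@primers$frame_id == frame_id, ]
  off <- bundle@frameInfo$gene_offset[match(frame_id, bundle@frameInfo$frame_id)]
  fwd <- pr[pr$direction == "forward", ][1, ]
  rev_ <- pr[pr$direction == "reverse", ][1, ]
  fwd_anchor <- fwd$name_position - off          # 5' end of forward primer
  rev_end <- rev_$name_position - off            # 3' end of reverse primer site
  rc <- revComp(seq)

  # primer search: forward primer on both strands, then reverse primer
  cand <- list(
    list(s = seq, orient = "forward",
         hit = .find_primer(fwd$seq, seq, maxMismatch), anchor = fwd_anchor),
    list(s = rc, orient = "reverse_complemented",
         hit = .find_primer(fwd$seq, rc, maxMismatch), anchor = fwd_anchor),
    list(s = seq, orient = "forward",
         hit = .find_primer(revComp(rev_$seq), seq, maxMismatch),
         anchor = rev_end - nchar(rev_$seq) + 1L),
    list(s = rc, orient = "reverse_complemented",
         hit = .find_primer(revComp(rev_$seq), rc, maxMismatch),
         anchor = rev_end - nchar(rev_$seq) + 1L))
  found <- Filter(function(x) !is.null(x$hit), cand)
  flags <- character(0)

  oriented <- NULL; method <- NULL; map <- NULL
  if (length(found)) {
    mm <- vapply(found, function(x) x$hit$mismatches, numeric(1))
    best <- found[[which.min(mm)]]
    start_ref <- best$anchor - (best$hit$start - 1L)
    ident <- .ungapped_identity(best$s, frame_chars, start_ref)
    if (ident >= identityThreshold) {
      n <- nchar(best$s)
      refpos <- start_ref + seq_len(n) - 1L
      keep <- refpos >= 1L & refpos <= length(frame_chars)
      if (!all(keep)) flags <- c(flags, "overhangs_frame")
      map <- list(bases = strsplit(best$s, "")[[1]][keep],
                  refPos = refpos[keep])
      oriented <- best$orient
      method <- "primer"
    } else {
      oriented <- best$orient
    }
  }

  if (is.null(map)) {
    # fall back to global-in-query alignment against the amplicon region
    ref_amp <- substring(frame, region["start"], region["end"])
    align_one <- function(s) {
      Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(s),
        subject = Biostrings::DNAString(ref_amp),
        type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 2, gapExtension = 2)
    }
    als <- if (is.null(oriented)) list(forward = align_one(seq),
                                       reverse_complemented = align_one(rc))
           else stats::setNames(list(align_one(
             if (oriented == "forward") seq else rc)), oriented)
    scores <- vapply(als, Biostrings::score, numeric(1))
    oriented <- names(als)[which.min(-scores)]
    al <- als[[oriented]]
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ref_at <- region["start"] + Biostrings::start(Biostrings::subject(al)) - 2L
    bases <- character(0); refPos <- integer(0)
    for (k in seq_along(pat)) {
      if (sub[k] != "-") ref_at <- ref_at + 1L
      if (pat[k] == "-") next
      bases <- c(bases, pat[k])
      refPos <- c(refPos, if (sub[k] == "-") NA_integer_ else ref_at)
    }
    aligned <- !is.na(refPos) & bases %in% rownames(.iupac_tabs$compat)
    matches <- sum(.iupac_tabs$compat[cbind(bases[aligned],
                                            frame_chars[refPos[aligned]])])
    ident <- matches / length(bases)
    if (ident < identityThreshold)
      stop(sprintf(
        "unanchorable sequence for marker %s: best identity %.3f below threshold %.2f",
        marker, ident, identityThreshold), call. = FALSE)
    map <- list(bases = bases, refPos = refPos)
    method <- "alignment"
    flags <- c(flags, "anchored_by_alignment")
  }

  if (trimPrimers) {
    fwd_rng <- fwd_anchor:(fwd_anchor + nchar(fwd$seq) - 1L)
    rev_rng <- (rev_end - nchar(rev_$seq) + 1L):rev_end
    drop <- !is.na(map$refPos) & (map$refPos %in% c(fwd_rng, rev_rng))
    # keep insertions adjacent to retained positions only
    map$bases <- map$bases[!drop]
    map$refPos <- map$refPos[!drop]
  }
  new("AnchoredSequence", frameId = frame_id, bases = map$bases,
      refPos = map$refPos, orientation = oriented, anchorMethod = method,
      flags = flags)
}

#' Extract per-site IUPAC calls from an anchored sequence
#'
#' Uncovered sites are reported as \code{NA} ("missing"); calls whose
#' expansion falls outside the site's allowed bases are retained but listed
#' in the \code{unexpected_base} attribute.
#'
#' @param anchored an [AnchoredSequence].
#' @param bundle a [MarkerBundle].
#' @return named character vector (site_id -> IUPAC code or NA) with
#'   attribute \code{unexpected_base}.
#' @export
extractSiteCalls <- function(anchored, bundle) {
  st <- siteTable(bundle, frame = anchored@frameId)
  if (nrow(st) == 0) stop("no sites defined for frame ", anchored@frameId)
  calls <- stats::setNames(rep(NA_character_, nrow(st)), st$site_id)
  unexpected <- character(0)
  for (i in seq_len(nrow(st))) {
    j <- match(st$position[i], anchored@refPos)
    if (is.na(j)) next
    code <- anchored@bases[j]
    calls[st$site_id[i]] <- code
    allowed <- strsplit(st$allowed[i], "")[[1]]
    exp_ <- tryCatch(iupacExpand(code), error = function(e) character(0))
    if (length(exp_) == 0 || !all(exp_ %in% allowed))
      unexpected <- c(unexpected, st$site_id[i])
  }
  attr(calls, "unexpected_base") <- unexpected
  calls
}

#' Anchor and extract site calls in one step
#'
#' @inheritParams anchorSequence
#' @param ... passed to [anchorSequence()].
#' @return see [extractSiteCalls()].
#' @export
siteCallsFromSequence <- function(seq, marker, bundle, ...) {
  extractSiteCalls(anchorSequence(seq, marker, bundle, ...), bundle)
}
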