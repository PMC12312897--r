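## tpi_typing: Z-linkage-aware TpiE4 strain genotype (C/R/H), TpiE4
## haplotype group assignment, and catalog-constrained deconvolution of
## heterozygous males (the mechanism by which AfrRa3 was inferred).

.tpi_site_ids <- function(bundle) siteTable(bundle, "TpiGenomic")$site_id

#' Call the TpiE4 strain genotype with Z-linkage awareness
#'
#' The R strain is defined by T at gTpi183Y, the C strain by C. A C/T double
#' peak (IUPAC Y) marks an interstrain hybrid male (H): females carry a
#' single Z chromosome and can never be heterozygous, so Y in a known female
#' is flagged \code{impossible_female_het} and left unresolved. Specimens of
#' unknown sex (larval collections) showing heterozygosity are treated as
#' males and flagged \code{sex_assumed_male_for_het}. Ambiguity restricted
#' to non-diagnostic positions (intrastrain heterozygotes) leaves the strain
#' call intact; strain-associated sites conflicting with gTpi183Y are
#' flagged \code{discordant_sites} but never override it.
#'
#' @param calls Tpi site-call vector from [extractSiteCalls()].
#' @param sex \code{"male"}, \code{"female"} or \code{"unknown"}.
#' @param bundle a [MarkerBundle].
#' @param anySeqAmbiguity optional logical: whether the full anchored Tpi
#'   sequence contains any ambiguity code (detects intron-only
#'   heterozygotes); defaults to ambiguity among the site calls.
#' @param specimen_id optional id carried through.
#' @return data.frame row: specimen_id, tpi_strain (C/R/H/unresolved),
#'   zygosity, tpi_flags.
#' @export
callTpiStrain <- function(calls, sex = "unknown", bundle,
                          anySeqAmbiguity = NULL,
                          specimen_id = NA_character_) {
  res <- function(strain, zygosity, flags = character(0))
    data.frame(specimen_id = specimen_id, tpi_strain = strain,
               zygosity = zygosity, tpi_flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  g183 <- calls[["gTpi183Y"]]
  site_amb <- isAmbiguousCode(calls[!is.na(calls)])
  het_signal <- isTRUE(any(site_amb)) || isTRUE(anySeqAmbiguity)
  if (is.na(g183)) return(res("unresolved", "unknown", "missing_site"))
  flags <- character(0)
  # strain-associated exon sites disagreeing with gTpi183Y
  if (!isAmbiguousCode(g183)) {
    conc <- c(gTpi165Y = if (g183 == "T") "T" else "C",
              gTpi168Y = if (g183 == "T") "T" else "C")
    # AfrRa1 legitimately carries C at gTpi165Y, so only flag, never override
    for (sid in names(conc)) {
      v <- calls[[sid]]
      if (!is.na(v) && !isAmbiguousCode(v) && v != conc[[sid]] &&
          sid == "gTpi168Y")
        flags <- c(flags, "discordant_sites")
    }
  }
  if (g183 %in% c("C", "T")) {
    strain <- if (g183 == "T") "R" else "C"
    if (sex == "female") {
      if (het_signal) flags <- c(flags, "impossible_female_het")
      return(res(strain, "hemizygous_female", flags))
    }
    if (het_signal) {
      # intrastrain heterozygote (C/C or R/R with differing alleles)
      if (sex == "unknown") flags <- c(flags, "sex_assumed_male_for_het")
      return(res(strain, "heterozygous", flags))
    }
    zyg <- if (sex == "male") "homozygous" else "unknown"
    return(res(strain, zyg, flags))
  }
  if (g183 == "Y") {
    if (sex == "female")
      return(res("unresolved", "unknown", c(flags, "impossible_female_het")))
    if (sex == "unknown") flags <- c(flags, "sex_assumed_male_for_het")
    return(res("H", "heterozygous", flags))
  }
  res("unresolved", "unknown", c(flags, "unexpected_base"))
}

#' Assign the TpiE4 haplotype group
#'
#' Matches unambiguous site calls (hemizygous/homozygous specimens, or one
#' deconvolved allele) against the TpiE4 haplotype definitions by exact
#' agreement on every site a definition specifies. When several definitions
#' match, the most specific (most defined sites) wins; full-profile
#' definitions (AfrCa1, AfrCa2, AfrRa1-3) therefore take precedence over the
#' three-site WH consensus definitions, which catch WH-like profiles with no
#' African extras. No exact match returns \code{"novel"} with the
#' mismatching sites listed in the \code{mismatches} attribute.
#'
#' @param calls unambiguous Tpi site-call vector.
#' @param bundle a [MarkerBundle].
#' @return character group label (attribute \code{mismatches} when novel).
#' @export
assignE4Group <- function(calls, bundle) {
  defs <- haplotypeDefs(bundle, marker = "TpiE4")
  per <- split(defs, defs$label)
  hits <- character(0); sizes <- integer(0)
  best_miss <- NULL; best_n <- -1L
  for (lab in names(per)) {
    h <- per[[lab]]
    obs <- calls[h$site_id]
    cmp <- !is.na(obs) & obs == h$base
    if (all(cmp)) {
      hits <- c(hits, lab); sizes <- c(sizes, nrow(h))
    } else if (sum(cmp) > best_n) {
      best_n <- sum(cmp)
      best_miss <- h$site_id[!cmp]
    }
  }
  if (length(hits) == 0) {
    out <- "novel"
    attr(out, "mismatches") <- best_miss
    return(out)
  }
  win <- hits[which.max(sizes)]
  if (win %in% c("WH_C_consensus", "WH_R_consensus")) win <- "WH-like"
  win
}

#' Deconvolve a heterozygous male against the allele catalog
#'
#' Phase 1 enumerates all unordered catalog pairs and keeps those whose
#' site-wise IUPAC superposition equals the observed sequence (exact
#' candidates). If none exist, Phase 2 takes each catalog allele in turn and
#' infers the partner site-wise: at each position the partner base set is
#' \{p : union(allele, p) = observed\}; an allele is viable only if every
#' position yields a non-empty set. Positions observed as N/missing leave
#' the partner base unconstrained; each consistent completion yields one
#' candidate, capped at \code{completionCap} with flag
#' \code{completion_cap_truncated}. Exact candidates precede requires_novel
#' candidates in the result.
#'
#' @param observed observed sequence over the catalog window (IUPAC codes).
#' @param catalog [Biostrings::DNAStringSet] of catalog alleles (equal
#'   length, same window).
#' @param completionCap maximum candidates from unconstrained completions
#'   (default 8).
#' @return list with elements \code{candidates} (list of lists: labelA,
#'   labelB, sequenceB, consistency) and \code{flags}. Errors with
#'   "unexplained_heterozygote" naming the conflicting sites when neither
#'   phase yields a candidate.
#' @export
deconvolveHeterozygote <- function(observed, catalog, completionCap = 8L) {
  observed <- toupper(observed)
  seqs <- toupper(as.character(catalog))
  labs <- names(catalog)
  len_ok <- nchar(seqs) == nchar(observed)
  obs_chars <- strsplit(observed, "")[[1]]
  flags <- character(0)
  if (!all(len_ok)) flags <- c(flags, "length_mismatch_alleles_skipped")

  candidates <- list()
  usable <- which(len_ok)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  # Phase 1: exact catalog pairs (unordered, self-pairs included)
  for (i in usable) for (j in usable[usable >= i]) {
    u <- .iupac_tabs$union[cbind(chars[[i]], chars[[j]])]
    if (all(u == obs_chars))
      candidates[[length(candidates) + 1L]] <-
        list(labelA = labs[i], labelB = labs[j], sequenceB = unname(seqs[j]),
             consistency = "exact")
  }
  if (length(candidates))
    return(list(candidates = candidates, flags = flags))

  # Phase 2: infer a novel partner for each catalog allele
  for (i in usable) {
    a <- chars[[i]]
    pstr <- .iupac_tabs$partner[cbind(obs_chars, a)]
    pstr[obs_chars == "N"] <- "ACGT"
    if (any(nchar(pstr) == 0)) next
    sets <- strsplit(pstr, "")
    n_comp <- prod(lengths(sets))
    if (n_comp > completionCap) {
      flags <- c(flags, "completion_cap_truncated")
      n_comp <- completionCap
    }
    free <- which(lengths(sets) > 1L)
    base_seq <- vapply(sets, `[[`, "", 1L)
    combos <- if (length(free) == 0) list(integer(0)) else {
      grid <- do.call(expand.grid, lapply(sets[free], seq_along))
      lapply(seq_len(min(nrow(grid), n_comp)), function(r) unlist(grid[r, ]))
    }
    for (cb in combos[seq_len(min(length(combos), max(1L, n_comp)))]) {
      s <- base_seq
      if (length(free)) s[free] <- mapply(function(k, ix) sets[[k]][ix], free, cb)
      candidates[[length(candidates) + 1L]] <-
        list(labelA = labs[i], labelB = "novel",
             sequenceB = paste(s, collapse = ""), consistency = "requires_novel")
    }
  }
  if (length(candidates) == 0) {
    conflict <- which(vapply(seq_along(obs_chars), function(k) {
      all(vapply(usable, function(i)
        length(iupacPartner(obs_chars[k], substring(seqs[i], k, k))) == 0,
        logical(1)))
    }, logical(1)))
    stop("unexplained_heterozygote: no catalog-consistent allele pair; ",
         "conflicting positions: ", paste(conflict, collapse = ", "),
         call. = FALSE)
  }
  list(candidates = candidates, flags = unique(flags))
}

#' Full TpiE4/TpiI4a200 typing for one specimen
#'
#' Combines [callTpiStrain()], deconvolution and group assignment. Resolved
#' alleles (hemizygous/homozygous specimens, or heterozygotes with a unique
#' exact deconvolution) carry catalog labels; inferred novel alleles carry
#' \code{novel}. Group calls come from each resolved allele's exon states.
#'
#' @param anchored [AnchoredSequence] for the Tpi marker.
#' @param sex specimen sex.
#' @param bundle a [MarkerBundle].
#' @param catalog catalog to deconvolve against (default the bundle's).
#' @param specimen_id id carried through.
#' @return one-row data.frame: specimen_id, tpi_strain, zygosity, e4_groups
#'   (comma-joined), allele_a, allele_b, allele_seqs (list-column),
#'   tpi_flags.
#' @export
typeTpi <- function(anchored, sex, bundle, catalog = alleleCatalog(bundle),
                    specimen_id = NA_character_) {
  win <- catalogWindow(bundle)
  obs <- .window_sequence(anchored, win)
  calls <- extractSiteCalls(anchored, bundle)
  het <- !is.null(obs) && grepl("[^ACGTN]", obs)
  strain_row <- callTpiStrain(calls, sex, bundle, anySeqAmbiguity = het,
                              specimen_id = specimen_id)
  flags <- strsplit(strain_row$tpi_flags, ";")[[1]]
  allele_a <- allele_b <- NA_character_
  allele_seqs <- list()
  groups <- character(0)

  resolved_single <- !het && !is.null(obs) && !grepl("[^ACGT]", obs)
  if (resolved_single) {
    hit <- match(obs, as.character(catalog))
    allele_a <- if (!is.na(hit)) names(catalog)[hit] else "novel"
    if (strain_row$zygosity == "homozygous") allele_b <- allele_a
    allele_seqs <- list(obs)
    groups <- assignE4Group(calls, bundle)
  } else if (het && strain_row$zygosity == "heterozygous" && !is.null(obs)) {
    dec <- tryCatch(deconvolveHeterozygote(obs, catalog),
                    error = function(e) NULL)
    if (is.null(dec)) {
      flags <- c(flags, "unexplained_heterozygote")
    } else {
      exact <- Filter(function(x) x$consistency == "exact", dec$candidates)
      if (length(exact) == 1L) {
        allele_a <- exact[[1]]$labelA
        allele_b <- exact[[1]]$labelB
        seqA <- as.character(catalog[[allele_a]])
        allele_seqs <- list(seqA, exact[[1]]$sequenceB)
        groups <- unique(c(
          assignE4Group(.calls_from_window_seq(seqA, bundle), bundle),
          assignE4Group(.calls_from_window_seq(exact[[1]]$sequenceB, bundle),
                        bundle)))
      } else if (length(exact) > 1L) {
        flags <- c(flags, "ambiguous_deconvolution")
      } else {
        flags <- c(flags, "requires_novel_allele")
        first <- dec$candidates[[1]]
        allele_a <- first$labelA
        allele_b <- "novel"
        seqA <- as.character(catalog[[allele_a]])
        allele_seqs <- list(seqA, first$sequenceB)
        groups <- unique(c(
          assignE4Group(.calls_from_window_seq(seqA, bundle), bundle),
          assignE4Group(.calls_from_window_seq(first$sequenceB, bundle),
                        bundle)))
      }
    }
  }
  out <- strain_row
  out$e4_groups <- paste(groups, collapse = ",")
  out$allele_a <- allele_a
  out$allele_b <- allele_b
  out$allele_seqs <- I(list(allele_seqs))
  out$tpi_flags <- paste(unique(flags), collapse = ";")
  out
}

# query subsequence spanning a reference window; NULL when uncovered
.window_sequence <- function(anchored, win) {
  pos <- anchored@refPos
  inside <- !is.na(pos) & pos >= win[1] & pos <= win[2]
  if (!any(inside)) return(NULL)
  covered <- pos[inside]
  if (min(covered) > win[1] || max(covered) < win[2]) return(NULL)
  idx <- range(which(inside))
  paste(anchored@bases[idx[1]:idx[2]], collapse = "")
}

# site calls from a catalog-window sequence (positions relative to window)
.calls_from_window_seq <- function(seq, bundle) {
  win <- catalogWindow(bundle)
  st <- siteTable(bundle, "TpiGenomic")
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- st$position - win[1] + 1L
  ok <- idx >= 1L & idx <= length(chars)
  out <- stats::setNames(rep(NA_character_, nrow(st)), st$site_id)
  out[ok] <- chars[idx[ok]]
  out
}
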