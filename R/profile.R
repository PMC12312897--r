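## pop_profile: collection-level aggregation and the population analyses --
## CSh profile typing (FL vs TX), Pearson profile comparison, Fisher-exact
## introduction-signal flagging, R-chromosome carrier statistics.

#' Round half-up to integer percent
#'
#' Reported percentages follow half-up rounding (17.5 -> 18); raw fractions
#' are emitted alongside so rounding never compounds.
#'
#' @param x numeric.
#' @return numeric of same length.
#' @export
roundHalfUp <- function(x) floor(x + 0.5)

#' Aggregate calls into collection-level profiles
#'
#' One [CollectionProfile] per group; unclassified COIB calls, unresolved
#' Tpi calls and (by default) provisional novel intron haplotypes are
#' excluded from frequency denominators. Empty groups are dropped with a
#' warning.
#'
#' @param calls data.frame of per-specimen calls (columns among coib_label,
#'   tpi_strain, intron_label, intron_status).
#' @param metadata specimen metadata (must contain specimen_id and the
#'   grouping columns).
#' @param grouping character vector of metadata column names.
#' @param includeProvisional include provisional novel intron haplotypes in
#'   profiles (default FALSE).
#' @return named list of [CollectionProfile].
#' @export
buildProfiles <- function(calls, metadata, grouping = c("country", "year"),
                          includeProvisional = FALSE) {
  miss <- setdiff(grouping, names(metadata))
  if (length(miss))
    stop("grouping key(s) absent from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- merge(calls, metadata, by = "specimen_id", all.x = TRUE)
  keyvals <- do.call(paste, c(df[grouping], sep = "|"))
  out <- list()
  for (k in unique(keyvals)) {
    g <- df[keyvals == k, , drop = FALSE]
    if (nrow(g) == 0) { warning("empty group ", k, " dropped"); next }
    coib <- if ("coib_label" %in% names(g)) {
      keep <- !is.na(g$coib_label) & g$coib_label != "unclassified"
      table(g$coib_label[keep])
    } else table(character(0))
    tpi <- if ("tpi_strain" %in% names(g)) {
      keep <- !is.na(g$tpi_strain)
      t0 <- table(factor(g$tpi_strain[keep],
                         levels = c("C", "R", "H", "unresolved")))
      t0
    } else table(character(0))
    intr <- if ("intron_label" %in% names(g)) {
      keep <- !is.na(g$intron_label)
      if (!includeProvisional && "intron_status" %in% names(g))
        keep <- keep & g$intron_status != "provisional"
      table(g$intron_label[keep])
    } else table(character(0))
    key <- stats::setNames(as.character(g[1, grouping]), grouping)
    out[[k]] <- new("CollectionProfile", key = key,
                    nSpecimens = nrow(g),
                    coibCounts = stats::setNames(as.integer(coib), names(coib)),
                    tpiStrainCounts = stats::setNames(as.integer(tpi), names(tpi)),
                    intronCounts = stats::setNames(as.integer(intr), names(intr)))
  }
  out
}

#' Frequency vector of a profile
#'
#' @param profile a [CollectionProfile].
#' @param marker \code{"coib"}, \code{"tpi"} or \code{"intron"}.
#' @param categories optional category ordering/universe; counts missing
#'   from the profile are 0.
#' @return named numeric vector summing to 1 over classified categories
#'   (all-zero when nothing is classified).
#' @export
profileFrequencies <- function(profile, marker = c("coib", "tpi", "intron"),
                               categories = NULL) {
  marker <- match.arg(marker)
  counts <- switch(marker, coib = profile@coibCounts,
                   tpi = profile@tpiStrainCounts,
                   intron = profile@intronCounts)
  if (!is.null(categories)) {
    full <- stats::setNames(rep(0L, length(categories)), categories)
    full[intersect(names(counts), categories)] <-
      counts[intersect(names(counts), categories)]
    counts <- full
  }
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(rep(0, length(counts)), names(counts)))
  counts / tot
}

#' R-chromosome carrier statistics
#'
#' Specimen-level: a carrier holds at least one R_TpiE4 Z chromosome (strain
#' R of any zygosity, or hybrid H). Chromosome-level: a homozygote
#' contributes 2 R chromosomes, a heterozygote 1, a hemizygous female 1;
#' unknown-zygosity R specimens (unambiguous calls from unsexed larvae)
#' contribute 1 and are flagged. Percentages are reported half-up rounded
#' with raw fractions alongside.
#'
#' @param tpiCalls data.frame with columns tpi_strain and zygosity.
#' @return list of tallies, fractions and rounded percentages.
#' @export
carrierStats <- function(tpiCalls) {
  s <- tpiCalls$tpi_strain
  z <- tpiCalls$zygosity
  n_total <- nrow(tpiCalls)
  is_R <- !is.na(s) & s == "R"
  is_H <- !is.na(s) & s == "H"
  n_homo_hemi_R <- sum(is_R)
  n_het <- sum(is_H)
  n_carriers <- n_homo_hemi_R + n_het
  chrom_homo_hemi <- sum(ifelse(is_R & z == "homozygous", 2L,
                         ifelse(is_R, 1L, 0L)))
  chrom_het <- sum(is_H)
  chrom_total <- chrom_homo_hemi + chrom_het
  flags <- if (any(is_R & z == "unknown")) "unknown_zygosity_counted_once"
           else character(0)
  list(
    n_total = n_total,
    n_carriers = n_carriers,
    n_homo_hemi_R = n_homo_hemi_R,
    n_het = n_het,
    r_chromosomes = c(homo_hemi = chrom_homo_hemi, het = chrom_het,
                      total = chrom_total),
    frac_carriers = if (n_total > 0) n_carriers / n_total else NA_real_,
    frac_homo_hemi_chrom = if (chrom_total > 0)
      chrom_homo_hemi / chrom_total else NA_real_,
    pct_carriers = if (n_total > 0)
      roundHalfUp(100 * n_carriers / n_total) else NA_real_,
    pct_homo_hemi_chrom = if (chrom_total > 0)
      roundHalfUp(100 * chrom_homo_hemi / chrom_total) else NA_real_,
    flags = flags)
}

#' Pearson similarity of two frequency profiles
#'
#' @param pA,pB named frequency vectors over identical ordered categories
#'   (>= 3 categories, nonzero variance in each).
#' @return Pearson correlation coefficient.
#' @export
pearsonProfileSimilarity <- function(pA, pB) {
  if (is.null(names(pA)) || is.null(names(pB)) ||
      !identical(names(pA), names(pB)))
    stop("profiles must share an identical ordered category set", call. = FALSE)
  if (length(pA) < 3)
    stop("need at least 3 categories", call. = FALSE)
  if (stats::sd(pA) == 0 || stats::sd(pB) == 0)
    stop("zero-variance profile; Pearson undefined", call. = FALSE)
  stats::cor(pA, pB)
}

#' Classify a CSh profile as FL-type or TX-type
#'
#' Nearest reference CSh frequency vector by total-variation distance; a
#' winning margin below \code{marginThreshold} is indeterminate. The
#' packaged references encode the regional profile contrast: FL-type
#' (Florida/Caribbean) is CSh4-dominated with scarce CSh2, TX-type
#' (Texas/Mexico/South America) carries a large CSh2 component.
#'
#' @param profile a [CollectionProfile] with COIB counts.
#' @param referenceProfiles named list of reference frequency vectors over
#'   CSh1..CSh4 (default the packaged FL/TX references).
#' @param marginThreshold minimum distance margin (default 0.05).
#' @return list: type (\code{FL-type}/\code{TX-type}/\code{indeterminate}),
#'   distances.
#' @export
classifyProfileType <- function(profile,
                                referenceProfiles = referenceCshProfiles(),
                                marginThreshold = 0.05) {
  categories <- c("CSh1", "CSh2", "CSh3", "CSh4")
  if (sum(profile@coibCounts[intersect(names(profile@coibCounts),
                                       categories)]) == 0)
    stop("profile lacks classified C_COIB counts", call. = FALSE)
  p <- profileFrequencies(profile, "coib", categories = categories)
  tv <- vapply(referenceProfiles,
               function(q) 0.5 * sum(abs(p - q[categories])), numeric(1))
  ord <- order(tv)
  margin <- if (length(tv) > 1) tv[ord[2]] - tv[ord[1]] else Inf
  type <- if (margin < marginThreshold) "indeterminate" else names(tv)[ord[1]]
  list(type = type, distances = tv)
}

#' Packaged FL-type / TX-type reference CSh profiles
#'
#' Synthetic transcription of the regional profile contrast: both regions
#' share minority CSh1 (3-18\%) and rare CSh3 (1-3\%), and differ in the
#' CSh2/CSh4 balance.
#'
#' @return named list of frequency vectors.
#' @export
referenceCshProfiles <- function() {
  list(
    `FL-type` = c(CSh1 = 0.10, CSh2 = 0.04, CSh3 = 0.02, CSh4 = 0.84),
    `TX-type` = c(CSh1 = 0.15, CSh2 = 0.45, CSh3 = 0.02, CSh4 = 0.38))
}

#' Flag an introduction signal against a baseline
#'
#' Formalizes the transient-rare-haplotype-influx argument as a two-sided
#' Fisher exact test: haplotypes rarer than \code{rareThreshold} in the
#' baseline define the "rare" class, and the focal collection's rare/other
#' split is tested against the baseline's. This test is an artifact of the
#' pipeline (the original argument is qualitative) and the output labels it
#' as such.
#'
#' @param profile focal [CollectionProfile].
#' @param baselineProfile baseline [CollectionProfile].
#' @param marker which counts to compare (default \code{"coib"}).
#' @param rareThreshold baseline frequency below which a haplotype counts as
#'   rare (default 0.02).
#' @param alpha significance level (default 0.05).
#' @return list: flagged, p_value, odds_ratio, rare_labels, table, note.
#' @export
detectIntroductionSignal <- function(profile, baselineProfile,
                                     marker = "coib", rareThreshold = 0.02,
                                     alpha = 0.05) {
  get_counts <- function(pr) switch(marker, coib = pr@coibCounts,
                                    tpi = pr@tpiStrainCounts,
                                    intron = pr@intronCounts)
  base <- get_counts(baselineProfile)
  if (sum(base) == 0) stop("baseline has no classified counts", call. = FALSE)
  foc <- get_counts(profile)
  labels <- union(names(base), names(foc))
  basev <- stats::setNames(rep(0L, length(labels)), labels)
  basev[names(base)] <- base
  focv <- stats::setNames(rep(0L, length(labels)), labels)
  focv[names(foc)] <- foc
  rare <- labels[basev / sum(basev) < rareThreshold]
  tab <- matrix(c(sum(focv[rare]), sum(focv) - sum(focv[rare]),
                  sum(basev[rare]), sum(basev) - sum(basev[rare])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("focal", "baseline"), c("rare", "other")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(flagged = ft$p.value < alpha,
       p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       rare_labels = rare,
       table = tab,
       note = "Fisher-exact formalization added by this pipeline")
}

#' Cross-tabulate strain calls against host-plant class
#'
#' Summarizes marker/host concordance, e.g. the share of R-strain specimens
#' collected from C-strain-associated host plants.
#'
#' @param strain character vector of strain calls (C/R/H).
#' @param hostClass character vector (C_host/R_host/unknown).
#' @return list with the contingency table and, per strain, the fraction and
#'   half-up-rounded percentage found on C-strain hosts.
#' @export
strainHostSummary <- function(strain, hostClass) {
  keep <- !is.na(strain) & hostClass %in% c("C_host", "R_host")
  tab <- table(strain = strain[keep], host = hostClass[keep])
  per_strain <- lapply(rownames(tab), function(s) {
    n <- sum(tab[s, ])
    on_c <- if ("C_host" %in% colnames(tab)) tab[s, "C_host"] else 0L
    list(n = n, on_c_host = as.integer(on_c),
         frac_on_c_host = if (n > 0) on_c / n else NA_real_,
         pct_on_c_host = if (n > 0) roundHalfUp(100 * on_c / n) else NA_real_)
  })
  names(per_strain) <- rownames(tab)
  list(table = tab, per_strain = per_strain)
}
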