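## cli_report: end-to-end orchestration (anchor -> type -> census ->
## profile) with a machine-readable summary. The package functions are the
## primary interface; inst/cli/straintype.R wraps the same entry points for
## shell use.

#' Type every specimen of a SpecimenSet
#'
#' Anchors each marker sequence, extracts site calls, classifies COIB, types
#' Tpi (with heterozygote deconvolution) and assembles per-specimen and
#' per-chromosome call tables.
#'
#' @param specimens a [SpecimenSet].
#' @param bundle a [MarkerBundle].
#' @param catalog deconvolution/census catalog (default the bundle's; pass a
#'   subset to emulate an earlier catalog state).
#' @param minSupport singleton-verification threshold for novel intron
#'   haplotypes.
#' @return list: \code{calls} (per specimen), \code{intronCalls} (per
#'   resolved chromosome), \code{census} (see [intronCensus()]).
#' @export
typeCohort <- function(specimens, bundle, catalog = alleleCatalog(bundle),
                       minSupport = 2L) {
  meta <- specimenMeta(specimens)
  if (nrow(meta) == 0) stop("no specimens", call. = FALSE)
  coib_seqs <- specimenSeqs(specimens, "COIB")
  tpi_seqs <- specimenSeqs(specimens, "Tpi")
  rows <- list()
  chrom <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$specimen_id[i]
    sex <- if (is.na(meta$sex[i])) "unknown" else meta$sex[i]
    coib_row <- if (!is.null(coib_seqs) && id %in% names(coib_seqs)) {
      anc <- anchorSequence(as.character(coib_seqs[[id]]), "COIB", bundle)
      classifyCoib(extractSiteCalls(anc, bundle), bundle, specimen_id = id)
    } else data.frame(specimen_id = id, coib_label = "unclassified",
                      coib_strain = NA_character_, coib_flags = "no_sequence")
    tpi_row <- if (!is.null(tpi_seqs) && id %in% names(tpi_seqs)) {
      anc <- anchorSequence(as.character(tpi_seqs[[id]]), "Tpi", bundle)
      typeTpi(anc, sex, bundle, catalog = catalog, specimen_id = id)
    } else data.frame(specimen_id = id, tpi_strain = "unresolved",
                      zygosity = "unknown", tpi_flags = "no_sequence",
                      e4_groups = "", allele_a = NA_character_,
                      allele_b = NA_character_,
                      allele_seqs = I(list(list())))
    seqs <- tpi_row$allele_seqs[[1]]
    labs <- c(tpi_row$allele_a,
              if (!is.na(tpi_row$allele_b)) tpi_row$allele_b)
    if (length(seqs) == 1L && !is.na(tpi_row$allele_b))
      seqs <- c(seqs, seqs)  # homozygote: both chromosomes carry the allele
    for (k in seq_along(seqs))
      chrom[[length(chrom) + 1L]] <- data.frame(
        specimen_id = id, chromosome = k,
        allele_label = if (k <= length(labs)) labs[k] else NA_character_,
        window_seq = seqs[[k]], stringsAsFactors = FALSE)
    row <- cbind(coib_row,
                 tpi_row[, c("tpi_strain", "zygosity", "e4_groups",
                             "allele_a", "allele_b", "tpi_flags")])
    rows[[i]] <- row
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  chromdf <- if (length(chrom)) do.call(rbind, chrom) else
    data.frame(specimen_id = character(0), chromosome = integer(0),
               allele_label = character(0), window_seq = character(0))
  cat_introns <- stats::setNames(
    vapply(as.character(catalog), function(s)
      .intron_from_window_seq(s, bundle), ""),
    names(catalog))
  segs <- stats::setNames(
    vapply(chromdf$window_seq, function(s)
      .intron_from_window_seq(s, bundle), ""),
    paste(chromdf$specimen_id, chromdf$chromosome, sep = "/"))
  census <- intronCensus(segs, cat_introns, minSupport = minSupport)
  intron_calls <- cbind(chromdf[, c("specimen_id", "chromosome",
                                    "allele_label")],
                        census$calls[, c("intron_label", "matched",
                                         "support_count", "status")])
  list(calls = calls, intronCalls = intron_calls, census = census)
}

#' Run the full pipeline and build a summary report
#'
#' Deterministic given its inputs. When \code{outDir} is set, writes the
#' call tables (TSV), profiles (TSV), the novel-haplotype registry (FASTA)
#' and a machine-readable \code{summary.json}.
#'
#' @param specimens a [SpecimenSet] (e.g. from [readSpecimens()] or
#'   [generateCohort()]).
#' @param bundle a [MarkerBundle] (default packaged).
#' @param grouping metadata columns defining collections.
#' @param catalog census/deconvolution catalog (default the bundle's).
#' @param minSupport novel-haplotype confirmation threshold.
#' @param outDir optional output directory.
#' @return list: calls, intronCalls, census, profiles, carrier, summary.
#' @export
runPipeline <- function(specimens, bundle = defaultBundle(),
                        grouping = c("country", "year"),
                        catalog = alleleCatalog(bundle), minSupport = 2L,
                        outDir = NULL) {
  typed <- typeCohort(specimens, bundle, catalog = catalog,
                      minSupport = minSupport)
  meta <- specimenMeta(specimens)
  profiles <- buildProfiles(typed$calls, meta, grouping = grouping)
  icalls <- data.frame(specimen_id = typed$intronCalls$specimen_id,
                       intron_label = typed$intronCalls$intron_label,
                       intron_status = typed$intronCalls$status)
  intron_profiles <- buildProfiles(icalls,
                                   meta[, c("specimen_id", grouping)],
                                   grouping = grouping)
  carrier <- carrierStats(typed$calls)
  novel_confirmed <- unique(typed$census$calls$intron_label[
    typed$census$calls$matched == "novel" &
      typed$census$calls$status == "confirmed"])
  novel_prov <- unique(typed$census$calls$intron_label[
    typed$census$calls$matched == "novel" &
      typed$census$calls$status == "provisional"])
  summary <- list(
    n_specimens = nrow(meta),
    coib = as.list(table(typed$calls$coib_label)),
    tpi_strain = as.list(table(typed$calls$tpi_strain)),
    carrier = carrier[c("n_total", "n_carriers", "n_homo_hemi_R", "n_het",
                        "frac_carriers", "pct_carriers")],
    intron_haplotypes = sort(unique(
      typed$intronCalls$intron_label[!is.na(typed$intronCalls$intron_label)])),
    n_intron_haplotypes = length(unique(
      typed$intronCalls$intron_label[!is.na(typed$intronCalls$intron_label)])),
    novel_confirmed = novel_confirmed,
    novel_provisional = novel_prov)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(typed$calls, file.path(outDir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(typed$intronCalls, file.path(outDir, "intron_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prof_rows <- do.call(rbind, lapply(names(profiles), function(k) {
      pr <- profiles[[k]]
      data.frame(group = k, n = pr@nSpecimens,
                 t(as.matrix(profileFrequencies(pr, "tpi"))))
    }))
    utils::write.table(prof_rows, file.path(outDir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    reg <- novelRegistryFasta(typed$census)
    if (length(reg)) writeLines(reg, file.path(outDir, "novel_registry.fasta"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(calls = typed$calls, intronCalls = typed$intronCalls,
       census = typed$census, profiles = profiles,
       intronProfiles = intron_profiles, carrier = carrier,
       summary = summary)
}

#' Compare pipeline calls to a cohort's ground-truth ledger
#'
#' Closed-loop recovery check: a specimen is recovered when its COIB label
#' and Tpi strain genotype match the ledger truth and every resolved allele
#' label is consistent with the true allele pair. Zygosity is not compared
#' for unsexed specimens (a homozygous male and a hemizygous female are
#' indistinguishable from an unambiguous direct sequence).
#'
#' @param result [runPipeline()] output.
#' @param cohort the [SyntheticCohort] the specimens came from.
#' @return list: recovery fraction, per-specimen logical vector, mismatches.
#' @export
ledgerRecovery <- function(result, cohort) {
  led <- cohort@ledger
  calls <- result$calls
  m <- match(led$specimen_id, calls$specimen_id)
  calls <- calls[m, ]
  coib_ok <- calls$coib_label == led$mito_label
  strain_ok <- calls$tpi_strain == led$strain_genotype
  allele_ok <- vapply(seq_len(nrow(led)), function(i) {
    truth <- stats::na.omit(c(led$allele_a[i], led$allele_b[i]))
    got <- stats::na.omit(c(calls$allele_a[i], calls$allele_b[i]))
    got_known <- setdiff(got, "novel")
    all(got_known %in% truth)
  }, logical(1))
  ok <- coib_ok & strain_ok & allele_ok
  list(recovery = mean(ok), per_specimen = stats::setNames(ok, led$specimen_id),
       mismatches = led$specimen_id[!ok])
}
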