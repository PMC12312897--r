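## coib_typing: classify the COIB haplotype (R_COIB or CSh1-4) from the two
## diagnostic sites. COIB is mitochondrial, hence effectively haploid: an
## ambiguity code at either site signals mixed template, never
## heterozygosity, and yields an unclassified call.

#' Classify a COIB haplotype from site calls
#'
#' T at mCOI1164D is diagnostic of the R strain (R_COIB); the A/G states at
#' mCOI1164D crossed with A/G at mCOI1287R define CSh1-CSh4. The
#' T_1164 G_1287 configuration (unobserved in field surveys) is classified
#' R_COIB by the T-at-1164 rule but flagged \code{atypical}. Ambiguity codes
#' yield \code{unclassified} with flag \code{ambiguous_site}; uncovered
#' sites yield \code{unclassified} with flag \code{missing_site}.
#'
#' @param calls site-call vector from [extractSiteCalls()] (COI frame).
#' @param bundle a [MarkerBundle].
#' @param specimen_id optional id carried through to the result.
#' @return data.frame row: specimen_id, coib_label, coib_strain, coib_flags.
#' @export
classifyCoib <- function(calls, bundle, specimen_id = NA_character_) {
  res <- function(label, strain, flags = character(0))
    data.frame(specimen_id = specimen_id, coib_label = label,
               coib_strain = strain,
               coib_flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  b1164 <- calls[["mCOI1164D"]]
  b1287 <- calls[["mCOI1287R"]]
  if (is.na(b1164) || is.na(b1287))
    return(res("unclassified", NA_character_, "missing_site"))
  if (isAmbiguousCode(b1164) || isAmbiguousCode(b1287))
    return(res("unclassified", NA_character_, "ambiguous_site"))
  st <- siteTable(bundle, "COI")
  ok1164 <- b1164 %in% strsplit(st$allowed[st$site_id == "mCOI1164D"], "")[[1]]
  ok1287 <- b1287 %in% strsplit(st$allowed[st$site_id == "mCOI1287R"], "")[[1]]
  if (!ok1164 || !ok1287)
    return(res("unclassified", NA_character_, "unexpected_base"))
  if (b1164 == "T") {
    flags <- if (b1287 == "A") character(0) else "atypical"
    return(res("R_COIB", "R", flags))
  }
  defs <- haplotypeDefs(bundle, marker = "COIB")
  defs <- defs[defs$label != "R_COIB", ]
  wide <- split(defs, defs$label)
  for (lab in names(wide)) {
    h <- wide[[lab]]
    if (identical(h$base[h$site_id == "mCOI1164D"], b1164) &&
        identical(h$base[h$site_id == "mCOI1287R"], b1287))
      return(res(lab, "C"))
  }
  res("unclassified", NA_character_, "unexpected_base")
}

#' Classify COIB haplotypes for a whole cohort
#'
#' @param callList named list of site-call vectors (per specimen).
#' @param bundle a [MarkerBundle].
#' @return data.frame, one row per specimen.
#' @export
classifyCoibCohort <- function(callList, bundle) {
  do.call(rbind, Map(function(calls, id) classifyCoib(calls, bundle, id),
                     callList, names(callList)))
}
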