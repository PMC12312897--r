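## refcat: reference frames, diagnostic site tables, haplotype definitions,
## allele catalogs, primer metadata. All other stages consume these as data.

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE)
}

.strip_fa_names <- function(xs) {
  # keep the first word as the label, the rest as free-text provenance
  full <- names(xs)
  lab <- sub("\\s.*$", "", full)
  prov <- trimws(sub("^\\S+\\s*", "", full))
  names(xs) <- lab
  list(seqs = xs, info = data.frame(label = lab, provenance = prov,
                                    stringsAsFactors = FALSE))
}

#' Validate a MarkerBundle, enumerating every violation
#'
#' @param bundle a [MarkerBundle].
#' @return invisibly \code{TRUE}; otherwise stops with a message listing all
#'   violations found.
#' @export
validateBundle <- function(bundle) {
  errs <- character(0)
  frames <- bundle@frames
  for (fid in names(frames)) {
    s <- as.character(frames[[fid]])
    if (nchar(s) == 0) errs <- c(errs, sprintf("frame %s: empty sequence", fid))
    if (grepl("[^ACGT]", s))
      errs <- c(errs, sprintf("frame %s: non-ACGT characters", fid))
  }
  st <- bundle@sites
  suffix_alpha <- c(D = "AGT", R = "AG", Y = "CT", B = "CGT")
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    if (!row$frame_id %in% names(frames)) {
      errs <- c(errs, sprintf("site %s: unknown frame %s", row$site_id, row$frame_id))
      next
    }
    flen <- length(frames[[row$frame_id]])
    if (is.na(row$position) || row$position < 1 || row$position > flen)
      errs <- c(errs, sprintf(
        "site %s: position %s outside frame %s (1..%d); coordinates are 1-based",
        row$site_id, row$position, row$frame_id, flen))
    suf <- substring(row$site_id, nchar(row$site_id))
    want <- unname(suffix_alpha[suf])
    if (!is.na(want)) {
      got <- paste(sort(strsplit(row$allowed, "")[[1]]), collapse = "")
      if (!identical(got, want))
        errs <- c(errs, sprintf(
          "site %s: allowed bases %s do not match IUPAC suffix %s (%s)",
          row$site_id, row$allowed, suf, want))
    }
  }
  tpi_diag <- st$site_id[st$frame_id == "TpiGenomic" &
                           st$role == "strain_diagnostic"]
  if (!identical(tpi_diag, "gTpi183Y"))
    errs <- c(errs, paste0("exactly one TpiE4 site must have role ",
                           "strain_diagnostic (gTpi183Y); found: ",
                           paste(tpi_diag, collapse = ", ")))
  hap <- bundle@haplotypes
  for (lab in unique(hap$label)) {
    h <- hap[hap$label == lab, ]
    mk <- unique(h$marker)
    ok_sites <- if (identical(mk, "COIB")) st$site_id[st$frame_id == "COI"]
                else st$site_id[st$frame_id == "TpiGenomic"]
    bad <- setdiff(h$site_id, ok_sites)
    if (length(bad))
      errs <- c(errs, sprintf("haplotype %s: sites not of marker %s: %s",
                              lab, mk, paste(bad, collapse = ", ")))
  }
  coib <- hap[hap$marker == "COIB", ]
  cshx <- split(coib, coib$label)
  need <- c("R_COIB", "CSh1", "CSh2", "CSh3", "CSh4")
  miss <- setdiff(need, names(cshx))
  if (length(miss)) {
    errs <- c(errs, paste("missing COIB definitions:", paste(miss, collapse = ", ")))
  } else {
    for (lab in need) {
      got <- sort(cshx[[lab]]$site_id)
      if (!identical(got, c("mCOI1164D", "mCOI1287R")))
        errs <- c(errs, sprintf(
          "COIB definition %s must cover exactly mCOI1164D and mCOI1287R", lab))
    }
    b1164 <- vapply(cshx, function(h) h$base[h$site_id == "mCOI1164D"][1], "")
    b1287 <- vapply(cshx, function(h) h$base[h$site_id == "mCOI1287R"][1], "")
    # R territory: T at 1164 belongs to R_COIB alone; CSh1-4 must tile
    # {A,G} x {A,G} exactly once each
    for (lab in setdiff(need, "R_COIB"))
      if (b1164[lab] == "T")
        errs <- c(errs, sprintf(
          "COIB definition %s has T at mCOI1164D, colliding with R_COIB territory", lab))
    if (!(b1164["R_COIB"] == "T" && b1287["R_COIB"] == "A"))
      errs <- c(errs, "R_COIB must be T_1164 A_1287")
    grid <- paste(b1164[setdiff(need, "R_COIB")], b1287[setdiff(need, "R_COIB")])
    want_grid <- c("A A", "A G", "G A", "G G")
    if (!setequal(grid, want_grid) || anyDuplicated(grid))
      errs <- c(errs, "CSh1..CSh4 must tile the {A,G}x{A,G} grid exactly")
  }
  tpiE4 <- hap[hap$marker == "TpiE4", ]
  for (lab in unique(tpiE4$label)) {
    h <- tpiE4[tpiE4$label == lab, ]
    g183 <- h$base[h$site_id == "gTpi183Y"]
    strain <- unique(h$strain)
    if (length(g183) == 1) {
      if (strain == "R" && g183 != "T")
        errs <- c(errs, sprintf("TpiE4 R definition %s must have T at gTpi183Y", lab))
      if (strain == "C" && g183 != "C")
        errs <- c(errs, sprintf("TpiE4 C definition %s must have C at gTpi183Y", lab))
    }
  }
  if (anyDuplicated(names(bundle@catalog)))
    errs <- c(errs, "catalog labels must be unique")
  if (length(bundle@catalog)) {
    amb <- vapply(as.character(bundle@catalog),
                  function(s) grepl("[^ACGT]", s), logical(1))
    if (any(amb))
      errs <- c(errs, paste("catalog sequences must be unambiguous:",
                            paste(names(bundle@catalog)[amb], collapse = ", ")))
  }
  african <- c(paste0("AfrCa1", letters[1:6]), paste0("AfrCa2", letters[1:3]),
               "AfrRa1", "AfrRa2")
  # packaged default must carry the eleven African labels; user bundles may
  # subset, so only warn-level check when the bundle claims to be default
  pr <- bundle@primers
  for (i in seq_len(nrow(pr))) {
    if (grepl("[^ACGT]", pr$seq[i]))
      errs <- c(errs, sprintf("primer %s: ambiguous sequence", pr$name[i]))
    num <- suppressWarnings(as.integer(gsub("\\D", "", pr$name[i])))
    if (!is.na(num) && num != pr$name_position[i])
      errs <- c(errs, sprintf(
        "primer %s: name numeral %d inconsistent with name_position %d",
        pr$name[i], num, pr$name_position[i]))
    off <- bundle@frameInfo$gene_offset[match(pr$frame_id[i],
                                              bundle@frameInfo$frame_id)]
    anch <- pr$name_position[i] - off
    flen <- length(frames[[pr$frame_id[i]]])
    if (is.na(anch) || anch < 1 || anch > flen)
      errs <- c(errs, sprintf("primer %s: anchor %s outside frame %s",
                              pr$name[i], anch, pr$frame_id[i]))
  }
  if (length(errs))
    stop("bundle validation failed:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

#' Load a reference bundle from a directory
#'
#' Reads the bundle layout (\code{frames.fasta}, \code{frames.tsv},
#' \code{sites.tsv}, \code{haplotypes.tsv}, \code{catalog_TpiI4a200.fasta},
#' \code{catalog_extrapolated.fasta}, \code{primers.tsv},
#' \code{windows.tsv}) and returns a validated [MarkerBundle]. Validation
#' failures list every violation.
#'
#' @param path directory containing the bundle files.
#' @return a [MarkerBundle].
#' @export
loadBundle <- function(path) {
  need <- c("frames.fasta", "frames.tsv", "sites.tsv", "haplotypes.tsv",
            "catalog_TpiI4a200.fasta", "primers.tsv", "windows.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("bundle load error; missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  frames <- .strip_fa_names(readDNAStringSet(file.path(path, "frames.fasta")))
  cat_ <- .strip_fa_names(readDNAStringSet(file.path(path, "catalog_TpiI4a200.fasta")))
  extra_path <- file.path(path, "catalog_extrapolated.fasta")
  extra <- if (file.exists(extra_path))
    .strip_fa_names(readDNAStringSet(extra_path))$seqs else DNAStringSet()
  win_df <- .read_tsv(file.path(path, "windows.tsv"))
  windows <- stats::setNames(as.integer(win_df$value), win_df$key)
  bundle <- new("MarkerBundle",
    frames = frames$seqs,
    frameInfo = .read_tsv(file.path(path, "frames.tsv")),
    sites = .read_tsv(file.path(path, "sites.tsv")),
    haplotypes = .read_tsv(file.path(path, "haplotypes.tsv")),
    catalog = cat_$seqs,
    catalogInfo = cat_$info,
    extrapolated = extra,
    primers = .read_tsv(file.path(path, "primers.tsv")),
    windows = windows)
  validateBundle(bundle)
  bundle
}

#' Write a bundle back to the on-disk layout
#'
#' Serialization inverse of [loadBundle()]: reloading yields element-wise
#' identical definitions.
#'
#' @param bundle a [MarkerBundle].
#' @param path output directory (created if needed).
#' @return invisibly, \code{path}.
#' @export
writeBundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(bundle@frames, file.path(path, "frames.fasta"), width = 70)
  cat_out <- bundle@catalog
  prov <- bundle@catalogInfo$provenance[match(names(cat_out),
                                              bundle@catalogInfo$label)]
  names(cat_out) <- trimws(paste(names(cat_out), prov))
  writeXStringSet(cat_out, file.path(path, "catalog_TpiI4a200.fasta"), width = 70)
  if (length(bundle@extrapolated))
    writeXStringSet(bundle@extrapolated,
                    file.path(path, "catalog_extrapolated.fasta"), width = 70)
  wtab <- function(df, f) utils::write.table(df, file.path(path, f),
    sep = "\t", quote = FALSE, row.names = FALSE)
  wtab(bundle@frameInfo, "frames.tsv")
  wtab(bundle@sites, "sites.tsv")
  wtab(bundle@haplotypes, "haplotypes.tsv")
  wtab(bundle@primers, "primers.tsv")
  wtab(data.frame(key = names(bundle@windows),
                  value = unname(bundle@windows)), "windows.tsv")
  invisible(path)
}

#' The packaged default reference bundle
#'
#' @return the validated [MarkerBundle] shipped with the package.
#' @export
defaultBundle <- function() {
  loadBundle(system.file("extdata", "bundle", package = "fawtype"))
}

## ---- accessors -------------------------------------------------------------

#' @rdname MarkerBundle-accessors
#' @name MarkerBundle-accessors
#' @title Accessors for MarkerBundle components
#' @param bundle a [MarkerBundle].
#' @param marker,frame optional filters.
NULL

#' @rdname MarkerBundle-accessors
#' @export
refFrames <- function(bundle) bundle@frames

#' @rdname MarkerBundle-accessors
#' @export
siteTable <- function(bundle, frame = NULL) {
  st <- bundle@sites
  if (!is.null(frame)) st <- st[st$frame_id == frame, , drop = FALSE]
  st
}

#' @rdname MarkerBundle-accessors
#' @export
haplotypeDefs <- function(bundle, marker = NULL) {
  h <- bundle@haplotypes
  if (!is.null(marker)) h <- h[h$marker == marker, , drop = FALSE]
  h
}

#' @rdname MarkerBundle-accessors
#' @export
alleleCatalog <- function(bundle) bundle@catalog

#' @rdname MarkerBundle-accessors
#' @export
primerTable <- function(bundle) bundle@primers

#' @rdname MarkerBundle-accessors
#' @export
intronWindow <- function(bundle)
  c(bundle@windows[["tpi_intron_window_start"]],
    bundle@windows[["tpi_intron_window_end"]])

#' @rdname MarkerBundle-accessors
#' @export
catalogWindow <- function(bundle)
  c(bundle@windows[["tpi_catalog_window_start"]],
    bundle@windows[["tpi_catalog_window_end"]])

# frame coordinates of the amplified region (forward primer start .. reverse
# primer end), given the per-frame offset between published primer numerals
# and frame numbering
ampliconRegion <- function(bundle, frame_id) {
  pr <- bundle@primers[bundle@primers$frame_id == frame_id, ]
  off <- bundle@frameInfo$gene_offset[match(frame_id, bundle@frameInfo$frame_id)]
  fwd <- pr[pr$direction == "forward", ]
  rev_ <- pr[pr$direction == "reverse", ]
  c(start = fwd$name_position[1] - off, end = rev_$name_position[1] - off)
}

# marker name ("COIB"/"Tpi") -> frame id
markerFrame <- function(marker) {
  switch(marker, COIB = "COI", Tpi = "TpiGenomic",
         stop("unknown marker: ", marker))
}
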