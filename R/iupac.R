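## IUPAC ambiguity arithmetic. Direct Sanger sequencing of a diploid (male,
## ZZ) template superposes the two allele signals: a double peak is encoded
## as the IUPAC code covering both bases. Union encodes a double peak;
## subtraction inverts it during deconvolution.

.iupac_expand <- local({
  m <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  names(m) <- names(Biostrings::IUPAC_CODE_MAP)
  m
})

.iupac_collapse <- local({
  keys <- vapply(strsplit(Biostrings::IUPAC_CODE_MAP, ""),
                 function(b) paste(sort(b), collapse = ""), "")
  setNames(names(Biostrings::IUPAC_CODE_MAP), keys)
})

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code single IUPAC nucleotide letter.
#' @return character vector of plain bases (subset of A, C, G, T).
#' @export
iupacExpand <- function(code) {
  code <- toupper(code)
  out <- .iupac_expand[[code]]
  if (is.null(out)) stop("not an IUPAC nucleotide code: ", code)
  out
}

# precomputed 15x15 union table and compatibility/partner tables; exact
# per-character arithmetic is the inner loop of deconvolution and anchoring
.iupac_tabs <- local({
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  exp_ <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  keys <- vapply(exp_, function(b) paste(sort(b), collapse = ""), "")
  collapse <- setNames(codes, keys)
  un <- matrix(NA_character_, length(codes), length(codes),
               dimnames = list(codes, codes))
  for (a in codes) for (b in codes)
    un[a, b] <- collapse[[paste(sort(unique(c(exp_[[a]], exp_[[b]]))),
                                collapse = "")]]
  plain <- c("A", "C", "G", "T")
  compat <- matrix(FALSE, length(codes), 4, dimnames = list(codes, plain))
  for (a in codes) compat[a, ] <- plain %in% exp_[[a]]
  partner <- matrix("", length(codes), 4, dimnames = list(codes, plain))
  for (o in codes) for (a in plain)
    partner[o, a] <- paste(plain[un[a, plain] == o], collapse = "")
  list(union = un, compat = compat, partner = partner)
})

#' Union of two IUPAC codes
#'
#' Returns the minimal IUPAC code whose expansion covers both arguments --
#' the textual encoding of overlapping chromatogram peaks when a
#' heterozygous male is sequenced directly. Vectorised over equal-length
#' inputs.
#'
#' @param b1,b2 IUPAC nucleotide codes.
#' @return IUPAC code(s) covering both expansions.
#' @examples
#' iupacUnion("C", "T")  # "Y"
#' iupacUnion("A", "A")  # "A"
#' @export
iupacUnion <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  if (length(b1) != length(b2)) stop("arguments must have equal length")
  bad <- unique(c(b1[!b1 %in% rownames(.iupac_tabs$union)],
                  b2[!b2 %in% rownames(.iupac_tabs$union)]))
  if (length(bad)) stop("not an IUPAC nucleotide code: ",
                        paste(bad, collapse = ", "))
  unname(.iupac_tabs$union[cbind(b1, b2)])
}

#' Subtract a base from an IUPAC code
#'
#' Inverts the double-peak encoding: given the observed code at a site and
#' one known allele's base, returns the base set the partner allele may
#' carry. Self-subtraction of an unambiguous call keeps the shared base
#' (a homozygous site): \code{iupacSubtract("A", "A")} is \code{"A"}.
#'
#' @param code observed IUPAC code.
#' @param b base (IUPAC code) to remove.
#' @return character vector of remaining plain bases (possibly empty).
#' @export
iupacSubtract <- function(code, b) {
  e <- iupacExpand(code)
  rm_ <- iupacExpand(b)
  if (length(e) == 1L && identical(e, rm_)) return(e)  # homozygous site
  setdiff(e, rm_)
}

#' Partner bases consistent with an observed superposition
#'
#' The set of plain bases p such that \code{iupacUnion(alleleBase, p)}
#' equals the observed code. Empty when the known allele base is
#' inconsistent with the observation. This is the site-wise inference rule
#' used by heterozygote deconvolution; unlike raw subtraction it guarantees
#' that the reconstructed pair superposes back to the observation.
#'
#' @param observed observed IUPAC code at the site.
#' @param alleleBase plain base carried by the known allele.
#' @return character vector of consistent partner bases.
#' @export
iupacPartner <- function(observed, alleleBase) {
  s <- .iupac_tabs$partner[toupper(observed), toupper(alleleBase)]
  if (nchar(s) == 0) character(0) else strsplit(s, "")[[1]]
}

#' Site-wise superposition of two equal-length sequences
#'
#' @param s1,s2 DNA strings of equal length (IUPAC codes permitted).
#' @return character scalar, the site-wise IUPAC union.
#' @export
iupacUnionSeq <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  if (length(a) != length(b))
    stop("sequences must have equal length for site-wise superposition")
  paste(iupacUnion(a, b), collapse = "")
}

#' Is an IUPAC code ambiguous?
#'
#' A site call is ambiguous iff its code expands to two or more bases.
#'
#' @param code IUPAC code(s).
#' @return logical vector.
#' @export
isAmbiguousCode <- function(code) {
  vapply(toupper(code), function(x) {
    if (is.na(x)) return(NA)
    length(.iupac_expand[[x]]) >= 2L
  }, logical(1), USE.NAMES = FALSE)
}

revComp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
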