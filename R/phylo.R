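## phylo_strain: distance trees of TpiI4a200 haplotypes with bootstrap and
## midpoint rooting; strain assignment of queries from the clades of
## strain-labeled references. Neighbor joining stands in for the study's
## interactive ML trees: the downstream quantity is clade membership, which
## NJ recovers at these divergence levels, and a newick-import hook is
## provided for external trees.

#' Center-star progressive alignment
#'
#' Pairwise global alignment (match 1, mismatch -1, gap -2) of every
#' sequence against a center (the longest sequence; ties broken by
#' lexicographic id), with gaps merged into a common column space. Input
#' order does not affect the center choice.
#'
#' @param sequences named character vector or DNAStringSet (>= 3 sequences).
#' @return character matrix, rows = sequences, columns = alignment columns
#'   (gap \code{"-"}).
#' @export
alignHaplotypes <- function(sequences) {
  seqs <- stats::setNames(toupper(as.character(sequences)), names(sequences))
  if (length(seqs) < 3) stop("alignment needs at least 3 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  ord <- order(-nchar(seqs), names(seqs))
  center_id <- names(seqs)[ord[1]]
  center <- seqs[[center_id]]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  # per-sequence alignment to the center as (center-gaps, seq-gaps) strings
  pair <- lapply(seqs, function(s) {
    if (identical(s, center))
      return(list(c = center, q = s))
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(s), subject = Biostrings::DNAString(center),
      type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
    list(c = as.character(Biostrings::alignedSubject(al)),
         q = as.character(Biostrings::alignedPattern(al)))
  })
  # merge into a common column space via insertion slots: slot i holds query
  # bases aligned against center gaps before center residue i+1 (slot 0 =
  # before the first residue); matched[i] is the query char on residue i
  n_center <- nchar(center)
  decomp <- lapply(pair, function(p) {
    cc <- strsplit(p$c, "")[[1]]; qq <- strsplit(p$q, "")[[1]]
    ins <- vector("list", n_center + 1L)
    for (k in seq_len(n_center + 1L)) ins[[k]] <- character(0)
    matched <- character(n_center)
    slot <- 1L
    for (k in seq_along(cc)) {
      if (cc[k] == "-") ins[[slot]] <- c(ins[[slot]], qq[k])
      else { matched[slot] <- qq[k]; slot <- slot + 1L }
    }
    list(ins = ins, matched = matched)
  })
  W <- Reduce(pmax, lapply(decomp, function(d) lengths(d$ins)))
  width <- n_center + sum(W)
  out <- matrix("-", nrow = length(seqs), ncol = width,
                dimnames = list(names(seqs), NULL))
  for (si in seq_along(seqs)) {
    d <- decomp[[si]]
    row <- character(0)
    for (i in seq_len(n_center)) {
      pad <- c(d$ins[[i]], rep("-", W[i] - length(d$ins[[i]])))
      row <- c(row, pad, d$matched[i])
    }
    last <- d$ins[[n_center + 1L]]
    row <- c(row, last, rep("-", W[n_center + 1L] - length(last)))
    out[si, ] <- row
  }
  out
}

#' Pairwise distances from a gapped alignment
#'
#' Jukes-Cantor (JC69) distances, d = -(3/4) ln(1 - (4/3) p), with p the
#' mismatch proportion over pairwise-complete columns (gap-free in both
#' sequences: pairwise deletion, so the indel-rich intron does not discard
#' most columns as complete deletion would). Saturated pairs (p >= 3/4) are
#' set to \code{ceiling} and flagged. \code{model = "raw"} returns p itself.
#'
#' @param aln character matrix from [alignHaplotypes()].
#' @param model \code{"JC69"} or \code{"raw"}.
#' @param ceiling distance assigned to saturated pairs.
#' @return symmetric distance matrix with attribute \code{saturated}.
#' @export
pairwiseDistances <- function(aln, model = c("JC69", "raw"), ceiling = 5) {
  model <- match.arg(model)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  saturated <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- aln[i, ] != "-" & aln[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns for pair ", rownames(aln)[i], " / ",
           rownames(aln)[j], call. = FALSE)
    p <- mean(aln[i, ok] != aln[j, ok])
    if (model == "raw") { d[i, j] <- d[j, i] <- p; next }
    if (p >= 0.75) {
      d[i, j] <- d[j, i] <- ceiling
      saturated <- c(saturated,
                     paste(rownames(aln)[i], rownames(aln)[j], sep = "/"))
    } else {
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  attr(d, "saturated") <- saturated
  d
}

#' Neighbor-joining tree with clamped branch lengths
#'
#' @param distances symmetric distance matrix (n >= 3).
#' @return unrooted \code{ape::phylo}; negative NJ branch lengths are
#'   clamped to 0 and recorded in attribute \code{clamped}.
#' @export
buildNJTree <- function(distances) {
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  tree <- ape::nj(stats::as.dist(distances))
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path;
#' tip-to-tip path lengths are unchanged.
#'
#' @param tree an \code{ape::phylo}.
#' @return rooted \code{ape::phylo}.
#' @export
midpointRoot <- function(tree) phangorn::midpoint(tree)

#' Bootstrap support by alignment-column resampling
#'
#' Columns are resampled with replacement \code{nReps} times; support for
#' each internal edge of \code{tree} is the percentage of replicate NJ trees
#' containing the same bipartition. Seeded and reproducible.
#'
#' @param aln alignment matrix.
#' @param tree the tree whose bipartitions are scored (built from \code{aln}).
#' @param nReps replicates (default 100); 0 returns the tree unchanged with
#'   no supports.
#' @param seed RNG seed.
#' @param model distance model passed to [pairwiseDistances()].
#' @return \code{tree} with \code{node.label} set to integer percentages
#'   (root label empty).
#' @export
bootstrapSupport <- function(aln, tree, nReps = 100L, seed = 1L,
                             model = "JC69") {
  if (nReps == 0L) return(tree)
  set.seed(seed)
  reps <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    reps[[r]] <- buildNJTree(pairwiseDistances(aln[, cols, drop = FALSE],
                                               model = model))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- as.character(round(100 * counts / nReps))
  tree
}

#' Assign strain identity to query tips from reference clades
#'
#' For each query tip, walks rootward to the smallest clade containing at
#' least \code{minRefs} reference tips; if every such reference shares one
#' strain label the query is assigned it, otherwise it is unassigned with a
#' \code{mixed_reference_clade} flag. Reference labels derive from the
#' references' gTpi183Y-based strain identity.
#'
#' @param tree rooted \code{ape::phylo} (e.g. midpoint rooted).
#' @param referenceLabels named character vector tip -> \code{"C"}/\code{"R"}.
#' @param queryIds tips to assign.
#' @param minRefs minimum reference tips defining a clade (default 2).
#' @return data.frame: query, strain (C/R/unassigned), n_refs,
#'   ref_tips (comma-joined), support (clade bootstrap label when present),
#'   flag.
#' @export
assignStrainByClade <- function(tree, referenceLabels, queryIds,
                                minRefs = 2L) {
  missing_q <- setdiff(queryIds, tree$tip.label)
  if (length(missing_q))
    stop("query tip(s) not in tree: ", paste(missing_q, collapse = ", "),
         call. = FALSE)
  for (s in c("C", "R"))
    if (sum(referenceLabels == s & names(referenceLabels) %in% tree$tip.label)
        < minRefs)
      stop("tree must contain at least ", minRefs, " ", s,
           "-strain reference tips", call. = FALSE)
  ntip <- length(tree$tip.label)
  out <- vector("list", length(queryIds))
  for (qi in seq_along(queryIds)) {
    q <- queryIds[qi]
    tipnum <- match(q, tree$tip.label)
    anc <- phangorn::Ancestors(tree, tipnum, type = "all")
    res <- data.frame(query = q, strain = "unassigned", n_refs = 0L,
                      ref_tips = "", support = NA_character_,
                      flag = "no_reference_clade", stringsAsFactors = FALSE)
    for (node in anc) {
      tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
      refs <- intersect(tips, names(referenceLabels))
      refs <- setdiff(refs, q)
      if (length(refs) < minRefs) next
      labs <- unique(referenceLabels[refs])
      supp <- if (!is.null(tree$node.label)) tree$node.label[node - ntip]
              else NA_character_
      res <- data.frame(query = q,
                        strain = if (length(labs) == 1L) unname(labs)
                                 else "unassigned",
                        n_refs = length(refs),
                        ref_tips = paste(refs, collapse = ","),
                        support = supp,
                        flag = if (length(labs) == 1L) ""
                               else "mixed_reference_clade",
                        stringsAsFactors = FALSE)
      break
    }
    out[[qi]] <- res
  }
  do.call(rbind, out)
}

#' Read an externally built tree (newick) for strain assignment
#'
#' Hook for plugging in an external maximum-likelihood tree in place of the
#' internal NJ tree.
#'
#' @param path newick file.
#' @return \code{ape::phylo}.
#' @export
readExternalTree <- function(path) ape::read.tree(path)

#' Write a tree with supports as internal node labels
#'
#' @param tree \code{ape::phylo}.
#' @param path output newick file.
#' @export
writeTreeNewick <- function(tree, path) ape::write.tree(tree, file = path)
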