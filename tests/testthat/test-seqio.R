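# IUPAC arithmetic, specimen IO, anchoring and site-call extraction.

test_that("iupacUnion matches the hand-written set oracle over all code pairs", {
  codes <- names(oracle_expand)
  for (a in codes) for (b in codes)
    expect_identical(iupacUnion(a, b), oracle_union(a, b),
                     info = paste(a, b))
  expect_identical(iupacUnion("C", "T"), "Y")
  expect_identical(iupacUnion("A", "A"), "A")
  expect_error(iupacUnion("A", "X"), "IUPAC")
})

test_that("iupacSubtract matches set semantics with the homozygous convention", {
  for (code in names(oracle_expand)) for (b in c("A", "C", "G", "T")) {
    want <- if (length(oracle_expand[[code]]) == 1 &&
                oracle_expand[[code]] == b) b
            else setdiff(oracle_expand[[code]], b)
    expect_identical(sort(iupacSubtract(code, b)), sort(want),
                     info = paste(code, b))
  }
  expect_identical(iupacSubtract("Y", "C"), "T")
  expect_identical(iupacSubtract("A", "A"), "A")
})

test_that("subtraction inverts union: subtract(union(a,b), a) contains b", {
  plain <- c("A", "C", "G", "T")
  for (a in plain) for (b in plain)
    expect_true(b %in% iupacSubtract(iupacUnion(a, b), a),
                info = paste(a, b))
})

test_that("iupacPartner returns exactly the bases whose union reproduces obs", {
  plain <- c("A", "C", "G", "T")
  for (obs in names(oracle_expand)) for (a in plain) {
    want <- plain[vapply(plain, function(p)
      oracle_union(a, p) == obs, logical(1))]
    expect_identical(iupacPartner(obs, a), want, info = paste(obs, a))
  }
})

test_that("readSpecimens joins FASTA to metadata and normalizes case", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "seqs.fasta")
  lines <- character(0)
  for (id in c("S1", "S2", "S3")) {
    lines <- c(lines, paste0(">", id, "|COIB"), tolower(mito_reads[["CSh4"]]),
               paste0(">", id, "|Tpi"), tpi_reads[["AfrCa1a"]])
  }
  writeLines(lines, fa)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("specimen_id\tcountry\tsite\tyear\tsex\tmethod",
               "S1\tGhana\tEjura\t2018\tunknown\tlarva",
               "S2\tGhana\tEjura\t2018\tmale\tpheromone_trap",
               "S3\tTogo\tVogan\t2018\tfemale\tlarva"), meta)
  ss <- readSpecimens(fa, meta)
  expect_equal(nrow(specimenMeta(ss)), 3L)
  expect_setequal(names(ss@sequences), c("COIB", "Tpi"))
  # lowercase uppercased
  expect_identical(as.character(specimenSeqs(ss, "COIB")[["S1"]]),
                   mito_reads[["CSh4"]])
  # trap implies male
  expect_identical(specimenMeta(ss)$sex[2], "male")
})

test_that("trap-caught females and duplicate records are rejected", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "seqs.fasta")
  writeLines(c(">S1|COIB", mito_reads[["CSh4"]]), fa)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("specimen_id\tcountry\tsite\tyear\tsex\tmethod",
               "S1\tGhana\tEjura\t2018\tfemale\tpheromone_trap"), meta)
  expect_error(readSpecimens(fa, meta), "pheromone_trap.*female")

  fa2 <- file.path(dir, "dup.fasta")
  writeLines(c(">S1|COIB", mito_reads[["CSh4"]],
               ">S1|COIB", mito_reads[["CSh2"]]), fa2)
  expect_error(readSpecimens(fa2, meta), "duplicate")
})

test_that("specimens missing one side of the join are flagged with a warning", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "seqs.fasta")
  writeLines(c(">S1|COIB", mito_reads[["CSh4"]]), fa)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("specimen_id\tcountry\tsite\tyear",
               "S2\tGhana\tEjura\t2018"), meta)
  expect_warning(expect_warning(ss <- readSpecimens(fa, meta),
                                "no sequence"), "no metadata")
  m <- specimenMeta(ss)
  expect_identical(m$join_flag[m$specimen_id == "S1"], "no_metadata")
  expect_identical(m$join_flag[m$specimen_id == "S2"], "no_sequence")
})

test_that("an exact reference amplicon anchors forward with full coverage", {
  region <- fawtype:::ampliconRegion(bundle, "COI")
  coib <- substring(as.character(refFrames(bundle)[["COI"]]),
                    region["start"], region["end"])
  anc <- anchorSequence(coib, "COIB", bundle)
  expect_identical(anc@orientation, "forward")
  expect_identical(anc@anchorMethod, "primer")
  # every frame position between the trimmed primers is covered
  pr <- primerTable(bundle)
  inner <- (region["start"] + nchar(pr$seq[pr$name == "c891F"])):
           (region["end"] - nchar(pr$seq[pr$name == "c1472R"]))
  expect_true(all(inner %in% anc@refPos))
})

test_that("anchoring is strand-invariant and idempotent", {
  read <- tpi_reads[["AfrRa1"]]
  calls_f <- siteCallsFromSequence(read, "Tpi", bundle)
  calls_r <- siteCallsFromSequence(fawtype:::revComp(read), "Tpi", bundle)
  expect_identical(calls_f, calls_r)
  # re-anchoring the anchored extraction changes no call
  anc <- anchorSequence(read, "Tpi", bundle)
  re_calls <- siteCallsFromSequence(paste(anc@bases, collapse = ""),
                                    "Tpi", bundle)
  expect_identical(unclass(re_calls), unclass(calls_f))
})

test_that("an intron deletion shifts downstream coordinates correctly", {
  # delete 12 bases at frame positions 300..311 (inside the intron window)
  read <- tpi_reads[["AfrCa1a"]]
  del_start <- 300L; del_len <- 12L
  mutant <- paste0(substring(read, 1, del_start - 1L),
                   substring(read, del_start + del_len, nchar(read)))
  anc <- anchorSequence(mutant, "Tpi", bundle)
  expect_identical(anc@anchorMethod, "alignment")
  # exon sites (all < 300) still called identically
  calls <- extractSiteCalls(anc, bundle)
  ref_calls <- siteCallsFromSequence(read, "Tpi", bundle)
  expect_identical(unclass(calls), unclass(ref_calls))
  # hand-computed coordinate map: query base mapped to ref position p >= 312
  # must equal the reference base there; deleted positions are unmapped
  frame_chars <- strsplit(as.character(refFrames(bundle)[["TpiGenomic"]]),
                          "")[[1]]
  expect_equal(sum(is.na(anc@refPos)), 0L)  # deletion, no insertions
  # positions clear of the deletion (equivalent-cost gap placements may
  # shift inside repeats, so probe well downstream)
  for (p in c(320L, 400L, 500L)) {
    j <- match(p, anc@refPos)
    expect_false(is.na(j))
    expect_identical(anc@bases[j], frame_chars[p])
  }
  # intron segment shortened by exactly the deletion
  seg <- extractIntronSegment(anc, bundle)
  iw <- intronWindow(bundle)
  expect_equal(nchar(seg), (iw[2] - iw[1] + 1L) - del_len)
})

test_that("site calls report missing sites and ambiguity correctly", {
  # truncated before mCOI1287R
  region <- fawtype:::ampliconRegion(bundle, "COI")
  coib <- substring(as.character(refFrames(bundle)[["COI"]]),
                    region["start"], region["end"])
  trunc <- substring(coib, 1, 1250 - region["start"])
  calls <- siteCallsFromSequence(trunc, "COIB", bundle)
  expect_false(is.na(calls[["mCOI1164D"]]))
  expect_true(is.na(calls[["mCOI1287R"]]))
  # AfrRa1 catalog sequence carries the R-diagnostic T at gTpi183Y
  calls_r <- siteCallsFromSequence(tpi_reads[["AfrRa1"]], "Tpi", bundle)
  expect_identical(calls_r[["gTpi183Y"]], "T")
  # superposition of AfrRa1/AfrCa1a is heterozygous Y at gTpi183Y
  u <- iupacUnionSeq(tpi_reads[["AfrRa1"]], tpi_reads[["AfrCa1a"]])
  calls_u <- siteCallsFromSequence(u, "Tpi", bundle)
  expect_identical(calls_u[["gTpi183Y"]], "Y")
  expect_true(isAmbiguousCode("Y"))
  expect_false(isAmbiguousCode("T"))
})

test_that("unanchorable sequences error with the best score", {
  set.seed(1)
  junk <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  expect_error(anchorSequence(junk, "COIB", bundle), "unanchorable")
  expect_error(anchorSequence("ACGT", "COIB", bundle), "shorter than minimum")
})
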