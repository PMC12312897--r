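mk_meta <- function(ids, country = "Ghana", year = 2018L) {
  data.frame(specimen_id = ids, country = country, site = "x", year = year)
}

test_that("profile frequencies use classified denominators only", {
  ids <- sprintf("s%02d", 1:10)
  calls <- data.frame(specimen_id = ids,
                      coib_label = c(rep("CSh4", 10)))
  p <- buildProfiles(calls, mk_meta(ids))[[1]]
  f <- profileFrequencies(p, "coib", categories = c("CSh1", "CSh2", "CSh3",
                                                    "CSh4"))
  expect_equal(unname(f), c(0, 0, 0, 1))
  # two unclassified drop out of the denominator
  calls2 <- data.frame(specimen_id = ids,
                       coib_label = c(rep("CSh4", 6), rep("CSh2", 2),
                                      rep("unclassified", 2)))
  p2 <- buildProfiles(calls2, mk_meta(ids))[[1]]
  f2 <- profileFrequencies(p2, "coib")
  expect_equal(sum(f2), 1)
  expect_equal(unname(f2[["CSh4"]]), 6 / 8)
  expect_equal(unname(f2[["CSh2"]]), 2 / 8)
})

test_that("profiles are invariant to specimen order and reject bad keys", {
  ids <- sprintf("s%02d", 1:8)
  calls <- data.frame(specimen_id = ids,
                      tpi_strain = c("C", "C", "R", "H", "C", "C", "R", "C"))
  p1 <- buildProfiles(calls, mk_meta(ids))[[1]]
  perm <- sample(seq_along(ids))
  p2 <- buildProfiles(calls[perm, ], mk_meta(ids)[perm, ])[[1]]
  expect_identical(p1@tpiStrainCounts, p2@tpiStrainCounts)
  expect_error(buildProfiles(calls, mk_meta(ids), grouping = "continent"),
               "continent")
})

test_that("carrier accounting follows the Z-chromosome dosage rules", {
  # 1 RR male + 1 C/R male + 1 R female in n = 10
  calls <- data.frame(
    specimen_id = sprintf("s%02d", 1:10),
    tpi_strain = c("R", "H", "R", rep("C", 7)),
    zygosity = c("homozygous", "heterozygous", "hemizygous_female",
                 rep("hemizygous_female", 7)))
  cs <- carrierStats(calls)
  expect_equal(cs$n_carriers, 3L)
  expect_equal(cs$n_homo_hemi_R, 2L)
  expect_equal(cs$n_het, 1L)
  expect_equal(unname(cs$r_chromosomes["total"]), 4L)   # 2 + 1 + 1
  expect_equal(cs$n_carriers, cs$n_homo_hemi_R + cs$n_het)
  # all-C cohort
  calls0 <- data.frame(specimen_id = "a", tpi_strain = "C",
                       zygosity = "hemizygous_female")
  expect_equal(carrierStats(calls0)$n_carriers, 0L)
  expect_equal(carrierStats(calls0)$pct_carriers, 0)
})

test_that("chromosome-denominated shares reproduce printed arithmetic", {
  # 36 of 208 R chromosomes in homo/hemizygous specimens -> 17%
  calls <- data.frame(
    specimen_id = sprintf("s%04d", 1:198),
    tpi_strain = c(rep("R", 26), rep("H", 172)),
    zygosity = c(rep("homozygous", 10), rep("hemizygous_female", 16),
                 rep("heterozygous", 172)))
  cs <- carrierStats(calls)
  expect_equal(unname(cs$r_chromosomes["homo_hemi"]), 36L)
  expect_equal(unname(cs$r_chromosomes["total"]), 208L)
  expect_equal(cs$pct_homo_hemi_chrom, 17)
})

test_that("Pearson similarity handles the analytic cases and guards", {
  v <- c(a = 0.2, b = 0.3, c = 0.5)
  expect_equal(pearsonProfileSimilarity(v, v), 1)
  expect_equal(pearsonProfileSimilarity(c(a = 1, b = 0, c = 0),
                                        c(a = 0, b = 1, c = 0)), -0.5)
  expect_error(pearsonProfileSimilarity(v, v[c(2, 1, 3)]), "identical ordered")
  expect_error(pearsonProfileSimilarity(c(a = 1, b = 1, c = 1), v),
               "zero-variance")
  expect_error(pearsonProfileSimilarity(v[1:2], v[1:2]), "3 categories")
})

test_that("FL/TX profile typing is nearest-reference with a margin", {
  mk_prof <- function(counts) new("CollectionProfile",
    key = c(country = "x", year = "2018"), nSpecimens = sum(counts),
    coibCounts = counts, tpiStrainCounts = integer(0),
    intronCounts = integer(0))
  refs <- referenceCshProfiles()
  # the FL reference vector itself
  fl_counts <- setNames(as.integer(round(refs[["FL-type"]] * 100)),
                        names(refs[["FL-type"]]))
  expect_identical(classifyProfileType(mk_prof(fl_counts))$type, "FL-type")
  # CSh4-dominated with CSh2 ~ 0: the continental African background
  afr <- c(CSh1 = 0L, CSh2 = 1L, CSh3 = 0L, CSh4 = 99L)
  expect_identical(classifyProfileType(mk_prof(afr))$type, "FL-type")
  # constructed midpoint between the references is indeterminate
  mid <- (refs[["FL-type"]] + refs[["TX-type"]]) / 2
  mid_counts <- setNames(as.integer(round(mid * 1000)), names(mid))
  expect_identical(classifyProfileType(mk_prof(mid_counts))$type,
                   "indeterminate")
  expect_error(classifyProfileType(mk_prof(c(CSh1 = 0L, CSh2 = 0L,
                                             CSh3 = 0L, CSh4 = 0L))),
               "lacks classified")
})

test_that("introduction signal reproduces the Ejura 2018 CSh2 influx", {
  mk_prof <- function(counts) new("CollectionProfile",
    key = c(country = "x", year = "y"), nSpecimens = sum(counts),
    coibCounts = counts, tpiStrainCounts = integer(0),
    intronCounts = integer(0))
  focal <- mk_prof(c(CSh2 = 51L, CSh4 = 78L))
  baseline <- mk_prof(c(CSh2 = 4L, CSh4 = 323L))
  sig <- detectIntroductionSignal(focal, baseline)
  expect_true(sig$flagged)
  expect_identical(sig$rare_labels, "CSh2")
  expect_equal(sig$table["focal", "rare"], 51)
  expect_equal(sig$p_value, oracle_fisher_p(sig$table), tolerance = 1e-9)
  expect_lt(sig$p_value, 1e-10)
  # a focal collection at baseline frequencies is not flagged
  same <- mk_prof(c(CSh2 = 1L, CSh4 = 81L))
  expect_false(detectIntroductionSignal(same, baseline)$flagged)
  # tiny focal n: exact p against the hypergeometric enumeration oracle
  tiny <- mk_prof(c(CSh2 = 1L, CSh4 = 2L))
  sig2 <- detectIntroductionSignal(tiny, baseline)
  expect_equal(sig2$p_value, oracle_fisher_p(sig2$table), tolerance = 1e-9)
  expect_error(detectIntroductionSignal(focal, mk_prof(c(CSh4 = 0L))),
               "baseline")
})

test_that("host-use cross-tab reproduces share-on-C-host arithmetic", {
  strain <- c(rep("R", 85), rep("C", 87))
  host <- c(rep("C_host", 24), rep("R_host", 61),
            rep("C_host", 85), rep("R_host", 2))
  hs <- strainHostSummary(strain, host)
  expect_equal(hs$per_strain[["R"]]$on_c_host, 24L)
  expect_equal(hs$per_strain[["R"]]$pct_on_c_host, 28)
  expect_equal(hs$per_strain[["C"]]$n, 87L)
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(roundHalfUp(17.5), 18)
  expect_equal(roundHalfUp(16.5), 17)
  expect_equal(roundHalfUp(98.776), 99)
  expect_equal(roundHalfUp(c(0.4, 0.5, 2.49)), c(0, 1, 2))
})
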