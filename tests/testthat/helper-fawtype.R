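# Shared fixtures and independent oracles for the suite.

bundle <- defaultBundle()

# full emitted amplicon reads per allele / mito haplotype (generator internals
# reused as fixture builders)
tpi_reads <- fawtype:::.allele_reads(bundle)
mito_reads <- fawtype:::.mito_reads(bundle)
catalog_seqs <- setNames(as.character(alleleCatalog(bundle)),
                         names(alleleCatalog(bundle)))

# ---- independent IUPAC oracle (hand-written, no package code) --------------
oracle_expand <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

oracle_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  names(oracle_expand)[vapply(oracle_expand, function(e)
    paste(sort(e), collapse = "") == key, logical(1))]
}

oracle_union <- function(a, b)
  oracle_code_for(c(oracle_expand[[a]], oracle_expand[[b]]))

# lookup form of the oracle union (still derived only from the hand-written
# expansion table above), so exhaustive enumerations stay fast
oracle_union_tab <- local({
  codes <- names(oracle_expand)
  m <- matrix(NA_character_, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes) m[a, b] <- oracle_union(a, b)
  m
})

# ---- brute-force deconvolution oracle --------------------------------------
# all unordered catalog pairs whose per-position oracle union reproduces obs
oracle_pairs <- function(obs, cat_seqs) {
  oc <- strsplit(obs, "")[[1]]
  labs <- names(cat_seqs)
  chars <- lapply(cat_seqs, function(s) strsplit(s, "")[[1]])
  out <- list()
  for (i in seq_along(labs)) for (j in i:length(labs)) {
    u <- oracle_union_tab[cbind(chars[[i]], chars[[j]])]
    if (all(u == oc))
      out[[length(out) + 1L]] <- sort(c(labs[i], labs[j]))
  }
  out
}

# ---- exact hypergeometric oracle for 2x2 Fisher p --------------------------
# two-sided p: sum of P(X = k) over all k with P(X = k) <= P(X = x)
oracle_fisher_p <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  kk <- max(0, k - n):min(k, m)
  probs <- choose(m, kk) * choose(n, k - kk) / choose(m + n, k)
  px <- probs[kk == x]
  sum(probs[probs <= px * (1 + 1e-7)])
}

# ---- cached expensive pipeline runs (shared across acceptance blocks) ------
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(scenario, catalog_mode = c("full", "catalog2016"),
                       seed = NULL) {
  catalog_mode <- match.arg(catalog_mode)
  key <- paste(scenario, catalog_mode, if (is.null(seed)) "default" else seed,
               sep = "_")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  sc <- packagedScenarios()[[scenario]]
  coh <- if (is.null(seed)) generateCohort(sc, bundle)
         else generateCohort(sc, bundle, seed = seed)
  cat_ <- if (catalog_mode == "catalog2016")
    alleleCatalog(bundle)[c("AfrCa1a", "AfrCa1b", "AfrCa1c", "AfrCa2a",
                            "AfrCa2b", "AfrCa2c", "AfrRa1")]
  else alleleCatalog(bundle)
  res <- runPipeline(coh@specimens, bundle, grouping = c("country", "year"),
                     catalog = cat_)
  out <- list(cohort = coh, result = res)
  .run_cache[[key]] <- out
  out
}

# pooled intron haplotype frequencies over a pipeline result
pooled_intron_freq <- function(res, categories) {
  counts <- table(res$intronCalls$intron_label)
  v <- setNames(rep(0, length(categories)), categories)
  known <- intersect(names(counts), categories)
  v[known] <- counts[known]
  v / sum(v)
}

background7 <- c("AfrCa1a", "AfrCa1b", "AfrCa1c", "AfrCa2a", "AfrCa2b",
                 "AfrCa2c", "AfrRa1")

# small mixed scenario for fast closed-loop unit tests
small_scenario <- function(n = 60L, seed = 7L, ...) {
  scenarioConfig(
    data.frame(country = "Togo", site = "Vogan", year = 2018L, n = n),
    zAllelePool = c(AfrCa1a = 0.5, AfrCa2a = 0.25, AfrRa1 = 0.25),
    mitoPool = c(R_COIB = 0.5, CSh4 = 0.45, CSh2 = 0.05),
    seed = seed, ...)
}
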