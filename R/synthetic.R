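## synthetic_cohort: seeded generator of specimen cohorts with the
## statistical structure the analysis assumes. Inheritance follows the
## ZW/ZZ system: females carry one Z (hemizygous at Tpi, never
## heterozygous), males two; the Z carries strain identity and the Tpi
## markers, the mitochondrion travels matrilineally and may be
## strain-discordant. Direct sequencing of a heterozygous male is emulated
## by the site-wise IUPAC union of his two allele sequences.

.allele_strain_class <- function(alleleSeqs, bundle) {
  cw <- catalogWindow(bundle)
  st <- siteTable(bundle, "TpiGenomic")
  pos183 <- st$position[st$site_id == "gTpi183Y"] - cw[1] + 1L
  vapply(alleleSeqs, function(s)
    if (substring(s, pos183, pos183) == "T") "R" else "C", "")
}

#' Build a scenario configuration
#'
#' @param collections data.frame with columns country, site, year, n and
#'   optionally sex_ratio (probability female, default 0.5) and method
#'   (\code{larva}/\code{pheromone_trap}, default larva).
#' @param zAllelePool named numeric: Z-allele label -> frequency (labels
#'   resolve against the bundle catalog or its extrapolated entries).
#' @param mitoPool named numeric: COIB label -> frequency.
#' @param hybridizationRate \code{NULL} for random mating (independent
#'   allele draws: interstrain heterozygosity arises at 2 pC pR), or a
#'   probability that a male's two Z alleles are drawn from different
#'   strain classes.
#' @param discordanceRate \code{NULL} for a mito pool independent of the Z
#'   (the Eastern Hemisphere situation), or the probability that a
#'   specimen's mitochondrion comes from the opposite strain class.
#' @param novelInjection list of \code{list(label =, copies =)}; injected
#'   specimens are forced female so the allele is directly resolvable.
#' @param errorRate per-base substitution probability on emitted sequences.
#' @param intronIndelRate probability that a resolvable specimen's intron
#'   carries a small deletion (indel stress switch; never applied to
#'   heterozygotes so superposition stays site-wise).
#' @param hostChoiceProb named numeric, probability a specimen of each
#'   strain class is collected from a C-strain host.
#' @param seed default RNG seed for the scenario.
#' @return validated config list of class \code{scenario_config}.
#' @export
scenarioConfig <- function(collections, zAllelePool, mitoPool,
                           hybridizationRate = NULL, discordanceRate = NULL,
                           novelInjection = list(), errorRate = 0,
                           intronIndelRate = 0,
                           hostChoiceProb = c(C = 0.98, R = 0.28, H = 0.63),
                           seed = 1L) {
  stopifnot(all(c("country", "site", "year", "n") %in% names(collections)))
  if (any(collections$n < 1)) stop("collection n must be >= 1")
  if (!"sex_ratio" %in% names(collections)) collections$sex_ratio <- 0.5
  if (!"method" %in% names(collections)) collections$method <- "larva"
  for (pool in list(zAllelePool, mitoPool))
    if (abs(sum(pool) - 1) > 1e-9)
      stop("pool frequencies must sum to 1", call. = FALSE)
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0,1)")
  structure(list(collections = collections, zAllelePool = zAllelePool,
                 mitoPool = mitoPool, hybridizationRate = hybridizationRate,
                 discordanceRate = discordanceRate,
                 novelInjection = novelInjection, errorRate = errorRate,
                 intronIndelRate = intronIndelRate,
                 hostChoiceProb = hostChoiceProb, seed = seed),
            class = "scenario_config")
}

# full emitted amplicon strings per allele label (frame with the catalog
# window substituted), plus COIB reads per mito label
.allele_reads <- function(bundle) {
  cw <- catalogWindow(bundle)
  frame <- as.character(bundle@frames[["TpiGenomic"]])
  alleles <- c(as.character(bundle@catalog),
               stats::setNames(as.character(bundle@extrapolated),
                               names(bundle@extrapolated)))
  names(alleles) <- c(names(bundle@catalog), names(bundle@extrapolated))
  reads <- vapply(alleles, function(s)
    paste0(substring(frame, 1, cw[1] - 1L), s,
           substring(frame, cw[2] + 1L, nchar(frame))), "")
  reads
}

.mito_reads <- function(bundle) {
  region <- ampliconRegion(bundle, "COI")
  frame_chars <- strsplit(as.character(bundle@frames[["COI"]]), "")[[1]]
  defs <- haplotypeDefs(bundle, "COIB")
  st <- siteTable(bundle, "COI")
  out <- character(0)
  for (lab in unique(defs$label)) {
    h <- defs[defs$label == lab, ]
    chars <- frame_chars
    for (r in seq_len(nrow(h)))
      chars[st$position[st$site_id == h$site_id[r]]] <- h$base[r]
    out[lab] <- paste(chars[region["start"]:region["end"]], collapse = "")
  }
  out
}

# apply substitution errors to an emitted read; returns the read and the
# indices that changed
.apply_errors <- function(read, errorRate) {
  if (errorRate == 0) return(list(read = read, changed = integer(0)))
  chars <- strsplit(read, "")[[1]]
  hit <- which(stats::runif(length(chars)) < errorRate)
  for (i in hit) {
    plain <- c("A", "C", "G", "T")
    chars[i] <- if (chars[i] %in% plain)
      sample(setdiff(plain, chars[i]), 1L) else sample(plain, 1L)
  }
  list(read = paste(chars, collapse = ""), changed = hit)
}

#' Generate a synthetic cohort
#'
#' All randomness flows from a single seed. The returned [SyntheticCohort]
#' carries the emitted sequences/metadata (a [SpecimenSet]) and a
#' ground-truth ledger. Metadata \code{sex} is \code{unknown} for larval
#' collections (true sex lives in the ledger), \code{male} for pheromone
#' traps, matching what a field study can actually record.
#'
#' @param config a [scenarioConfig()].
#' @param bundle a [MarkerBundle].
#' @param seed overrides the scenario's default seed.
#' @return a [SyntheticCohort].
#' @export
generateCohort <- function(config, bundle, seed = config$seed) {
  set.seed(seed)
  tpi_reads <- .allele_reads(bundle)
  mito_reads <- .mito_reads(bundle)
  bad <- setdiff(names(config$zAllelePool), names(tpi_reads))
  if (length(bad))
    stop("unresolvable Z allele label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(names(config$mitoPool), names(mito_reads))
  if (length(bad))
    stop("unresolvable mito label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (inj in config$novelInjection)
    if (!inj$label %in% names(tpi_reads))
      stop("unresolvable injection label: ", inj$label, call. = FALSE)

  aclass <- .allele_strain_class(
    stats::setNames(as.character(c(bundle@catalog, bundle@extrapolated)),
                    c(names(bundle@catalog), names(bundle@extrapolated))),
    bundle)
  pool <- config$zAllelePool
  pool_class <- aclass[names(pool)]
  mito_strain <- ifelse(names(config$mitoPool) == "R_COIB", "R", "C")

  draw_allele <- function(class = NULL) {
    p <- pool
    if (!is.null(class)) {
      p <- p[pool_class == class]
      if (length(p) == 0) stop("no ", class, "-class alleles in pool")
    }
    sample(names(p), 1L, prob = p)
  }
  draw_mito <- function(zclass) {
    p <- config$mitoPool
    if (!is.null(config$discordanceRate) && zclass %in% c("C", "R")) {
      want <- if (stats::runif(1) < config$discordanceRate)
        setdiff(c("C", "R"), zclass) else zclass
      sub <- p[mito_strain == want]
      if (length(sub) > 0) p <- sub
    }
    sample(names(p), 1L, prob = p)
  }

  # diagnostic-site offsets within each emitted read, for error accounting
  st_coi <- siteTable(bundle, "COI")
  region <- ampliconRegion(bundle, "COI")
  coi_off <- st_coi$position - region["start"] + 1L
  tpi_off <- siteTable(bundle, "TpiGenomic")$position
  iw <- intronWindow(bundle)

  rows <- list(); n_all <- sum(config$collections$n)
  sp_i <- 0L
  for (ci in seq_len(nrow(config$collections))) {
    col <- config$collections[ci, ]
    for (k in seq_len(col$n)) {
      sp_i <- sp_i + 1L
      id <- sprintf("SP%04d", sp_i)
      trap <- col$method == "pheromone_trap"
      sex <- if (trap) "male" else
        if (stats::runif(1) < col$sex_ratio) "female" else "male"
      if (sex == "female") {
        a1 <- draw_allele(); a2 <- NA_character_
      } else if (is.null(config$hybridizationRate)) {
        a1 <- draw_allele(); a2 <- draw_allele()
      } else if (stats::runif(1) < config$hybridizationRate) {
        a1 <- draw_allele("C"); a2 <- draw_allele("R")
      } else {
        cls <- sample(c("C", "R"), 1L,
                      prob = vapply(c("C", "R"), function(cl)
                        sum(pool[pool_class == cl]), numeric(1)))
        a1 <- draw_allele(cls); a2 <- draw_allele(cls)
      }
      classes <- aclass[c(a1, a2)[!is.na(c(a1, a2))]]
      strain <- if (length(unique(classes)) > 1) "H" else unique(classes)
      mito <- draw_mito(if (strain == "H") "H" else strain)
      rows[[sp_i]] <- data.frame(
        specimen_id = id, country = col$country, site = col$site,
        year = col$year, method = col$method, sex = sex,
        allele_a = a1, allele_b = a2, strain_genotype = strain,
        mito_label = mito, injected = FALSE, stringsAsFactors = FALSE)
    }
  }
  led <- do.call(rbind, rows)

  # novel injections: forced-female single-allele carriers
  for (inj in config$novelInjection) {
    copies <- if (is.null(inj$copies)) 1L else inj$copies
    free <- which(!led$injected)
    pick <- sample(free, copies)
    led$sex[pick] <- "female"
    led$allele_a[pick] <- inj$label
    led$allele_b[pick] <- NA_character_
    led$strain_genotype[pick] <- aclass[[inj$label]]
    led$injected[pick] <- TRUE
  }

  # emit sequences
  tpi_out <- character(nrow(led)); coib_out <- character(nrow(led))
  diag_errs <- integer(nrow(led))
  indel_flag <- logical(nrow(led))
  for (i in seq_len(nrow(led))) {
    a1 <- led$allele_a[i]; a2 <- led$allele_b[i]
    tpi <- if (is.na(a2) || a1 == a2) tpi_reads[[a1]]
           else iupacUnionSeq(tpi_reads[[a1]], tpi_reads[[a2]])
    if (config$intronIndelRate > 0 && (is.na(a2) || a1 == a2) &&
        stats::runif(1) < config$intronIndelRate) {
      dlen <- sample(1:12, 1L)
      dstart <- sample(iw[1]:(iw[2] - dlen), 1L)
      tpi <- paste0(substring(tpi, 1, dstart - 1L),
                    substring(tpi, dstart + dlen, nchar(tpi)))
      indel_flag[i] <- TRUE
    }
    coib <- mito_reads[[led$mito_label[i]]]
    e1 <- .apply_errors(tpi, config$errorRate)
    e2 <- .apply_errors(coib, config$errorRate)
    # diagnostic-site error accounting only valid without indels
    diag_errs[i] <- if (indel_flag[i]) NA_integer_ else
      sum(e1$changed %in% tpi_off) + sum(e2$changed %in% coi_off)
    tpi_out[i] <- e1$read
    coib_out[i] <- e2$read
  }
  led$n_diag_errors <- diag_errs
  led$intron_indel <- indel_flag
  led$collection <- paste(led$country, led$year, sep = "|")

  host_p <- config$hostChoiceProb[led$strain_genotype]
  led$host_class_true <- ifelse(stats::runif(nrow(led)) < host_p,
                                "C_host", "R_host")

  meta <- data.frame(
    specimen_id = led$specimen_id, country = led$country, site = led$site,
    year = led$year, month = NA_integer_, host_plant = NA_character_,
    host_class = ifelse(led$method == "larva", led$host_class_true, "unknown"),
    sex = ifelse(led$method == "pheromone_trap", "male", "unknown"),
    method = led$method, stringsAsFactors = FALSE)

  specimens <- SpecimenSet(meta, list(
    COIB = stats::setNames(coib_out, led$specimen_id),
    Tpi = stats::setNames(tpi_out, led$specimen_id)))
  new("SyntheticCohort", specimens = specimens, ledger = led,
      config = c(unclass(config), list(seed_used = seed)))
}

#' Ground-truth tallies from a cohort ledger
#'
#' @param cohort a [SyntheticCohort].
#' @return list of truth tallies: strain genotypes, mito labels, and
#'   chromosome-level Z-allele counts.
#' @export
cohortTruthTallies <- function(cohort) {
  led <- cohort@ledger
  alleles <- c(led$allele_a, led$allele_b)
  list(strain = table(led$strain_genotype),
       mito = table(led$mito_label),
       z_alleles = table(alleles[!is.na(alleles)]),
       n = nrow(led))
}

#' Write a cohort to disk (FASTA + metadata TSV + ledger JSON)
#'
#' @param cohort a [SyntheticCohort].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "specimens.fasta"),
             meta = file.path(dir, "metadata.tsv"),
             ledger = file.path(dir, "ledger.json"))
  con <- file(paths["fasta"], "w")
  for (mk in names(cohort@specimens@sequences)) {
    ss <- cohort@specimens@sequences[[mk]]
    for (id in names(ss))
      writeLines(c(paste0(">", id, "|", mk), as.character(ss[[id]])), con)
  }
  close(con)
  utils::write.table(cohort@specimens@metadata, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort@ledger, paths["ledger"], dataframe = "rows",
                       na = "null")
  invisible(paths)
}

#' Packaged scenario configurations
#'
#' \describe{
#'   \item{africa2016}{584 specimens over 16 country collections
#'     (2016-2017), the seven-haplotype continental background
#'     (AfrCa1a-c, AfrCa2a-c, AfrRa1), R_COIB-dominated mitochondria with
#'     the minority C_COIB almost entirely CSh4, no sequencing error.}
#'   \item{vogan2018}{221 specimens (Togo/Ghana/Benin 2018 axis) on the
#'     same background with the four post-2017 variants (AfrCa1d/e/f,
#'     AfrRa2) spiked in single copy.}
#'   \item{africa2019}{176 specimens, background pool, 2019 collections.}
#'   \item{hybrid_stress}{all-male trap collection with forced interstrain
#'     pairing (every male heterozygous C/R).}
#'   \item{discordant_mito}{R_COI/C_Tpi configuration dominant, emulating
#'     the Eastern Hemisphere marker discordance.}
#' }
#'
#' @return named list of \code{scenario_config}.
#' @export
packagedScenarios <- function() {
  background <- c(AfrCa1a = 0.64, AfrCa2a = 0.18, AfrCa1b = 0.05,
                  AfrCa1c = 0.02, AfrCa2b = 0.02, AfrCa2c = 0.03,
                  AfrRa1 = 0.06)
  mito_africa <- c(R_COIB = 0.70, CSh4 = 0.297, CSh2 = 0.003)
  countries16 <- c("Benin", "Burundi", "CaboVerde", "CAR", "Chad", "DRCs",
                   "DRCn", "Ethiopia", "Ghana", "Kenya", "Nigeria", "SaoTome",
                   "SouthAfrica", "Tanzania", "Togo", "Zambia")
  col16 <- data.frame(country = countries16, site = "Multiple",
                      year = rep(c(2016L, 2017L), 8),
                      n = rep(c(37L, 36L), each = 8))
  list(
    africa2016 = scenarioConfig(col16, background, mito_africa, seed = 11L),
    vogan2018 = scenarioConfig(
      data.frame(country = c("Togo", "Ghana", "Benin"),
                 site = c("Vogan", "Ejura", "Houegbo"),
                 year = 2018L, n = c(75L, 81L, 65L)),
      background, mito_africa,
      novelInjection = list(list(label = "AfrCa1d", copies = 1L),
                            list(label = "AfrCa1e", copies = 1L),
                            list(label = "AfrCa1f", copies = 1L),
                            list(label = "AfrRa2", copies = 1L)),
      seed = 18L),
    africa2019 = scenarioConfig(
      data.frame(country = c("Togo", "Senegal", "SouthAfrica", "Tanzania"),
                 site = "Multiple", year = 2019L, n = c(50L, 42L, 44L, 40L)),
      background, mito_africa, seed = 19L),
    hybrid_stress = scenarioConfig(
      data.frame(country = "SouthAfrica", site = "Multiple", year = 2019L,
                 n = 60L, method = "pheromone_trap"),
      background, mito_africa, hybridizationRate = 1, seed = 23L),
    discordant_mito = scenarioConfig(
      data.frame(country = "India", site = "Karnathaka", year = 2018L,
                 n = 80L),
      background, mito_africa, discordanceRate = 0.85, seed = 29L))
}

#' Simulate a strain-labeled Western Hemisphere reference panel
#'
#' Generates TpiI4a200 reference sequences for phylogenetic strain
#' assignment: C-strain references scatter around the C intron backbone
#' with WH-consensus C exon states (gTpi192Y/gTpi198Y polymorphic within
#' strain), R-strain references scatter around the divergent R intron
#' backbone with WH-consensus R exon states. Emulates the two-clade
#' structure of field reference sets; it is synthetic data, not the
#' GenBank reference sequences.
#'
#' @param nC,nR number of C- and R-strain references.
#' @param bundle a [MarkerBundle].
#' @param seed RNG seed.
#' @param meanSubs mean number of private substitutions per reference.
#' @return list: \code{seqs} named character (catalog-window coordinates),
#'   \code{labels} named strain vector.
#' @export
simulateReferencePanel <- function(nC = 20L, nR = 20L, bundle, seed = 1L,
                                   meanSubs = 3) {
  set.seed(seed)
  cw <- catalogWindow(bundle)
  iw <- intronWindow(bundle)
  st <- siteTable(bundle, "TpiGenomic")
  frame_chars <- strsplit(as.character(bundle@frames[["TpiGenomic"]]), "")[[1]]
  exon <- frame_chars[cw[1]:(iw[1] - 1L)]
  intron_c <- strsplit(.intron_from_window_seq(
    as.character(bundle@catalog[["AfrCa1a"]]), bundle), "")[[1]]
  intron_r <- strsplit(.intron_from_window_seq(
    as.character(bundle@catalog[["AfrRa1"]]), bundle), "")[[1]]
  flip <- c(A = "G", G = "A", C = "T", T = "C")
  site_at <- function(exon, sid, base) {
    exon[st$position[st$site_id == sid] - cw[1] + 1L] <- base
    exon
  }
  make <- function(strain, idx) {
    ex <- exon
    if (strain == "C") {
      for (s in c("gTpi165Y", "gTpi168Y", "gTpi183Y")) ex <- site_at(ex, s, "C")
    } else {
      for (s in c("gTpi165Y", "gTpi168Y", "gTpi183Y")) ex <- site_at(ex, s, "T")
    }
    # strain-nonspecific within-strain polymorphism
    ex <- site_at(ex, "gTpi192Y", sample(c("C", "T"), 1))
    ex <- site_at(ex, "gTpi198Y", sample(c("C", "T"), 1))
    intr <- if (strain == "C") intron_c else intron_r
    k <- stats::rpois(1, meanSubs)
    if (k > 0) {
      at <- sample(seq_along(intr), min(k, length(intr)))
      intr[at] <- flip[intr[at]]
    }
    paste(c(ex, intr), collapse = "")
  }
  seqs <- c(
    stats::setNames(vapply(seq_len(nC), function(i) make("C", i), ""),
                    sprintf("WH_C_%02d", seq_len(nC))),
    stats::setNames(vapply(seq_len(nR), function(i) make("R", i), ""),
                    sprintf("WH_R_%02d", seq_len(nR))))
  labels <- c(rep("C", nC), rep("R", nR))
  names(labels) <- names(seqs)
  list(seqs = seqs, labels = labels)
}
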