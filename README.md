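# fawtype

Strain typing of fall armyworm (*Spodoptera frugiperda*) from directly
sequenced mitochondrial **COIB** and Z-linked **Tpi** amplicons.

Fall armyworm comprises two morphologically identical host strains — the
C strain infesting corn and sorghum, and the R strain associated with
pasture grasses, millet, alfalfa and rice — that only molecular markers can
separate. This package is for entomologists and molecular ecologists
monitoring invasive populations: it turns raw amplicon sequences plus
collection metadata into strain calls, hybrid detections, intron haplotype
censuses and collection-level population profiles, and ships a synthetic
cohort generator so the full pipeline is testable without any specimen
data.

## The markers and the rules

* **COIB** (mitochondrial, haploid): `mCOI1164D` ∈ {A,G,T} and
  `mCOI1287R` ∈ {A,G}. `T_1164 A_1287` → `R_COIB`; the four A/G
  combinations → `CSh1`–`CSh4`. Ambiguity codes here mean mixed template,
  never heterozygosity.
* **TpiE4** (Z-linked): `gTpi183Y` is the strain diagnostic — `T` = R
  strain, `C` = C strain. Males are ZZ: a C/T double peak (IUPAC `Y`) in a
  directly sequenced male marks an interstrain hybrid (`H_TpiE4`). Females
  are ZW (hemizygous): a double peak in a female is impossible and is
  flagged as an artifact.
* **TpiI4a200** (the leading ~200 bp of *Tpi* intron 4): an exact-match
  haplotype catalog (AfrCa1a–f, AfrCa2a–c, AfrRa1–2) with
  singleton-verification for novel variants, used for phylogenetic strain
  assignment (neighbor joining on JC69 distances, 100 bootstrap
  replicates, midpoint rooting) and introduction monitoring.

A heterozygous male's direct read is the site-wise IUPAC union of his two
alleles. `deconvolveHeterozygote()` inverts that union against the allele
catalog: exact catalog pairs first, otherwise site-wise inference of the
unknown partner ({p : union(a, p) = observed}) — the mechanism by which
the third African R allele (AfrRa3) was characterized from hybrids alone.

## Worked example

Generate a pheromone-trap cohort with forced interstrain hybridization and
run the full pipeline:

```r
library(fawtype)
bundle <- defaultBundle()
cohort <- generateCohort(packagedScenarios()$hybrid_stress, bundle)
res    <- runPipeline(cohort@specimens, bundle)

res$summary$tpi_strain
#> $H
#> [1] 60
res$summary$coib
#> $CSh4
#> [1] 24
#> $R_COIB
#> [1] 36
res$carrier[c("n_total", "n_carriers", "pct_carriers")]
#> $n_total
#> [1] 60
#> $n_carriers
#> [1] 60
#> $pct_carriers
#> [1] 100
```

Every one of the 60 trap males is called an interstrain hybrid (the
scenario forces one C and one R allele per male), so all 60 carry an
R_TpiE4 Z-chromosome; the mitochondrial haplotypes split 36 `R_COIB` /
24 `CSh4` independently of the Z, illustrating why COI is an unreliable
strain marker once strains hybridize. The IUPAC arithmetic underneath:

```r
iupacUnionSeq("ACGTC", "ACTTC")
#> [1] "ACKTC"

dec <- deconvolveHeterozygote(
  iupacUnionSeq(as.character(alleleCatalog(bundle)[["AfrRa1"]]),
                as.character(alleleCatalog(bundle)[["AfrCa1a"]])),
  alleleCatalog(bundle))
dec$candidates[[1]][c("labelA", "labelB", "consistency")]
#> $labelA
#> [1] "AfrCa1a"
#> $labelB
#> [1] "AfrRa1"
#> $consistency
#> [1] "exact"
```

A shell wrapper (`inst/cli/straintype.R`) exposes `simulate` and
`run-all` subcommands over the same functions.

Note: the packaged reference frames and allele catalog are deterministic
synthetic stand-ins that reproduce the documented marker relationships;
swap in GenBank-derived FASTA/TSV files in the bundle directory to type
real specimens (see the vignette).

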