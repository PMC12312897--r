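---
title: "Strain typing fall armyworm from COI and Tpi marker sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain typing fall armyworm from COI and Tpi marker sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawtype)
```

## The biology behind the pipeline

Fall armyworm (*Spodoptera frugiperda*) comprises two morphologically
identical host strains: the C strain, dominant in corn and sorghum, and the
R strain, associated with pasture grasses, millet, alfalfa and rice. Only
molecular markers separate them. Two markers have been validated against
host-plant use in both American continents:

* **COIB** — an ~500 bp mitochondrial *COI* segment downstream of the
  barcoding region. Two sites define the haplotypes: `mCOI1164D`
  (A/G/T) and `mCOI1287R` (A/G). `T` at 1164 with `A` at 1287 is the
  R-strain haplotype (`R_COIB`); the four A/G combinations define the
  C-strain haplotypes CSh1–CSh4, whose relative frequencies distinguish
  regional "FL-type" from "TX-type" populations.
* **TpiE4 / TpiI4a200** — the fourth exon of the Z-linked
  *Triosephosphate isomerase* gene plus the leading ~200 bp of the fourth
  intron. `gTpi183Y` is the strain diagnostic: `T` = R strain, `C` = C
  strain. Because *Tpi* is Z-linked, females (ZW) are hemizygous and males
  (ZZ) diploid: a C/T double peak at gTpi183Y in a directly sequenced male
  is an interstrain hybrid (`H_TpiE4`), and a double peak in a female is
  physically impossible — the pipeline flags it as an error signal.

Direct Sanger sequencing of an unclosed PCR product superposes the two
allele signals of a diploid template. The package models chromatograms at
the text level: a double peak is an IUPAC ambiguity code, the superposition
of two alleles is the site-wise IUPAC union, and heterozygote deconvolution
inverts that union against a catalog of known alleles.

## The reference bundle

All marker definitions live in a data bundle (`defaultBundle()`), never in
code: reference frames, the ten diagnostic sites, COIB and TpiE4 haplotype
definitions, the eleven African TpiI4a200 alleles (AfrCa1a–f, AfrCa2a–c,
AfrRa1, AfrRa2), the extrapolated AfrRa3, and primer metadata. Two
documented coordinate conventions deserve attention:

* Site numerals are frame coordinates (`mCOI1164D` sits at COI position
  1164; `gTpi183Y` at Tpi-frame position 183).
* The published *Tpi* primer numerals (t412F/t1140R) refer to full-gene
  coordinates. The packaged Tpi frame is the amplicon renumbered from 1,
  and a per-frame `gene_offset` (411) reconciles primer numerals with
  frame anchors. The two numbering systems are historical and genuinely
  different; the bundle records the choice in `frames.tsv`.

The packaged reference sequences are deterministic synthetic stand-ins,
not GenBank records: they reproduce every relationship the marker
literature states (exon site states per haplotype group, AfrCa1d/e/f
clustering near AfrCa1a, AfrRa1/AfrRa2 as divergent singletons inside the
R clade, AfrRa3 matching the Western Hemisphere R consensus at the strain
sites) while being generated from a fixed seed. Analyses of real specimens
should replace `catalog_*.fasta` and `frames.fasta` with sequences derived
from the public accessions; everything downstream is data-driven, so that
substitution requires no code change.

## Anchoring and site calling

`anchorSequence()` orients a read by the best primer match (tolerance 2
mismatches, configurable) on either strand, then maps it onto the frame.
An ungapped mapping is accepted when its identity reaches 80%
(configurable); otherwise a global-in-query/local-in-reference
Needleman–Wunsch alignment (match 1, mismatch −1, gap −2) builds the
coordinate map, which handles the frequent intron indels. Insertions
relative to the frame are retained but never position-numbered: diagnostic
sites are reference positions, while intron haplotype strings keep their
length differences. Primer-covered positions are trimmed by default
(configurable), since whether the study trimmed primers is unstated.
Anchoring below 80% identity fails loudly with the best score.

## Typing rules and their edge cases

* **COIB** is haploid: ambiguity at either diagnostic site can only be
  mixed template or sequencing artifact, so it yields `unclassified`
  with an `ambiguous_site` flag, never a heterozygote.
* `T_1164 G_1287`, unobserved in the field surveys, classifies as
  `R_COIB` under the T-at-1164 rule but carries an `atypical` flag: the
  rule extension is explicit, not silent. Bases outside the empirically
  observed alphabets give `unclassified` + `unexpected_base`.
* **Tpi** strain calls follow gTpi183Y alone; conflicting states at the
  secondary strain-associated sites add a `discordant_sites` flag but
  never override (AfrRa1 legitimately carries a C-state at gTpi165Y, so
  only gTpi168Y participates in the conflict check).
* Heterozygosity in a specimen of unknown sex (larval collections) is
  treated as male — two signals require two Z chromosomes — and flagged
  `sex_assumed_male_for_het`. An unambiguous Tpi read from an unsexed
  specimen gets zygosity `unknown`: a homozygous male and a hemizygous
  female are indistinguishable there.

## Deconvolution: how AfrRa3 falls out of the arithmetic

For a heterozygous male, `deconvolveHeterozygote()` first enumerates all
unordered catalog pairs whose site-wise union equals the observation
(Phase 1). If none fits, each catalog allele is assumed to be one of the
two Z's and the partner is inferred site-wise as the base set
$\{p : \mathrm{union}(a, p) = \mathrm{observed}\}$ (Phase 2). That set is
empty when the allele is inconsistent, a singleton at every informative
position, and unconstrained only where the observation is missing/N
(completions are capped at 8 and flagged). A deliberate convention makes
this work site-wise: subtracting an unambiguous call from itself keeps the
shared base — a homozygous site. Phase-2 inference is exactly the
mechanism by which the third African R allele (AfrRa3) was characterized:
it exists in the data only as superpositions with C alleles, and
leave-one-out tests verify that any withheld catalog allele is
reconstructed base-for-base from its unions.

The literal set-subtraction alternative at observed two-base codes can
propose partners whose superposition does not reproduce the observation;
the union-inverse formulation guarantees the soundness invariant that
every returned pair superposes back to the observed sequence.

## Intron cataloguing and the singleton policy

`TpiI4a200` matching is exact string equality after uppercasing — the
study treats every repeat-confirmed variation as a distinct haplotype, so
mismatch-tolerant clustering is intentionally rejected. A novel haplotype
seen once is `provisional`; it becomes `confirmed` at support ≥ 2 (the
in-silico analog of re-amplification and re-sequencing of singletons) or
by an explicit confirmation flag. Provisional novels are excluded from
frequency profiles by default. Novel labels are deterministic 24-bit
hashes of the sequence, stable across runs and input orderings. The
intron window (frame positions 211–410, the first ~60% of intron 4) is a
packaged constant transcribed from the catalog alignment.

## Phylogenetic strain assignment

Trees are neighbor-joining on JC69 distances with pairwise deletion
(complete deletion would discard most columns of an indel-rich intron),
100-replicate column-bootstrap support and midpoint rooting. The original
analysis used an interactive ML package; NJ replaces it here because the
downstream quantity is clade membership of strain-labeled references
versus queries, which NJ recovers at these divergence levels, and because
it is fully specifiable and testable (additive matrices are recovered
exactly). `readExternalTree()` accepts a newick tree from any external ML
program when fidelity to that choice matters. Saturated pairs
(p ≥ 3/4) receive a configurable ceiling distance and a flag.
`assignStrainByClade()` walks each query rootward to the smallest clade
holding ≥ 2 references and assigns the strain only when those references
are unanimous.

## The synthetic cohort generator

`generateCohort()` is the oracle the whole test suite leans on. It encodes
the inheritance model: females draw one Z allele, males two; interstrain
heterozygosity arises either from independent draws (random mating, the
default: hybrid males appear at $2 p_C p_R$) or from an explicit
`hybridizationRate`; the mitochondrion is drawn independently or with a
configured strain-discordance probability (the Eastern Hemisphere
R_COI/C_Tpi configuration). Emitted Tpi sequences are the allele itself
(females, homozygotes) or the site-wise union of the two alleles
(heterozygous males). Sequencing error is substitution-only: each emitted
symbol is replaced with probability ε, so the chance a specimen acquires
at least one corrupted diagnostic-site call is exactly
$1-(1-\varepsilon)^{10}$ (ten covered diagnostic sites), which the suite
checks against binomial bounds. Intron indel stress is a separate switch
applied only to single-allele specimens so that superposition stays
site-wise. Metadata reports what a field study can record: sex `unknown`
for larval collections, `male` for pheromone traps (trap catches are
males); the ledger keeps the truth.

Packaged scenarios emulate the study structure: `africa2016` (584
specimens, 16 collections, the seven-haplotype continental background),
`vogan2018` (221 specimens with AfrCa1d/e/f and AfrRa2 spiked in single
copy), `africa2019` (176 specimens), plus `hybrid_stress` and
`discordant_mito`. The background Z-allele pool
(AfrCa1a .64, AfrCa2a .18, AfrCa1b .05, AfrCa1c .02, AfrCa2b .02,
AfrCa2c .03, AfrRa1 .06) is a package choice: the study's per-haplotype
frequency table is not reproduced here, so the pool was calibrated once to
the study-level summary statistics it reports — strong dominance of a
single AfrCa1 haplotype, an R-chromosome carrier rate near 10%,
homo/hemizygous R specimens near 3%, and year-over-year Pearson
correlations at these sample sizes of at least 0.99. The host-choice
probabilities (C strain on C hosts 0.98, R strain 0.28) mirror the
reference-set concordance figures.

What passing closed-loop tests show — and what they do not: at error rate
0 the pipeline recovers the ledger exactly, which validates the typing
logic, the coordinate arithmetic and the deconvolution. Real
chromatograms add base-call noise, primer degradation, heterozygote peak
imbalance and chimeric PCR products that the generator does not model;
field performance therefore depends on upstream base calling quality in a
way these tests cannot certify.

## Population profiling

Profiles count classified calls per collection; frequencies exclude
unclassified/unresolved calls and provisional novels. Carrier statistics
are reported both specimen-level ("carries at least one R_TpiE4 Z", the
headline rate) and chromosome-level (homozygote 2, heterozygote 1,
hemizygous female 1; unknown-zygosity R specimens count 1 with a flag),
because published counts use both denominators. Percentages are rounded
half-up with raw fractions alongside. The introduction-signal test is a
deliberate formalization of a narrative argument: haplotypes below 2%
baseline frequency form a "rare" class and a two-sided Fisher exact test
compares the focal collection's rare/other split against the baseline; the
output labels the test as a pipeline addition. FL/TX profile typing is
nearest-reference by total-variation distance with a 0.05 indeterminacy
margin.

## Numerical and scale choices

* All randomness funnels through one seed per generation/bootstrap call;
  reruns are byte-identical.
* Distance ceiling for saturated JC69 pairs: 5 substitutions/site.
* Negative NJ branch lengths are clamped to zero and counted.
* Alignment scores: match 1, mismatch −1, gap −2; the center-star
  alignment picks the longest sequence as center with lexicographic tie
  break, making it input-order invariant.
* The test suite and the worked examples run the full packaged scenarios
  (584/221/176 specimens); the complete suite takes under two minutes on
  one core.

## Known limitations

* Intron haplotypes are assigned only to resolved alleles (hemizygous or
  homozygous specimens and unique exact deconvolutions); heterozygotes
  needing a novel allele contribute strain calls but not intron census
  entries — the wet-lab analog (cloning and re-sequencing) is out of
  scope.
* The deconvolution is catalog-constrained: two novel alleles
  superposed on one another are reported `unexplained_heterozygote`.
* JC69 approximates the composite-likelihood distances of the original
  analysis; for the shallow divergences involved the clade structure is
  unaffected, and the newick-import hook exists for exact replication.
* The packaged reference data are synthetic stand-ins (see above); all
  quantitative statements in the README are computed on generated
  cohorts, not on the study's physical specimens.
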