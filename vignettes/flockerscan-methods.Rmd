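---
title: "Methods: calling candidate flocking bacteria from EET gene evidence"
author: "flockerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling candidate flocking bacteria from EET gene evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockerscan)
```

# The problem

Cable bacteria (*Ca.* Electronema, *Ca.* Electrothrix) conduct electrons
over centimetres through sediment. Motile bacteria have been observed
"flocking" around active filaments without touching them, a behaviour
hypothesised to reflect interspecies electron transfer: the flocker donates
respiratory electrons — most plausibly via diffusible electron shuttles such
as flavins or phenazines — and the cable bacterium carries them to oxygen.

A flocker candidate must therefore (i) be motile, (ii) possess, and
transcribe, the genetic machinery for extracellular electron transfer
(EET), and (iii) show an ecological link to the cable bacteria: either its
genus tracks cable-bacteria abundance in 16S rRNA time series, or its EET
genes are transcribed significantly more when cable bacteria are abundant.
`flockerscan` turns this argument into a reproducible, testable pipeline
over three input families: MAG gene-annotation tables, amplicon count
tables with seven-rank taxonomy, and per-gene transcript count matrices
contrasting low versus high cable-bacteria abundance.

# The EET catalog and the complex rule engine

The unit of EET capability is the porin-cytochrome complex (pcc): an
integral outer-membrane porin, a periplasmic cytochrome anchored inside the
porin, and an outer-surface cytochrome (omc), or a single protein spanning
the membrane (or, in Gram-positives, the cell wall). The default catalog
(`defaultCatalog()`, shipped as `inst/extdata/eet_catalog.yaml`) declares
32 pcc labels organised into 12 complex definitions from the model EET
organisms (*Shewanella* MtrCAB/MtrDEF/DmsAEF, *Rhodopseudomonas* PioAB,
*Sideroxydans* MtoAB and Cyc2, *Thermincola* CwcA and the TherJR system,
*Geobacter* ExtEFG/ExtBCD/OmabcB, and the *Enterococcus*-type
dmkA + ndh3 + eetB system), ten inner-membrane/periplasmic conduit labels,
16 electron-shuttle synthesis/export labels, and a 55-gene
flagellar-assembly set.

Design choices a user should know:

* **Excluded carriers.** `mtoD` and `pioC` are soluble periplasmic carriers,
  not parts of the membrane-bound porin complex. They are declared (so
  inventories can record them) but barred — by validation — from every
  complex definition and hybrid slot. A genome carrying only `mtoD` has no
  EET complex.
* **Three systems reading.** `dmkA`, `ndh3` and `eetB` are treated as one
  three-gene Gram-positive system, with `cwcA` and `cyc2` as single-gene
  complete-alone complexes. The grouping is configurable in the YAML, not
  hard-coded, because gene-to-system assignments in this family are still
  debated.
* **Hybrid complexes.** Cross-pathway "hybrid" pccs are considered
  functional whenever one porin-slot label, one anchor-slot label and one
  omc-slot label co-occur in a genome (mixed-origin EET pathways are known
  to function in Vibrio). The slot membership lists are catalog data:
  porins {mtrB, mtrE, pioB, mtoB, dmsF, extD, extG, omabcB}, anchors
  {mtrA, mtrD, pioA, mtoA, dmsA, dmsE, extC, extF, therJR_0333,
  therJR_1122}, omcs {mtrC, mtrF, omcA, omcS, omcZ, therJR_2595, extB,
  extE}. Within the Ext systems the structural omc is not unambiguous; the
  default places `extB`/`extE` in the omc slot and `extC`/`extF` in the
  anchor slot, and users can reassign them in the YAML. Triples identical
  to a canonical complex are reported as canonical completes, never as
  hybrids. A porin + omc pair without an annotated anchor is *not* accepted
  as a hybrid: all three slots must fill.
* **Qualitative presence.** Duplicate gene copies count once for
  completeness (copy number is reported); a complex counts as transcribed
  in a condition when at least one member gene is.
* **Motility.** A genome is called motile when it carries strictly more
  than 30 of the 55 flagellar-assembly genes. The 55-gene membership list
  shipped by default is a placeholder stand-in for the KEGG flagellar
  assembly module — all logic depends only on cardinality and membership,
  so users with a preferred ortholog set can substitute it. An explicit
  per-MAG override exists for incomplete genomes whose lineage is known to
  be motile; overrides are always recorded in the rationale.
* **Label normalisation** lower-cases and strips punctuation except the
  "/" of `fccA/3`, so annotation dialects (`TherJR_2595`, `therjr2595`)
  converge.

Correctness of the engine is guarded by an independent brute-force oracle:
for random inventories, hybrid assembly and completeness are re-derived by
naive triple enumeration and subset checks, and the two must agree exactly.

# The genus-level correlation screen

The screen asks which genera track the focal cable-bacteria genus over a
time series, on fractional abundances:

1. fractional abundance per sample;
2. pruning of taxa unclassified at genus rank *before* agglomeration (so
   unclassified reads never inflate a genus), then summing per genus;
3. prevalence filter: a genus is tested only if its fractional abundance
   exceeds 0.09% in more than three samples. "More than three" is read
   strictly (at least four); the filter is evaluated on the samples inside
   the day window being screened, so the tested family matches the tested
   samples (both choices configurable);
4. optional restriction to a growth-phase day window per series, because
   a blooming focal genus depresses all other relative abundances and
   induces spurious negative rank correlations over a full series;
5. Spearman correlation (average-rank ties) of each remaining genus
   against the focal genus, with exact permutation p-values for nine or
   fewer samples and the t approximation otherwise;
6. Benjamini-Hochberg adjustment (Holm available) across the tested
   genera; a genus passes when adjusted p < 0.05 and rho >= 0.6, positive
   correlations only.

Genera with zero rank variance inside the window have no defined
correlation; they are skipped with a diagnostic and excluded from the
adjustment family rather than being assigned a fake p-value. The screen is
invariant to per-sample scaling of counts (it sees only fractions and
ranks), and its familywise false-positive behaviour under the adjustment is
checked by simulation in the test suite.

# The expression layer

RPKM (`counts * 1e9 / (length_bp * library_size)`) is the descriptive
unit; per-MAG sums of pcc-gene or shuttle-gene RPKM, averaged within the
low/high condition, rank the top transcribing genomes (top 5 by default,
remainder pooled, ties broken by MAG id).

The inferential unit is a deliberately simple negative-binomial contrast of
high (days 26/33) versus low (day 3) cable-bacteria abundance — two
conditions, day kept as metadata only:

* **Normalisation** by median-of-ratios size factors (median over
  all-positive genes of the ratio to the geometric-mean reference sample,
  rescaled to geometric mean one; upper-quartile fallback with a warning
  if no gene is positive everywhere).
* **Dispersion** per gene by the corrected method-of-moments estimator
  computed around each condition's own mean,
  `(s2 - m) / (m^2 - s2/n)`, pooled across conditions by degrees of
  freedom. The naive `(s2 - m)/m^2` form is biased low at two-to-four
  replicates (sample mean and variance are positively correlated for
  overdispersed counts) and, computed around a common mean, biased high
  for genuinely changed genes; both effects are large enough to distort
  calibration at this design size. Raw values are floored at 1e-8 and
  shrunk 50/50 toward a trend: the mean raw dispersion of the 50 genes
  nearest in mean normalised count.
* **Testing** by a Wald test on the NB GLM log fold change (log link,
  log-size-factor offsets, dispersion fixed at its shrunken estimate).
  When the GLM cannot be fit — typically a condition with all-zero
  counts — a delta-method Wald on continuity-corrected normalised group
  means substitutes. Genes with all-zero counts are excluded from the
  family; there is no independent filtering beyond that, for determinism.
  Benjamini-Hochberg adjustment; `significant_high` means adjusted
  p below alpha *and* positive log fold change.

This is not a re-implementation of any published differential-expression
package; it reproduces the inferential structure (NB counts, shared
dispersion information, Wald + FDR) with arithmetic that can be checked by
hand, and the test suite cross-checks its fold changes and calls against an
established NB package on a planted fixture.

# Evidence integration

Per MAG, the classifier combines four booleans into nested tiers:

| tier | predicate |
|------|-----------|
| `CANDIDATE` | motile AND (>= 1 complete complex OR >= 1 hybrid) |
| `ACTIVE_CANDIDATE` | `CANDIDATE` AND >= 1 member gene of a complete complex or hybrid transcribed in either condition |
| `SUPPORTED_CANDIDATE` | `ACTIVE_CANDIDATE` AND (correlation pass OR DE evidence) |

The support criterion's "or" is kept verbatim: a genus-level correlation
match *or* at least one catalog EET gene (pcc member, conduit or shuttle
gene) significantly more transcribed during high cable-bacteria abundance.
Tiers rather than a single binary are exposed because "actively flocking"
is an interpretation — operationalised here as pcc transcription — and
because the two support arms carry different kinds of evidence. The policy
is monotone: adding evidence can only raise a tier, which the tests verify
field by field.

Genus matching between genome taxonomy and amplicon taxonomy is exact
string match at genus rank, case-insensitive, with an optional
user-supplied synonym map; the two reference taxonomies genuinely differ
and silent fuzzy matching would manufacture support. Missing screen or DE
inputs disable the corresponding arm with a "no data" note instead of
failing. Every call carries a rationale listing each fired and failed rule.
The MexGHI-OpmD pump is reported as a capability flag but never counts
toward candidacy, since it is not specific to shuttle excretion.

# The synthetic-data generator

The generator produces all three input families under one seed with known
ground truth, so every stage and the end-to-end classifier can be tested
without external data.

**Community** (`simulateCommunity()`): sixteen samples over nine time
points of a 76-day series, duplicates at most time points; the focal genus
follows a logistic bloom to a peak fraction of 0.55 around days 26-33 and
then declines slowly; library sizes are drawn log-uniformly over
3,909-132,888 reads; counts are Dirichlet-multinomial. Five planted
correlated genera receive expected fraction `b * (1 + strength * f)` with
strength 0.8 and baselines 2-5%, imposed *directly* on their expected
fractions — only the background pool absorbs compositional closure — so
the planted monotone signal survives renormalisation (with closure applied
to every taxon, the bloom's `(1 - f)` factor would invert it). Forty-five
background genera fluctuate independently (log-normal, sd 0.3). The
Dirichlet concentration defaults to 5000: the generator models replicate
cores of a homogenised, low-diversity laboratory enrichment, which behave
like near-technical replicates, and the planted association — bounded by a
1.44-fold multiplier — is only rank-detectable over sixteen samples under
modest overdispersion. `concentration = Inf` switches to deterministic
expected counts, in which the strength-1 association yields rho exactly 1.

**Genomes** (`simulateGenomes()`): thirty MAGs drawn from archetypes —
complete-pcc transcriber, hybrid-only, partial (one required gene
missing), shuttle-only, conduit-only, empty — crossed with motile
(40/55 flagellar genes) and non-motile (10/55). Each archetype satisfies
its defining predicate and violates all stronger ones, verified against
the rule engine in the tests rather than assumed. Among motile complete
transcribers, two are designated DE-supported and one
correlation-supported (its genus is drawn from the community's correlated
pool); these are the ground-truth supported candidates.

**Transcripts** (`simulateTranscripts()`): negative-binomial counts with
log-normal baselines (mean 100), dispersion 0.2, per-sample library
factors 0.5-2x, two low-condition and four high-condition samples; the
designated flockers' EET genes carry an 8-fold increase in the high
condition. Genes a profile marks untranscribed in a condition are zero
there. `dispersion = 0` with unit library factors gives deterministic
counts for the noise-free configuration.

What the generator does **not** emulate: real taxonomic structure and
shared lineages, ecological interactions among non-focal genera,
sequencing error and chimeras, rRNA carry-over in transcriptomes,
fragmented or unbinned transcripts, and genome incompleteness biases in
gene inventories. Passing tests therefore demonstrate that the pipeline's
logic and statistics behave as specified under their own model — not that
the biological conclusions would transfer to any particular real data set.

# Numerical choices and problem sizes

Deterministic ordering everywhere: complexes by name, hybrids by
porin/anchor/omc, expression ranks tie-broken by MAG id. Dispersion floor
1e-8; continuity correction `0.5/mean(sf)` in the fallback Wald;
permutation p-values use a 1e-12 tolerance on rho comparisons. The test
and acceptance workloads use desk-scale sizes chosen so the full suite
runs in minutes: 1,000 random inventories for the engine oracle, 200
replicates for familywise screen calibration, 20 for recall, 2,000 genes
for DE calibration, and 20 seeded end-to-end replicates.

# Known limitations

* The rule engine trusts upstream ortholog labels; it performs no
  sequence-level verification, and annotation errors propagate.
* The hybrid rule is permissive by construction (any slot-compatible
  triple); it flags structural possibility, not demonstrated function.
* The DE stage's plug-in Wald test is mildly anticonservative at two
  low-condition replicates (null p < 0.05 fraction around 0.06 in the
  calibration tests); the shrunken dispersions keep it inside the
  documented band, but users wanting exact error control at this design
  size should treat borderline adjusted p-values with care.
* The screen tests association against the focal genus only; it is not a
  co-occurrence network, and correlation with a bloom can reflect shared
  environmental response rather than interaction.
* Calls are genomic/transcriptomic candidacy, not physiological
  verification.

# A worked run

```{r demo, eval = FALSE}
d <- simulateDemo(seed = 7)
res <- runPipeline(d$profiles, d$amplicon, d$counts,
                   focal = "Ca. Electronema")
table(res$calls$tier)
evaluateCalls(res$calls, d$truth$mags)
```
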