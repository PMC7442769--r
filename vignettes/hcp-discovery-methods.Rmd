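---
title: "Methods: HCP discovery by shared-peptide inference and full-scan peptide rescue"
author: "HCPprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HCP discovery by shared-peptide inference and full-scan peptide rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HCPprofiler)
```

## The problem

Biotherapeutic drug products made in mammalian cells (typically CHO) carry
trace amounts of host cell proteins (HCPs) — endogenous proteins that
survive downstream purification at the parts-per-million level relative to
the drug substance. Bottom-up LC-MS/MS can identify and relatively quantify
individual HCPs, but a conventional evaluation — proteins identified only
from fragment ion spectra of *unique* peptides — discards much of the
information present in the data: peptides matching more than one database
protein are ignored, and peptides that eluted but never triggered an MS/MS
event are invisible.

HCPprofiler implements an optimized data evaluation pipeline that recovers
both kinds of evidence:

1. **Shared-peptide protein inference.** Proteins are ranked by total
   peptide evidence; every shared peptide is assigned to the
   highest-ranking of its candidate proteins; peptide- and protein-level
   false discovery rates are controlled by a two-dimensional target-decoy
   strategy (1%, with a cap of 20 reverse hits at the protein level).
2. **In silico peptides.** For every peptide ion identified by MS/MS
   somewhere in a drug product, the remaining runs of that product are
   searched on the full-scan MS level for a matching chromatographic
   feature. A candidate becomes an "in silico peptide" — an identification
   without a fragment spectrum — if it passes three criteria detailed
   below.

Identifications are graded on an ordinal credibility scale, profiles are
aggregated from replicates to fractions to drug products, and profiles are
compared by Jaccard indices, including hierarchical clustering on the
Jaccard distance 1 − J.

## Data model

Inputs are deliberately tabular: a FASTA database (`ProteinDatabase`, a
thin S4 wrapper around `Biostrings::AAStringSet` carrying a category per
entry), per-run PSM tables, per-run MS1 feature tables with isotope
envelope intensities, and run metadata (drug product / fraction /
replicate). Raw spectra are out of scope: the method operates on
identified precursors and detected features, so nothing is lost by
starting from tables, and everything stays testable at desk scale.

The database distinguishes `host` entries (potential HCPs) from annotated
non-HCPs — the drug substance itself, spiked standard proteins, a
multi-peptide standard kept as a *single* entry, trypsin, protein A — and
keratin contaminants. A reference CHO setup (23,885 host sequences plus
these 6 additions) therefore has exactly 23,891 entries.

## FDR control and protein inference

Decoys are full-sequence reversals (`DECOY_` prefix). At the PSM level the
score threshold is the most permissive value `t` with
`#{decoys ≥ t} / #{targets ≥ t} ≤ q` (default q = 0.01). At the protein
level the ranked list is truncated at the last position where the
cumulative decoy/target ratio stays ≤ q *and* at most 20 decoys have been
accepted ("1% or 20 reverse count").

Protein ranking uses *total evidence*, operationalized as the sum over
distinct peptides of each peptide's best PSM score. This is a documented
simplification of the commercial probabilistic model whose observable
behaviour — rank by total evidence, assign each shared peptide to the
highest-ranking candidate, ties broken deterministically by accession —
is reproduced exactly. A protein enters the report if it has a unique
peptide of ≥ 5 residues or at least one shared peptide assigned to it.

A known limitation, visible in the package's own calibration study
(`simulatePsmScores()` + `psmFdrFilter()`): the uncorrected decoy/target
ratio is slightly anti-conservative on small datasets (realized FDP
≈ 1.1% at nominal 1% with ~2,000 true PSMs per dataset), converging to
nominal as datasets grow. The calibration tests therefore run at 40,000
true + 12,000 false + 12,000 decoy PSMs per dataset, where the realized
false-discovery proportion sits inside the binomial 95% band of 1% —
a size chosen once and verified across several disjoint seed sets.

## In silico peptide rescue

For each peptide ion (sequence, modifications, charge) with at least one
MS/MS identification in a drug product, `buildRtWindows()` spans the
retention-time window `[min RT, max RT]` of those identifications. In
every run of the same product lacking an MS/MS identification of that ion,
candidate features must satisfy:

1. **Retention time**: feature apex within the window widened by 0.5 min
   (30 s) on each edge (`feature_center_tolerance`), and peak width within
   0.1 min of the mean width of the MS/MS-matched features
   (`feature_duration_tolerance`). The width reference is the mean of the
   MS/MS-level detections — the symmetric choice where only "a change in
   peak width" is prescribed.
2. **Mass accuracy**: signed ppm deviation of the feature's neutral mass
   inside the empirical 2.5th–97.5th percentile band of the deviations of
   *all* precursor ions that had a fragment spectrum (after a coarse
   7 ppm gate; the m/z-closest candidate is taken when several qualify).
3. **Isotope pattern**: Pearson correlation between the observed envelope
   and the averagine-model envelope of the same residue count exceeding
   the 5th percentile of the correlations of all fragment-identified
   precursors. At least 3 aligned isotopologue peaks are required — the
   correlation over 2 points is ±1 by construction and carries no
   information — and at most 5 are compared.

Percentile references use linear interpolation between order statistics
and require at least 20 reference precursors; they are computed globally
over the processed dataset by default (the reference population reads
"all precursors with a fragment ion spectrum"), with a per-drug-product
mode available. Rejections record the first failed criterion
(`rt`, `mass_dev`, `correlation`, `low_information`). By construction,
~95% of the reference population passes each percentile filter when the
filters are applied back to it.

### The averagine model

Averagine is a model "average" residue with composition
C~4.9384~H~7.7583~N~1.3577~O~1.4773~S~0.0417~ and an average mass of about
111.125 Da; a peptide of *n* residues is modeled as *n* averagine units
(no water term — only the envelope *shape* is used, never its absolute
mass). Fractional element counts are rounded half-up before the
element-wise multinomial convolution over standard terrestrial isotope
abundances; the full distribution is computed, then truncated and
renormalized. The model is excellent for typical tryptic peptides (median
correlation with the true-composition envelope > 0.99 at natural
amino-acid frequencies) but degrades for sulfur-rich peptides — a peptide
with several Cys/Met residues can drop to r ≈ 0.8–0.94 because averagine
carries only 0.042 S per residue. This is a property of the model itself
and one reason the correlation threshold is set empirically from the
data's own reference population rather than at a fixed value.

## Profiles, tiers and quantification

Peptides that occur as substrings of any non-HCP sequence are stripped
from HCP evidence before anything else — they could arise from non-HCPs
via unspecific cleavage — and an HCP whose entire support disappears this
way is removed from the report. Keratins are recognized by database
category or a case-insensitive "keratin" in the entry description
(overridable by an explicit accession list; the recognition rule is a
package choice since only the filtering itself is prescribed).

Credibility tiers per protein: **4** ≥ 2 unique MS/MS peptides, **3**
exactly one unique MS/MS peptide, **2** only shared MS/MS peptides
(assigned), **1** in silico peptides only. The tier is the best evidence
class present; a "minimum tier L" query is cumulative, so profile size is
non-increasing in L. Profiles aggregate upward by union with max-tier
merge: a fraction holds every HCP seen in ≥ 1 replicate, a drug product
every HCP seen in ≥ 1 fraction.

Relative quantification follows the top-3 scheme: per replicate the mean
area of the up-to-3 most intense distinct peptides of a protein (feature
areas summed over charge states, since precursor ion current is
charge-agnostic), then the mean over replicates, then scaling to the
column (drug product × fraction) maximum so every value is a percent of
the column maximum. Cumulative keratin and HCP rows are summed before
scaling.

## Profile comparison

`jaccardIndex()` is |A∩B|/|A∪B| on accession sets; 1 − J is a metric.
`repeatability()` sweeps the minimum credibility tier and compares all
within-fraction replicate pairs (a 5-product × 2-fraction × 3-replicate
design gives exactly 30 comparisons per tier), summarized by median,
quartiles and 1.5·IQR whiskers. `clusterProfiles()` runs agglomerative
clustering on 1 − J; complete linkage is the default (the linkage is
configuration, not dogma — average and single are accepted), with the
Jaccard matrix exported in percent and the dendrogram as Newick.

Including lower-credibility identifications — in particular tier-1 in
silico peptides — raises replicate-to-replicate Jaccard indices: the
rescue stage fills in exactly the detections that stochastic MS/MS
sampling drops, so unions stabilize.

## The synthetic data generator

`simulateDatabase()` / `simulateRuns()` emulate the measurement structure
the pipeline targets, with full ground truth:

* random protein sequences at ~11% K/R frequency (tryptic peptides
  average 8–12 residues), host proteins plus the non-HCP cast (drug
  substance per product, trypsin, protein A, two standards, a
  six-peptide standard as one entry) and designated keratins;
* a configurable fraction of HCP pairs planted to share one tryptic
  peptide (shared-peptide inference is exercised, not assumed);
* one drug substance at intensity 10⁹ (arbitrary units) per product, HCP
  abundances 10²–10⁵-fold below it (log-uniform), drawn per product;
* per-peptide reproducible base retention times uniform over a 2–80 min
  gradient with N(0, 0.05 min) replicate jitter — the rescue algorithm
  needs repeatability, not a physical RT model, and the jitter is
  deliberately well inside the 0.5 min tolerance as in a well-behaved
  LC setup;
* every peptide of a present protein yields an MS1 feature; its m/z
  carries N(0, 2 ppm) centroid error, while PSM precursor m/z carries
  N(0, 3 ppm) — a single survey-scan readout is less precise than an
  elution-averaged feature centroid. One practical consequence: the
  percentile mass-deviation band, which is estimated from PSM-level
  deviations, is not the binding cut for true feature-level rescues;
* isotope envelopes are the averagine envelope of the residue count with
  5% multiplicative noise;
* MS/MS sampling is logistic in log10(area) (midpoint 10^4.5, scale 0.4
  decades), emulating abundance-dependent data-dependent acquisition,
  then thinned by a `missingness` probability per run — the knob that
  creates feature-only detections for rescue;
* true PSM scores are a gamma(4, 0.5) shifted by +25; false target PSMs
  and decoy PSMs draw from the unshifted null, in equal numbers (15% of
  true PSMs each by default), so decoy counting estimates the false
  proportion;
* "bait" features are planted > 20 ppm off every theoretical peptide ion
  of the same charge, inside real retention-time windows: rescue must
  never accept one.

What the generator does **not** emulate: chromatographic peak shapes, ion
suppression and co-elution physics (abundance effects enter only through
detection probabilities), modification localization, semi-tryptic
peptides, retention-time drift between runs (no alignment/warping is
implemented, matching the method's assumption of repeatable RTs), and
real CHO sequences. Passing tests therefore demonstrate the *logic* of
the evaluation protocol under its stated assumptions, not performance on
raw instrument data.

## Numerical choices and degenerate inputs

* Monoisotopic residue masses, water 18.010565 Da, proton 1.007276 Da;
  average atomic masses C 12.011, H 1.008, N 14.007, O 15.999, S 32.06
  (one averagine unit: 111.1250 Da).
* Cleavage rule: after K/R, not before P; missed cleavages configurable
  (default 2 in digestion; the generator uses fully cleaved peptides).
* Uniqueness is substring occurrence in full protein sequences (robust to
  missed cleavages); I/L are *not* equated.
* Ties in protein ranking and shared-peptide assignment break
  lexicographically by accession, making runs reproducible.
* Empty candidate sets, peptides mapping to no protein (warned and
  dropped), palindromic decoys (reported), fractions with a single
  replicate (skipped with a warning) and Jaccard comparisons of two empty
  sets (undefined; excluded with a warning, an error in clustering) are
  handled explicitly.
* Percentile filters error below 20 reference precursors rather than
  returning unstable bounds.

## Problem sizes used in the test suite

The packaged tests run desk-scale studies chosen once: FDR calibration on
20 datasets of 40k/12k/12k PSM scores; rescue recovery on a 50-HCP,
1-product, 3-replicate simulation at missingness 0.5; the repeatability
trend over 20 seeds of a 12-HCP, 2-fraction design; cluster recovery on
4 drug products in 2 planted classes (within-class J = 18/22, between
4/36); and the 5 × 2 × 3 design for the 30-comparison count. Headline
counts from any particular instrument study (numbers of HCPs in specific
commercial products, absolute Jaccard medians) depend on the underlying
raw data and are not reproduced here; the suite verifies the properties
of the procedure instead.

```{r quick-demo}
cfg <- simConfig(seed = 1, n_hcps = 10, n_drug_products = 1,
                 n_fractions_per_dp = 2, protein_length = 120,
                 missingness = 0.3, n_bait = 2)
simdb <- simulateDatabase(cfg)
sim <- simulateRuns(simdb$database, cfg)
res <- runHcpPipeline(simdb$database, sim$psms, sim$features, sim$meta)
res$psm_fdr
res$profiles$drug_product[[1]]
repeatability(res$profiles$replicate, min_tiers = c(1L, 4L))$summary
```
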