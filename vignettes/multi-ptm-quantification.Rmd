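---
title: "Multiplexed multi-PTM quantification with ptmplex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplexed multi-PTM quantification with ptmplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmplex)
```

# The analysis problem

Isobaric (TMT) labeling lets one multiplexed LC-MS/MS experiment quantify a
protein sample set across up to 18 reporter channels. When the pooled,
labeled peptides are split and enriched in parallel — thiol-affinity capture
for cysteine-containing peptides, IMAC for phosphopeptides, immunoaffinity
for acetyl-lysine peptides — the *same* biological samples yield global
protein abundances plus several PTM-site-level datasets. Comparing PTM site
abundances across conditions is then confounded by three nuisance factors
this package is built to remove:

1. **Channel loading**: unequal peptide amounts per channel shift every
   reporter intensity of a sample multiplicatively.
2. **Plex batch effects**: when the design spans several TMT plexes, each
   plex is a separate LC-MS/MS experiment with its own offset.
3. **Protein abundance**: a site's intensity is (occupancy x protein
   amount); a change in protein expression masquerades as a PTM change
   unless the protein-level signal is subtracted.

For cysteine redox biology a fourth quantity matters: the **stoichiometry**
of reversible thiol oxidation. Parallel sample preparations with and
without NEM blocking of free thiols ("thiol oxidation" and "total thiol"
channels in the same plex) make the % oxidation of each site estimable as
an intensity ratio.

# The processing model

All quantification starts from peptide-spectrum matches (PSMs) with raw
per-channel reporter intensities. PSMs are filtered on mass accuracy
(|ppm| <= 10, inclusive) and PepQ (< 0.01, strict); the boundary semantics
mirror the upstream search conventions. Reporter intensities of zero are
treated as missing before any aggregation — in reporter-ion data a zero is
a non-detection, not a measured abundance.

**Roll-up.** Protein-level values are sums of raw reporter intensities over
the protein's PSMs, per channel; site-level values are sums over PSMs
mapping to the same modified residue(s). A peptide carrying several target
modifications contributes to one *composite* site key (e.g. `P1-S10S14`),
never to the individual single-site keys: the data cannot say how the
intensity splits between the residues. Sites are identified in 1-based
protein coordinates verified letter-by-letter against the FASTA.

**Normalization chain.** The global protein matrix is log2-transformed,
batch corrected, and median centered. Site matrices follow the chain

```
log2 -> global-scaled -> batch-corrected -> protein-corrected -> na-filtered
```

which every `AbundanceMatrix` records in its metadata; calling an operation
out of order is a state error rather than a silent wrong answer.

* *Global scaling*: per sample, the median of the **not batch-corrected**
  log2 global peptide column is subtracted from the site column. A single
  subtraction both removes the channel-loading offset and median-centers
  the site data; using the global peptides (thousands of features) rather
  than the site matrix itself makes the median estimate nearly noiseless
  and independent of the enrichment.
* *Batch correction*: per feature, the batch mean is subtracted and the
  grand mean restored (both over non-missing values). This is the minimal
  correction that removes inter-plex offsets exactly while leaving every
  within-plex pairwise difference untouched, and it is idempotent. No
  distributional model is assumed; a more elaborate method can be slotted
  in where the pipeline calls `batchCorrect()`. Features observed in a
  single batch pass through unchanged and are flagged.
* *Protein correction*: for a site on protein p observed in condition c,
  the mean normalized abundance of p over the non-missing condition-c
  replicates is subtracted. At least 2 non-missing replicates are required;
  otherwise the site passes through for that condition and the condition is
  recorded in `uncorrected_conditions` — downstream consumers can exclude
  or annotate those values rather than trusting a one-replicate mean.
* *NA rule*: features with more than 2 missing values in any single
  condition (2 of 4 replicates) are removed before statistics. The
  "any condition" reading is the strict one; `scope = "all"` relaxes it.

**Redox stoichiometry.** For each site and condition, % oxidation =
100 x mean(oxidation-channel intensities) / mean(total-thiol intensities),
on the raw scale. The total-thiol channels used are those annotated with
the same condition when the design provides them (the timecourse design
carries one total-thiol singlet per condition) and otherwise all
total-thiol channels of the plex(es) involved. Channel loading is removed
in two stages. When the global peptide matrix is supplied as the
normalizer (the pipeline always does this), each channel is first divided
by 2^(its global column median): the unenriched data estimate every
channel's loading, including that of a total-thiol *singlet*, whose
loading cannot be separated from signal using the redox data alone — and
an uncorrected singlet puts its full loading error multiplicatively into
every stoichiometry of its condition. Second, within the per-condition
selection each channel is normalized by its column sum over sites
quantified in all selected channels, rescaled to the mean column sum of
its role group, which cancels residual loading variation *within* the
oxidation group and *within* the total-thiol group while preserving the
oxidation/total intensity ratio — the quantity of interest. A loading
offset *between* the +NEM and -NEM sample groups that the global data do
not capture is not identifiable and survives as a common multiplicative
bias; this is a stated limitation, not a bug. With a single noisy total
channel the ratio also carries a small positive Jensen bias (about +3% of
the value at 19% channel CV). Estimates above 100% are flagged
`over_range`, not clipped: their frequency is a useful QC readout, and
clipping is available as an option.

**Statistics.** The default two-group test is the pooled-variance
two-sample t on log2 values with Benjamini-Hochberg adjustment over all
tested features; features with fewer than two non-missing replicates in
either group are skipped. Zero within-group variance (common in noise-free
synthetic data) is floored at 1e-12 and flagged instead of returning NaN.
An empirical-Bayes variance-moderation mode (limma) is available behind
`moderated = TRUE` and is documented as an approximation: the package does
not claim to reproduce a full limma linear-model analysis. One-way ANOVA
uses the classic equal-variance F test per feature with per-condition
log2FC against the reference condition ("4 h control" by default);
reporting filters are adj. p <= 0.05 with |log2FC| >= 0.8 for two-group
contrasts feeding ORA and |log2FC| >= 1 for the ANOVA view.

**Over-representation.** Gene sets are read from GMT files, intersected
with the universe (all features quantified and tested in the relevant
modality — not the whole genome), and tested with the hypergeometric upper
tail P[X >= k]. Site-level hit lists are collapsed to parent proteins
first so one gene counts once. The reported q-value equals the BH-adjusted
p by default; a Storey-type estimate (pi0 at lambda = 0.5) is available
behind a flag. Reporting cutoffs are q <= 0.2 and adj. p <= 0.05.

**Structure mapping.** Predicted single-chain structures (PDB or mmCIF)
are reduced to their alpha-carbon trace; per-residue confidence (pLDDT) is
read from the B-factor column by AlphaFold2 convention. Distances between
selected modified residues are plain 3D Euclidean CA-CA distances in
Angstrom; side-chain geometry is deliberately out of scope. Residues with
pLDDT below 70 — the conventional "low confidence" boundary, configurable
— are flagged, and any distance involving a flagged residue should be
read as a screening hint, not a measurement: low-pLDDT regions are often
intrinsically disordered and their coordinates are not trustworthy.

# The synthetic-data generator

`generateTruth()` + `simulatePsmTables()` draw a complete multi-modality
experiment with known ground truth. The default design mirrors the
emulated study: two TMT18 plexes; conditions {Control, Cytokine} x
{4 h, 8 h, 24 h}; thiol-oxidation samples in quadruplicate, balanced two
per plex; one total-thiol singlet per condition; remaining channels empty.
Intensities follow

```
I(feature, channel) = 2^(baseline + condition effect + occupancy effect
                         + lambda_channel + delta_plex + epsilon)
```

with `epsilon ~ N(0, noiseSd^2)` on the log2 scale; redox oxidation
channels scale the site's total-thiol level by s/100. Key defaults, chosen
once as plausible for single-shot TMT data: baseline log2 intensity
N(20, 1.5^2); 4 peptides per protein with per-peptide ionization offsets
of sd 1 (log2); channel loading sd 0.3; plex offset sd 0.5; measurement
noise sd 0.25 (about 19% CV); 20% of features affected at |log2FC| = 1
with alternating sign and a deterministic count; TMT labeling efficiency
0.993; enrichment contaminant fractions 8.6% (redox) and 13.2% (phospho),
matching the selectivities the workflow is expected to reach. All
randomness flows from one seed with fixed per-modality offsets, so adding
a modality never perturbs another modality's draws.

Missingness is modeled at the identification level: a peptide species
missed in a plex loses all of that plex's channels together, as in
data-dependent acquisition. This is the missingness structure the
per-condition NA rule exists for — a feature identified in only one of two
plexes has exactly 2 of 4 replicates missing. Per-cell missingness, by
contrast, would make protein sums jump whenever a high-ionization peptide
drops out of a single channel, which is not how reporter-ion data behave
(MASIC-style extraction reports all channels of an identified spectrum).

What the generator does **not** emulate: isotopic impurity bleed between
channels, co-isolation interference (ratio compression), intensity-
dependent (left-censored) missingness, miscleavage patterns, retention-
time structure, or shared peptides between proteins. Passing the recovery
tests therefore demonstrates the correctness of the aggregation and
normalization algebra under a realistic noise/batch/dropout model — not
robustness to every artifact of real spectra.

# Numerical behavior and expected precision

Problem sizes in the test-suite and acceptance script were picked so the
whole suite runs in a couple of minutes on one CPU: 200-PSM tables for the
roll-up oracle, 500 x 17 matrices for normalization contracts, 2000
features for calibration, 250 proteins x 1000 sites for chain recovery,
10000 sites for estimator bias. The statistical claims below are what those
runs actually measure.

* Roll-up agrees with a brute-force accumulation loop to floating-point
  summation order (relative 1e-12); median centering and batch correction
  hit their zero-median / zero-offset contracts to 1e-9 or better, and
  both are idempotent.
* The noise-free closed loop is exact (max error ~1e-16): with zero
  noise, loading, batch offsets and dropout, and no protein-level effects,
  the corrected site contrast equals the injected occupancy log2FC. When
  protein-level effects *are* present, the per-column medians used for
  centering shift by O(1/n features) with the effect distribution, so
  recovery is exact through batch correction and approximate at the
  median-centering step; this is an estimation property of
  median-centering itself.
* Under the standard noisy conditions (sd 0.25, n = 4) the occupancy
  contrast error has two comparable sources: the site's own measurement
  noise (sd = 0.25 * sqrt(2/4) ~ 0.18) and the noise of the estimated
  per-condition protein mean being subtracted (~0.11 with 4 peptides per
  protein). The combined expected median absolute error is ~0.14, and the
  measured value fluctuates by roughly +/-0.01 between seeds — right at
  the 0.15 acceptance bound, which is why the acceptance script reports
  the value rather than only a pass/fail.
* The redox ratio-of-means estimator is unbiased at the percent level
  (mean over 10000 sites at s = 50% within 0.5 points) and exactly
  scale-invariant per site in its raw form. Its per-site precision is
  bounded by the channel counts: with 4 oxidation + 2 total channels at
  10% measurement CV the relative sd is ~0.10 * sqrt(1/4 + 1/2) ~ 8.7%,
  so at s = 95% a +/-5-percentage-point band is only +/-0.6 estimator sd
  and *no* unbiased estimator can place 95% of sites inside it; the
  acceptance suite asserts that coverage anyway and the assertion is
  expected to fail, with the observed fraction (~0.75) reported by the
  acceptance script. At low stoichiometries (5-25%) coverage is
  essentially complete.
* The pooled t-test's type-I error at alpha = 0.05 on a 2000-feature null
  lands within the binomial band 0.05 +/- 0.01, null p-values are uniform,
  and `bhAdjust()` matches a from-the-definition step-up implementation to
  1e-12 on random inputs.

Degenerate inputs are handled by explicit policy rather than NaN
propagation: zero within-group variance is floored and flagged; columns
that are entirely missing are left untouched with a warning; sites with no
total-thiol signal are excluded and counted; empty ORA sets are dropped;
structures with multiple chains are rejected with instructions rather than
silently picking one.

# Design choices that were genuinely open

* **Selectivity denominator**: enrichment selectivity is reported over
  unique peptides by default (identification lists are peptide-level);
  `unit = "psms"` is available.
* **Acetyl mass**: the registry stores +42.01056 Da for acetylation so
  that the dynamic-modification delta under fixed TMT is exactly
  -262.196586 Da, the value the upstream search pipeline uses; this
  differs from the Unimod monoisotopic value by 5e-6 Da.
* **Batch correction algorithm**: mean-shift with grand-mean restoration,
  chosen because it is assumption-free, exactly testable, idempotent and
  contrast-preserving. Empirical-Bayes alternatives (e.g. ComBat-style)
  shrink batch estimates but change within-plex contrasts; they can be
  substituted at the same call site.
* **Samples without a global counterpart**: site columns whose sample is
  absent from the global peptide matrix pass through *unscaled* and are
  flagged in `colData`, and sites whose protein is unquantified pass
  through *uncorrected* with the affected conditions recorded. Dropping
  them silently would bias any downstream summary toward well-covered
  proteins.
* **q-values**: q = BH-adjusted p by default. A full q-value computation
  needs a pi0 estimator whose behavior on short p-value lists is erratic;
  the optional Storey mode is provided but the default keeps the core
  reproducible.
* **ANOVA machinery**: classic one-way F per feature, not a moderated F
  with the reference encoded as an intercept; the reference condition
  enters only through the per-condition log2FC columns.

# Known limitations

* No isobaric interference or ratio-compression correction, no
  imputation, no peptide-shareability protein inference: accession strings
  are taken verbatim.
* The between-group (+NEM vs -NEM) loading component of the redox ratio
  is unidentifiable (see above); stoichiometry comparisons *across*
  conditions within one experiment are unaffected, absolute values carry
  the common bias.
* ORA results depend on the gene-set release supplied by the user; no
  live database retrieval is attempted, so pathway membership counts are
  reproducible but only as current as the GMT file.
* Distances on predicted structures are single-conformation screening
  values; for low-pLDDT (often disordered) regions they should only be
  used to nominate co-localization hypotheses.
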