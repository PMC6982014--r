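---
title: "Methods: TMT proteome and phosphoproteome differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT proteome and phosphoproteome differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtphos)
```

## The quantification model

A TMT multiplex measures every identified peptide once per channel; under the
3 × 3 design (CK, Cd, CdN × three biological replicates) each PSM carries nine
reporter intensities. The workflow treats the three replicates of a condition
as one pooled sample: per PSM and condition the replicate channels are
averaged arithmetically (zero intensities included, since a zero reporter is a
measurement, not a missing value — peptides whose *pooled* numerator or
denominator intensity is zero are excluded from ratio computation and
counted).

PSMs of the same peptide — identical sequence *and* modification state — are
collapsed by the **median** of their per-condition intensities before ratios
are formed. The median was chosen over the mean because repeated spectra of
one peptide occasionally include a co-isolation-distorted outlier; the choice
only matters for peptides observed in several spectra.

Peptide ratios for a contrast T/R are `r = I_T / I_R`. Each contrast is then
normalized by the **average ratio of the unique peptides** of that contrast:
all ratios (unique and shared) are divided by the arithmetic mean of the
unique-peptide ratios, after which the unique-peptide mean is exactly 1
(tested to 1e-9). Two choices are deliberate here:

* *Arithmetic mean on the ratio scale* is the default. Ratio distributions
  are right-skewed, so a geometric mean (log-space centring) is statistically
  the more natural estimator and is available via
  `normalize_sample(..., method = "geometric")`; the arithmetic form is the
  default because it is the conventional "average ratio of all unique
  peptides" normalization for this workflow. The difference is a single
  multiplicative constant per contrast and cancels entirely in the t-tests
  (which are translation-invariant in log space only up to this constant —
  see limitations).
* *Per contrast, not per channel pair*: the pooled-replicate route collapses
  channels before ratios exist, so the contrast is the natural normalization
  unit.

**Protein rollup** takes the median of a protein's unique-peptide normalized
ratios; shared peptides never contribute. Proteins need at least two unique
peptides (`min_unique_peptides = 2`) to be quantified. Even-count medians are
the mean of the middle pair. Significance is a **two-sided one-sample t-test
of the log2 peptide ratios against 0**. Testing in log space symmetrizes up-
and down-regulation (a 2-fold increase and a 2-fold decrease are equidistant
from no change); the literal alternative — raw ratios against mean 1 — is kept
as `test_space = "raw"`. With fewer than two ratios or zero variance the
p-value is undefined (`NA`), never an error, and undefined p-values classify
as `ns`.

## Phosphosites

Site identity is the triple (accession, 1-based position, S/T/Y residue);
multiply-phosphorylated peptides contribute to each of their sites
independently. Site-level records are filtered at **localization probability
strictly greater than 0.75** (a site at exactly 0.75 is discarded); because
the filter acts on individual supporting records, filtering and
quantification commute. A site's reported localization probability is the
maximum over its retained supporting records.

Per site and condition the intensity is the median over supporting
phosphopeptides; the site ratio is normalized by the average unique
phosphopeptide ratio of the contrast, exactly as in the protein route. The
p-value is a t-test over the supporting peptides' ratios when a site has two
or more supporting peptides, otherwise undefined.

**Protein normalization** divides the site ratio by the parent protein's fold
change from the unmodified-peptide route — division on the ratio scale, i.e.
subtraction in log space, the standard occupancy-style correction that
isolates phosphorylation regulation from abundance change. Sites whose
protein is unquantified (or absent) keep their raw ratio and are *flagged*
(`protein_normalized = FALSE`) rather than dropped: real site tables contain
sites whose proteins never reach two unique unmodified peptides, and
discarding them would silently bias the phosphoproteome toward well-covered
proteins.

## Differential calls

`up` iff `ratio > τ` and `p < α`; `down` iff `ratio < 1/τ` and `p < α`;
otherwise `ns`. Both inequalities are strict, so boundary values are `ns`.
The down threshold is the **reciprocal** `1/τ`, making calls symmetric under
ratio inversion (`classify_regulation(r, p) == "up"` iff
`classify_regulation(1/r, p) == "down"`); the bundled differential tables are
consistent with this reading (every published down ratio lies below 1/1.3).
Defaults are τ = 1.3 for proteins, τ = 1.2 for phosphosites, α = 0.05 on
**raw** p-values — no multiple-testing correction is applied to the calls, for
fidelity to the conventional workflow; a Benjamini–Hochberg column is emitted
for transparency.

## Enrichment and the z-score heatmap

Over-representation uses the one-sided hypergeometric tail
`p = P[X ≥ k]`, `X ~ Hypergeometric(N, K, n)` (equivalently the one-sided
Fisher test; the two-sided Fisher variant is available). The background is
the set of **quantified** proteins of the experiment, not the whole proteome:
detection in a TMT experiment is abundance-biased, and an all-proteome
background would manufacture spurious enrichment of highly expressed classes.

For the heatmap, category × cluster p-values (clusters are user-declared sets
such as "Cd/CK up") are collated with missing pairs imputed at p = 1,
filtered to categories with min p < 0.05 in at least one cluster, transformed
`x = −log10 p`, and z-scored per category with the sample SD (constant rows
become all-zero rather than NaN). Rows are clustered by average-linkage
hierarchical clustering on Euclidean distance — a deliberate, deterministic
choice among the several unnamed "one-way hierarchical clustering" variants;
ties follow `stats::hclust`'s input-order convention. The colour scale is
clipped to z ∈ [−2, 2].

## Physiological summaries

Raw replicate values behind published physiology tables are rarely available;
the package therefore computes one-way ANOVA and Tukey HSD **from summary
statistics** (mean, SD, n): `MSw = Σ(nᵢ−1)sᵢ² / Σ(nᵢ−1)`, pairwise
`q = |mᵢ−mⱼ| / sqrt(MSw/2 (1/nᵢ + 1/nⱼ))` referred to the studentized range
distribution. This is exact — the test suite verifies equality with
`aov()`/`TukeyHSD()` on raw balanced data to 1e-8.

Compact letters are assigned greedily in descending-mean order
(largest mean = "A"): each treatment joins every existing letter group it
does not differ from significantly (p ≤ 0.05) and opens a new letter
otherwise; fully contained letter groups are absorbed. With three treatments
this greedy display is canonical.

Where a published table's letters disagree with the ANOVA computed from its
own printed mean/SD/n, the package **reports the contradiction** rather than
reproducing the printed letters: `compare_letter_display()` returns the
disagreeing treatment pairs (comparison is by the induced partition, since
letter labels themselves are arbitrary). In the bundled physiology fixture
three metrics (Chl b, total chlorophyll, stomatal conductance) print shared
letters for treatment pairs whose Tukey p-values from the printed summaries
are below 0.05; the tests assert both the computed display and that these
pairs are flagged.

Percent changes are `100 (m_T − m_R)/m_R`, reported to one decimal; the sign
carries the direction.

## The synthetic-data generator

`simulate_tmt_experiment()` emulates the study design so that every stage has
a ground truth: log-normal peptide base intensities (`meanlog = log(1e6)`,
`sdlog = 1` — arbitrary intensity units), per-protein peptide counts from a
≥1-truncated Poisson with mean 5, 90% unique peptides, multiplicative
log2-normal channel noise (SD 0.15, a typical reporter-ion error scale), 10%
regulated proteins at 4-fold with random direction and a randomly chosen
perturbed treatment condition. Phosphosites (on 30% of proteins, 1–3 sites,
2–3 supporting peptides each) draw localization probabilities from
Beta(4, 1), under which about 68% of sites pass the 0.75 filter —
matching the pass fraction typical of real site tables. 10% of sites carry an
*independent* site-level effect (the realistic analogue of the protein-level
regulated fraction); the rest co-vary with their protein, which is exactly
the contrast the protein-normalization step must separate.

What the generator does **not** emulate: co-isolation interference (ratio
compression), isotope-impurity cross-talk between channels, missing channels,
intensity-dependent noise, shared-peptide protein inference, or decoy/FDR
structure of the identification step. Passing recovery tests therefore show
the *pipeline arithmetic* is right under the stated error model, not that
real TMT data meet that model.

## Numerical choices and degenerate inputs

* Undefined p-values (one peptide, zero variance) are `NA` and classify `ns`.
* Zero-denominator peptides are excluded and counted, never infinite ratios.
* Normalization with no unique peptides is an error (no scaling factor
  exists).
* Zero-variance enrichment rows z-transform to 0; single retained category
  skips clustering with a notice.
* All-identical treatment groups with zero SD get a single letter with a
  degenerate-input notice; zero `MSw` with unequal means yields p = 0.
* Output ratios print with 3 decimals and p-values with 4 significant
  digits; re-reading written tables reproduces values at that precision, and
  identical inputs give byte-identical files.

## Problem sizes in the test suite

The shipped tests run the recovery study at the default 2000-protein
configuration across 20 simulation seeds (pooled sensitivity must exceed
0.9 with pooled FDR below 0.15), one 2000-protein null batch for p-value
calibration against binomial 99% bounds, and five seeds for the
phospho-separation check; oracle comparisons enumerate the full
hypergeometric lattice to N = 30 and 100 random t-test cases. These sizes
keep the whole suite near half a minute while leaving the binomial bounds
tight enough to detect calibration failure.

## Known limitations

* Mean-ratio normalization assumes most entities are unregulated; with a
  large, directionally unbalanced regulated fraction the scaling factor is
  biased and shifts all calls. The geometric option is more robust to skew
  but not to imbalance.
* Raw-p calling at α = 0.05 does not control the FDR across thousands of
  proteins; the emitted BH column should be consulted for genome-scale
  claims.
* The one-sample t-test treats peptides as independent replicates of the
  protein ratio; shared ionization or digestion artifacts violate this.
* Tukey letters from summary statistics inherit the printed rounding of the
  source table; a borderline pair can flip with one more printed digit.
* Protein groups are not modelled: each accession is independent and only
  unique peptides quantify.
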