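# tmtphos

Differential analysis of TMT (tandem mass tag) labelled proteome and
phosphoproteome experiments, built around the multi-condition design used in
plant stress studies: a control (CK), a stressor (e.g. cadmium, Cd), and a
stressor-plus-amendment treatment (e.g. cadmium plus nitrogen, CdN), each with
three biological replicates multiplexed into one 9-channel TMT run.

The package is aimed at analysts who have reporter-ion quantified
peptide-spectrum matches (PSMs) — e.g. a MaxQuant-style export — and want the
complete downstream workflow: protein and phosphosite fold changes, significance
tests, differential calls, category enrichment, and the physiological summary
statistics that accompany such studies. A synthetic-data generator with known
ground truth makes every stage testable without any raw data.

## The method

For a contrast T/R (treatment over reference):

1. **Replicate averaging.** Per PSM and condition, reporter intensities of the
   condition's replicate channels are averaged, so the three replicates act as
   one pooled sample per condition.
2. **Peptide ratios.** PSMs of the same peptide (sequence + modification state)
   are collapsed by the median of their per-condition intensities; the peptide
   ratio is `r = I_T / I_R`.
3. **Normalization.** Every ratio is divided by the mean ratio of the *unique*
   peptides (peptides mapping to exactly one protein), so unique-peptide ratios
   average exactly 1 — removing global loading differences.
4. **Protein rollup.** A protein's ratio is the median of its unique-peptide
   ratios; at least two unique peptides are required, otherwise the protein is
   unquantified. Significance is a two-sided one-sample t-test of the protein's
   log2 peptide ratios against 0.
5. **Phosphosites.** Sites (accession, position, S/T/Y residue) are retained at
   localization probability > 0.75, quantified like peptides, and their fold
   change is divided by the parent protein's fold change — isolating
   phosphorylation regulation from protein-abundance change.
6. **Differential calls.** `up` iff `r > τ` and `p < α`; `down` iff `r < 1/τ`
   and `p < α`; else `ns`. Defaults: τ = 1.3 (proteome), τ = 1.2
   (phosphoproteome), α = 0.05.
7. **Enrichment.** For a differential set of size *n* with *k* members of a
   category against a quantified background of size *N* containing *K*
   members, `p = P[X ≥ k]`, `X ~ Hypergeometric(N, K, n)`. Category × cluster
   p-value matrices are filtered (min p < 0.05), transformed `x = −log10(p)`,
   z-scored per category, hierarchically clustered and drawn as a heatmap
   clipped to z ∈ [−2, 2].
8. **Physiology.** Percent changes between treatment means, and compact letter
   displays from one-way ANOVA + Tukey HSD computed directly from
   mean ± SD, n summaries (exact for balanced designs).

## Worked example

```r
library(tmtphos)

sim <- simulate_tmt_experiment(sim_config(seed = 42, n_proteins = 500))
pq  <- quantify_proteins(sim$psms, sim$design, c("Cd/CK", "CdN/CK"))
count_regulated(pq)
#>   contrast n_up n_down n_ns n_quantified
#> 1    Cd/CK   19      9  446          474
#> 2   CdN/CK   13     11  450          474

evaluate_recovery(pq, sim$truth)[, 1:5]
#>   contrast sensitivity specificity fdr direction_accuracy
#> 1    Cd/CK   0.9655172           1   0                  1
#> 2   CdN/CK   0.9230769           1   0                  1

sq <- quantify_phosphosites(sim$phospho_psms, sim$design, "Cd/CK",
                            protein_quant = pq)
head(sq[sq$regulated != "ns", c("position", "raw_ratio",
                                "normalized_ratio", "regulated")], 3)
#>    position raw_ratio normalized_ratio regulated
#> 21      591 2.9879111        3.3586136        up
#> 30       49 0.2233933        0.2201143      down
#> 31      420 0.2230715        0.2197973      down

d   <- subset(pq, contrast == "Cd/CK" & quantified)
enr <- enrich_categories(d$protein_accession[d$regulated == "up"],
                         d$protein_accession, sim$annotation)
head(enr[order(enr$p_value), c("category", "k", "n", "K", "N", "p_value")], 1)
#>   category  k  n  K   N      p_value
#> 1    CAT01 14 19 57 474 2.072472e-10
```

The simulator plants one enriched category (`CAT01`) among truly up-regulated
proteins; the enrichment stage recovers it at p ≈ 2e-10. With 500 proteins,
10% regulated 4-fold at log2 noise SD 0.15, 96% of regulated proteins are
recovered with zero false discoveries and every direction correct.

The package also ships transcribed summary tables from a poplar Cd/N study
(`tmtphos_example()`): physiological metrics (mean ± SD, n = 3, with reported
Tukey letters) and differentially regulated protein/phosphosite tables, used
as fixtures throughout the test suite. For example:

```r
phys <- read_physiology(tmtphos_example("poplar_physiology.tsv"))
ch   <- phenotype_summary(phys)$changes
subset(ch, metric == "Chl_a" & reference == "CK")
#>   metric treatment reference percent_change
#> 1  Chl_a        Cd        CK          -30.7
#> 2  Chl_a       CdN        CK           -8.0
```

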