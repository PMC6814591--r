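---
title: "Methods: cross-species aging signatures, variability and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species aging signatures, variability and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agesig)
```

# Scope and design

`agesig` analyses cross-sectional bulk RNA-seq of aging across several
species and tissues. Each (species, tissue) carries three age groups —
mature (M), aged (A) and old-aged (OA) — compared pairwise as early aging
(M vs A), late aging (M vs OA) and longevity (A vs OA). Ages are labelled
uniformly M/A/OA throughout; the longevity contrast always means A vs OA,
with the older group as the contrast so that a positive log2 fold change is
an increase with age. The pipeline identifies (i) genes regulated in the
same direction with age across species and tissues, (ii) genes regulated
exclusively in one tissue, (iii) changes in expression *variability*
between age groups, and (iv) the dominant biological processes among the
differentially expressed genes (DEGs).

Cross-species identity is anchored on a strict one-to-one ortholog map into
a single reference namespace. Many-to-many orthology rows are rejected at
read time rather than resolved heuristically: any resolution rule would be
arbitrary, and downstream logic (preselection, signature spans) requires an
unambiguous gene identity. Reference ids follow the mouse-orthologue
convention common in cross-species heatmaps.

# Differential expression

The DE stage is a deliberately simple, self-contained negative-binomial
Wald test. Downstream filters consume only (log2FC, FDR), so the stage is
designed for *calibration*, verified by simulation, rather than for
matching any particular published implementation's internals:

* **Size factors**: median-of-ratios against the per-gene geometric mean,
  excluding genes with a zero geometric mean, rescaled to geometric mean 1.
* **Dispersion**: per-gene method of moments under
  $\mathrm{Var} = \mu + \alpha\mu^2$, estimated in each group and pooled
  with degree-of-freedom weights, floored at $10^{-8}$. No shrinkage
  across genes.
* **Effect size**: $\log_2\!\frac{m_c + 0.5}{m_b + 0.5}$ on normalized
  means. The symmetric pseudocount of 0.5 keeps fold changes finite for
  zero-mean groups and is negligible at the expression levels that pass
  the TPM filter.
* **Reference distribution**: the Wald statistic (delta-method standard
  error) is referred to a two-sided Student-t with $n_b + n_c - 2$ degrees
  of freedom. With typical replicate numbers (n = 5 per group) the
  gene-wise variance estimate carries only ~8 df, and a standard-normal
  reference is visibly anti-conservative (empirical type-I error ≈ 0.087
  at nominal 0.05 in the null simulation below); the t reference absorbs
  that estimation noise and holds the measured type-I error at ≈ 0.05.
  This is the package's own small-sample choice, validated by the
  calibration test.
* **FDR**: Benjamini–Hochberg step-up, applied within each
  (species, tissue, comparison) table. Families are per table because each
  table is an independent screening question; no global adjustment across
  tissues is attempted.

The expressed-gene filter (TPM > 1 in at least one sample) is applied per
(species, tissue) over all three age groups jointly, before any
comparison, so all three contrasts of a tissue test the same gene universe.

Degenerate inputs are handled explicitly: identical groups give
log2FC = 0, p = 1; an all-zero sample keeps an all-zero TPM column (the
one documented exception to columns summing to $10^6$); a group with
fewer than two replicates is an error naming the offending cell.

# Signature filters

A gene **qualifies** in a (species, tissue) cell for direction *up* when
some comparison has FDR < 0.05 with positive log2FC and *every other*
comparison has $\log_2\mathrm{FC} \ge \log_2(1.1) \approx 0.1375$
(mirror-image for *down*). The 10% minimum change is read as a
fold-change magnitude (≥ 1.10), applied to the non-significant
comparisons only; the significant comparison needs only its sign. With
three comparisons the up and down rules can never both hold.

A direction is **conserved** when its supporting cells span at least 3
distinct species *and* at least 3 distinct tissues. Spanning is counted
jointly over the same supporting-cell set for one direction; the two
directions of a gene are evaluated independently, so a gene split between
directions is conserved only if one direction alone meets the span. All
thresholds (0.10, 0.25, FDR 0.05, 3 species, 3 tissues) are configuration
keys with these defaults.

**Tissue-exclusive markers** raise the minimum change to 25% and require
qualification in the focal tissue for *every* species of a comparison
group. The default groups are all species together plus the mammalian and
fish clades separately, since skin in particular ages differently between
fur-bearing mammals and scaled fish. Exclusivity is judged on the
direction-consistency *pattern*: a gene is disqualified if any other
tissue of the group shows the same-magnitude consistent change
(every comparison beyond the 25% threshold in one direction), whether or
not it is significant there. Requiring full significance elsewhere would
let genuinely global genes slip into the marker list whenever the
significance test happens to fail in the other tissues — exclusivity is a
statement about the expression pattern, not about the power of the test
elsewhere.

# Variability analysis

Per gene and age group, CV = sample standard deviation (n−1 denominator)
divided by mean of TPM across replicates. "Expressed" for CV purposes
means group-mean TPM > 1 within the (species, tissue, age group): a
per-sample reading would admit dropout-dominated rows whose CV measures
detection noise rather than expression control. Age groups are compared
with a two-sided Welch t-test on the per-gene CVs (no equal-variance
assumption is defensible between age groups), with significance tiers at
p ≤ 0.01, 0.001, 0.0001 and the direction labelled from the difference of
mean CVs. Percentile summaries (2.5%, median, 97.5%) use linear
interpolation.

# Functional profiles and separation scores

DEG sets are profiled by majority vote over gene→process annotations from
a controlled vocabulary (immune/inflammatory response, senescence,
apoptosis, oxidative stress response, cell cycle, other). A multi-label
gene votes once per label; unannotated DEGs are tallied under
`unannotated`; ties are reported as a set, never broken arbitrarily.
Profiles from fewer than 5 DEGs are flagged `low_support` rather than
suppressed.

The claim that samples organise by tissue and species rather than age is
made quantitative with mean silhouette widths (Euclidean) under three
labelings: tissue; species×tissue; and age, evaluated within each
species×tissue cluster and averaged. Scores are computed on the
log2(TPM+1) feature space over the selected genes; a 2-D embedding is
optional and delegated behind a narrow interface
(`embed_coordinates(inp, fn = ...)` accepts any
matrix → coordinates function, e.g. a t-SNE implementation; the built-in
default is a seeded 2-D PCA projection). The separation contract is
deliberately independent of any stochastic embedding optimizer. A
labeling with a single class yields NA, not an error.

# The simulator

`simulate_study()` is the package's reference data generator and the
stand-in for a real multi-species compendium. It emulates:

* a curated panel of expressed genes: baseline expected counts
  log10-uniform over [1, 3] (10–1000), as appropriate for a
  literature-curated senescence/inflammation panel rather than a whole
  transcriptome;
* species and tissue identity: per-(gene, species) and
  per-(gene, species, tissue) multiplicative offsets, log2-normal with
  sd 1.5 (typical ~3-fold differences — modest relative to real
  cross-tissue transcriptomes), which make tissue/species structure
  dominate age structure as in real data;
* library-size variation: a per-sample scale factor log10-uniform over
  [−0.15, 0.15];
* counts: gamma-Poisson with a single dispersion α = 0.1
  (Var = μ + αμ²);
* planted truth: conserved genes multiply their mean by fold 2 per age
  step (reciprocal for down) in every species and tissue, so all three
  comparisons see one direction; markers do the same only in their
  tissue; the OA group's dispersion is scaled by `oa_cv_scale`
  (default 0.5, the tighter expression control observed in long-lived
  individuals; values > 1 produce the opposite, fish-skin-like pattern).
  Variability is planted through dispersion, not the mean, so the CV
  effect is orthogonal to the fold-change effect and null genes keep
  log2FC centred at zero.

The generator does **not** model batch effects, GC/length bias, outlier
samples, correlated genes, partially missing orthology or unbalanced
designs beyond the explicit availability matrix. Passing recovery tests on
this generator therefore demonstrates the correctness and calibration of
the pipeline's logic under its stated model — not robustness to every
artefact of real compendia.

# Validation strategy and problem sizes

The test suite validates each stage against independent oracles: BH
against a brute-force step-up, the qualification and conservation rules
against literal loop translations of their definitions (exhaustive grids
plus hundreds of randomized instances), TPM and CV against closed forms,
and the DE test against Monte-Carlo calibration and power. End-to-end
acceptance runs use the default simulated study — 4 species × 3 tissues,
5 replicates per age group, 2000 genes, 30 + 30 conserved genes at fold 2,
10 liver markers — with 10–20 seeds per property and 100 seeds for the CV
null calibration; these sizes give stable Monte-Carlo estimates while a
full run of the suite stays within a couple of minutes.

# Known limitations

* The DE test has no dispersion or fold-change shrinkage; at very low
  counts it is conservative rather than powerful.
* The expression filter and DE stage assume three complete age groups per
  tissue; incomplete cells are skipped, not imputed.
* The marker screen's sensitivity decays with group size (qualification
  must hold in every species of the group); clade-level groups are the
  practical default.
* One-to-one orthology discards paralog-rich families entirely; such
  genes are recorded with the `missing_ortholog` exclusion reason rather
  than analysed.
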