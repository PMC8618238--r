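---
title: "Methods: TF dependence of gene expression under reduced insulin/IGF-1 signaling"
author: "riisregulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF dependence under rIIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riisregulome)
```

## The scientific question

Reduced insulin/IGF-1 signaling (rIIS) extends *C. elegans* lifespan
through three transcription factors acting downstream of the DAF-2
receptor: DAF-16 (FOXO), SKN-1 (Nrf) and HSF-1. Knocking each factor
down by RNAi in an rIIS background and sequencing the transcriptome
yields, per factor, the set of genes whose rIIS response depends on it.
The comparative questions this package answers are: which genes depend
on which factor, how completely each knockdown reverts rIIS-altered
expression to control levels, and — for genes targeted by several
factors — which factor sets the direction of expression.

The package implements the full comparative layer as reusable functions,
plus a ground-truth simulator of the seven-condition study design, so
every statistic can be validated against a known regulatory architecture
without any external download.

## The generative model

`generate_truth()` assigns each gene a target category (untargeted, or
targeted by exactly 1, 2 or 3 TFs), signed log2 effects per TF, an
optional TF-independent rIIS effect, a baseline and an exonic length.
`simulate_counts()` draws negative-binomial counts around

$$\log_2 \mu_{gs} = b_g + \log_2\!\frac{L_s}{L_0} + r_s\,\delta_g +
  \sum_{T} a_{T,s}\, e_{T,g},$$

where $b_g$ is the baseline log2 expected count at reference depth
$L_0$, $L_s$ the nominal sample depth, $r_s$ the rIIS indicator,
$\delta_g$ the direct rIIS effect and $a_{T,s} \in [0,1]$ the per-group
activity of factor $T$. Variance follows the standard RNA-seq count
model $\mathrm{Var} = \mu + d\mu^2$ (dispersion $d = 0.05$ by default;
$d = 0$ is the Poisson limit).

Group activities encode the pathway biology: DAF-16 and SKN-1 are
nuclear-active only under rIIS (activity 1 vs 0 in controls); HSF-1 has
basal activity 0.2 at 20 °C and 1.0 after heat shock; RNAi knockdown
leaves a residual activity of 0.1 (efficient but incomplete silencing).
All of these are `default_design()` parameters.

Under the default `daf16_dominant` combination rule, for DAF-16-target
genes the summed SKN-1 + HSF-1 contribution is clipped to at most
`dominance_clip` (default 0.9, strictly below 1) times
$|a_{\mathrm{daf16}} e_{\mathrm{daf16}}|$. The clip factor must be
below 1 so that DAF-16 sets the *sign* of the total effect even when the
other factors jointly oppose it at any magnitude; at exactly 1 an
opposing pair could cancel DAF-16 to zero. This makes the generative
rule itself the oracle for the dominance analysis: every DAF-16 target's
true rIIS direction equals the sign of its DAF-16 effect.

### Default parameters and what they emulate

| parameter | default | rationale |
|---|---|---|
| genes | 16,000 | matches the ~15k genes detected in the study design |
| replicates | 2 per group | the study's two biological replicates |
| library size | 2×10⁷ | typical bulk RNA-seq depth |
| dispersion | 0.05 | moderate bulk-RNA-seq biological variability |
| effect magnitudes | Uniform(log2 1.5, log2 8) | every true effect is at least the calling threshold |
| target fractions | 27% / 21% / 4% for 1/2/3 TFs | emulates the observed sharing structure: about half of TF-regulated genes specific to one factor, a small minority shared by all three |
| baseline | log2-normal, mean log2 400, sd 2 | wide, realistic dynamic range |
| lengths | log-normal(log 1500, 0.6), floor 50 bp | typical exonic lengths |

The simulator emulates replicate count noise, library-size differences
and the regulatory sharing structure. It does **not** emulate GC or
length bias, batch effects, isoform switching, or correlated gene
programs; passing recovery tests here demonstrates the statistics are
implemented correctly under the stated model, not that real libraries
are free of those artifacts.

The nominal `library_size` enters only through the depth offset; when
regulation is active, realized column totals drift above it because the
log-linear model is applied per gene without renormalizing the
transcriptome. We keep it that way deliberately: it makes the expected
count ratio between groups an exact function of the truth table, which
the recovery analyses score against.

## Quantification and QC

RPKM is `counts × 10⁹ / (library × length)` with the library taken as
the column total (whether the original study divided by mapped or
counted reads is not stated; column totals are used here). CPM columns
sum to 10⁶ exactly. QC follows the standard pipeline: log2(CPM+1),
per-gene z-score (zero-variance genes dropped), sample PCA by SVD, and
complete-linkage hierarchical clustering of Euclidean distances (the
linkage is configurable; only the distance is dictated by the study's
description). The log pseudocount is 1 and configurable.

## Differential expression

Comparisons are oriented — "activated" means up in the test group,
which is listed first (e.g. rIIS-C vs C) — and heat-shock groups are
only ever compared with heat-shock controls.

**Fold change.** The group-total ratio with library-size offsets,
$\mathrm{fc} = (\sum y_{test}/\sum L_{test}) / (\sum y_{base}/\sum
L_{base})$, which is the ML mean ratio of a two-group NB GLM with log
link and shared dispersion (exact at equal library sizes, where the
tests cross-check it against `MASS::glm.nb`). A pseudocount of 0.5 is
added to a group sum only when that sum is zero, keeping ratios finite
without biasing typical genes.

**Library sizes.** Both the fold change and the proportions test use
median-of-ratios *effective* library sizes by default
(`effective_library_sizes()`, cross-checked against DESeq2's size-factor
estimator). Raw column totals are available via `lib_method = "total"`,
but under strongly asymmetric regulation (about half the genes here are
strong TF targets) totals misattribute the composition shift —
rIIS libraries carry up to ~1.5× the reads of controls — to every
unchanged gene, which inflates false discoveries and masks reversal.
This is the same reasoning behind TMM and median-of-ratios
normalization in edgeR and DESeq2.

**Weighted proportions test.** Each replicate contributes a proportion
$p_i = y_i/n_i$ of its effective library. Group proportions are
combined with weights $w_i = 1/(1/n_i + \phi)$, where the
overdispersion $\phi \ge 0$ is estimated per gene by a two-pass method
of moments on the weighted residual variance: solve
$E[\sum_i w_i (p_i - \hat p)^2]$ for $\phi$ under
$\mathrm{Var}(p_i) = p(1-p)(1/n_i + \phi)$, clamp at zero, refresh the
weights, and repeat once. The statistic is
$z = (\hat p_{test} - \hat p_{base}) / \sqrt{\hat V_{test} + \hat
V_{base}}$ with $\hat V = \hat p (1-\hat p)/\sum w_i$, referred to the
standard normal. When $\phi = 0$ in both groups this is exactly the
(unpooled-variance) two-proportion z-test on the pooled counts.

**Dispersion moderation.** With two replicates a per-gene variance has
one degree of freedom, so the raw statistic behaves like a t with ~2 df:
against a normal reference its null rejection rate at 0.05 is ~0.17,
and against a t(2) reference the power for strong targets collapses.
Neither is acceptable for a calling rule built on standard p-values.
Because the count model implies $\phi \approx d\,p$ with $d$ the NB
dispersion, the per-gene $d = \phi/\hat p$ is shrunk toward its
across-gene mean with `prior_df` (default 10) prior degrees of freedom
before the final weight pass — the same information-sharing idea as
edgeR's common dispersion and limma's variance moderation. On the
global-null simulation this calibrates the rejection rate to ~0.05
while keeping sensitivity for strong targets above 0.95, and the common
dispersion estimate closely recovers the simulated $d$.
`prior_df = 0` restores the pure per-gene estimator, and
`ref_dist = "t"` the t reference, for users who want the unmoderated
construction.

**Calling.** Activated iff fc ≥ 1.5 and p ≤ 0.05; repressed iff
fc ≤ 1/1.5 and p ≤ 0.05; boundaries inclusive ("at least 1.5-fold").
No multiple-testing correction by default (calls use standard
p-values); Benjamini–Hochberg is available via `adjust = "BH"`.

## Overlap statistics

`log_hypergeom_sf()` computes $\log_{10} P(X \ge k)$ for
$X \sim \mathrm{Hypergeometric}(N, m, n)$ entirely in log space with
`lchoose` and log-sum-exp, so enrichment p-values thousands of orders
of magnitude below double underflow (log10 p < −2500 arises at these
set sizes) are returned exactly where a naive sum gives 0. The
representation factor is $k N / (m n)$. The overlap p-value is
upper-tail (enrichment) by default; depletion is behind
`alternative = "under"`.

The detection rule for "present in a condition" defaults to at least
one read in every replicate, with a mean-RPKM ≥ 10 alternative
(condition-exclusive genes are predominantly low-expressed). The
background universe defaults to the genes in the loaded count matrix
and is configurable; published representation factors imply a universe
of roughly 20,470 genes, which the worked-example fixtures use.
Percentages are reported at one decimal with half-up rounding, matching
the precision convention of published gene-set percentages.

## Classification layer

* **Cross-tab** (`riis_dependence_crosstab`): overlaps rIIS-activated
  with TF-activated and rIIS-repressed with TF-repressed sets; the
  combined fraction is $(k_{act}+k_{rep})/(|rIIS_{act}|+|rIIS_{rep}|)$,
  recomputed from integers, never cached floats.
* **Reversal** (`reversal_analysis`): restricted to genes with mean
  RPKM ≥ 10 in all three compared groups. A rIIS-DE gene "reverts" if
  it is *not* DE between knockdown and control at the same thresholds.
  The published analysis is visual (scatter shift toward the diagonal),
  so the operational rule is a design choice; an alternative band rule
  (|log2 fc| < log2 1.25) is provided, and both are logged. The default
  reuses the calibrated DE machinery rather than introducing a second
  ad-hoc threshold.
* **Quadrants** (`quadrant_classify`): sign pairs of log2 fold changes
  in two comparisons; exact zeros are excluded from percentages rather
  than arbitrarily assigned (ties are measure-zero under the count
  model); the same-direction fraction is Q1+Q3.
* **Dominance** (`dominance_patterns`): genes DE for ≥ 2 TFs and DE
  under rIIS, tabulated by their full sign pattern; per-TF concordance
  is the fraction of its genes whose rIIS direction matches. The focus
  TF is "dominant" when its concordance is the strict maximum and at
  least 0.9 (an artifact parameter — the biological claim is
  qualitative). The enumeration covers every sign combination, a
  superset of the published pattern rows. All steps key on gene
  identifiers, never row indices, so differing gene orders cannot
  misalign.

## Problem sizes and numerical checks

The test suite and acceptance script run the full design at 16,000
genes (seconds per stage on one CPU): exact-arithmetic worked examples,
a complete hypergeometric sweep over every configuration with N ≤ 60
against the base-R survival function (agreement to 1e-9 absolute in
log10), the global-null calibration band [0.03, 0.08], and recovery on
the dominant-rule simulation (sensitivity ≥ 0.8 and FDP ≤ 0.2 for
strong targets, reversal ≥ 0.8 among true DAF-16 targets, DAF-16
concordance ≥ 0.9 and strictly above the other factors). Determinism is
bit-exact: the same seed and configuration reproduce counts and the
summary JSON identically.

## Known limitations

* The reconstruction of the proportions test follows the cited
  weighted-proportions structure but the original toolchain's exact
  internals are proprietary; every constant here is exposed.
* The simulator's regulatory architecture is independent across genes;
  co-regulated modules would make replicate-level noise correlated and
  the effective number of independent tests smaller than the gene
  count.
* The heat-shock transcriptome shift beyond HSF-1 is not modelled by
  default (`riis_direct` covers TF-independent rIIS effects; a global
  HS effect would be analogous and is not needed to validate the
  statistics).
* Dataset-level published counts (e.g. 14,933 common genes, 932
  DAF-16-activated genes, the 78%/50% reversal fractions) derive from
  the study's sequenced libraries and are not reproducible from
  simulation; the package reproduces their *arithmetic* and recovers
  the analogous quantities on ground-truth data.
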