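---
title: "Cross-experiment meta-analysis of antioxidant-system expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-experiment meta-analysis of antioxidant-system expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aosmeta)
```

## The problem

Plants detoxify reactive oxygen species through the antioxidant system
(AOS): the enzyme families SOD, CAT, APX, GPX, GR, DHAR and MDHAR. How these
genes respond to abiotic stress — cold, water deficiency — has been measured
many times, but in individual experiments with few replicates, one platform,
one time point. `aosmeta` provides the machinery to pool such heterogeneous
experiments (microarray intensities and sequencing counts side by side) into
one comparable panel of fold changes, detect which experiments carry no
usable stress response, and call stress-regulated genes with false-discovery
control. A second, independent workflow quantifies relative expression from
qPCR fluorescence curves with per-amplicon efficiency correction, the method
used to validate such panels in the wet lab.

Because real cross-study inputs are large, heterogeneous downloads, the
package includes a first-class synthetic-data generator with planted ground
truth. All quantitative guarantees of the pipeline are demonstrated against
that ground truth.

## Normalization cascade

Three stages make replicates comparable across platforms and experiments:

1. **FPKM** (count platforms only):
   $\mathrm{fpkm}_{gs} = 10^9 \, c_{gs} / (L_g \, N_s)$ with $L_g$ the
   transcript length in bp and $N_s$ the library size. This is the canonical
   definition; intensity studies pass through unchanged.
2. **Housekeeping normalization**: every value in replicate $s$ is divided
   by that replicate's value of the flagged reference gene (for example a
   ubiquitin or tubulin gene chosen per species). This removes per-sample
   multiplicative scale and is idempotent.
3. **Control-relative normalization**: within each experiment, each gene is
   divided by the mean of its control replicates, so each value expresses
   deviation from that experiment's own control level and control
   replicates average exactly 1 (asserted to 1e-9 in the tests).

A note on ordering: stages 2 and 3 do not commute as an algebraic identity
(a mean of ratios is not a ratio of means), so the cascade is defined in
this fixed order. The property that actually matters — any multiplicative
factor shared by all genes of a replicate cancels out of the final panel —
holds exactly and is asserted in the test suite.

Genes whose control mean is zero in an experiment cannot be expressed as
fold changes there; they are excluded from that experiment's columns and
recorded, rather than imputed. The housekeeping gene (identically 1 after
stage 2) is dropped from the analysis panel.

## Clustering, cluster types and the experiment filter

Replicate fold-change profiles are clustered with Ward linkage
(`stats::hclust`, `"ward.D2"`) on Euclidean distances in
$\log_2(\mathrm{fold} + \varepsilon)$ space, $\varepsilon = 10^{-6}$
(configurable to linear space). Log space is used because fold changes act
multiplicatively; merge heights are non-decreasing by construction. `hclust`
is deterministic given the distance matrix; with continuous profiles exact
distance ties have probability zero, which is why no bespoke tie-breaking
rule is layered on top. The flat partition is obtained by cutting the tree;
when the number of clusters is not supplied, the cut maximizing the mean
silhouette width over $k \in [2, 15]$ is chosen — the source data behind
this pipeline give no rule for choosing $k$, so the package makes its
default explicit and overridable.

Clusters are labelled: *control* when they contain at least one control
replicate and controls form a strict majority; otherwise *CR*
(cold-response) or *WDR* (water-deficiency-response) by the majority stress
type of their stress members; an exact tie gives *mixed*, since there is no
basis to prefer either type.

The **experiment quality filter** implements the rule that an experiment
whose stress replicates mostly co-cluster with controls carries an implicit
or noisy response: for each experiment the fraction of its stress
replicates assigned to control-containing clusters is computed, and the
experiment is excluded iff that fraction is **strictly greater than 0.5**
(exactly one half retains). "Control-containing" defaults to the literal
reading — any cluster with at least one control replicate — with a
majority-control variant behind a switch. After filtering, the retained
panel (plus all controls) is re-clustered and all downstream statistics run
on that second pass.

## Differential calls

Each stress cluster is compared against all control replicates (or, in the
small-sample per-experiment mode, each experiment's stress replicates
against its own controls) with a per-gene two-sample t-test on log2 fold
values. Welch's unequal-variance form is the default — groups pooled across
experiments have no reason to share variances — with Student's form behind
a flag. The reported fold change is the geometric-mean ratio, matching the
log2 test scale; the arithmetic ratio of means is reported alongside.

Raw p-values are corrected per comparison with the **Benjamini–Yekutieli**
step-up, which controls the false discovery rate under arbitrary
dependence — appropriate here because genes of one enzyme family are
co-regulated. Sorted p-values are scaled by $m\,c(m)/i$ with
$c(m) = \sum_{j=1}^{m} 1/j$, followed by the cumulative-minimum step and
capping at 1; missing entries pass through without counting towards $m$.
The implementation delegates to `stats::p.adjust(method = "BY")`; a
brute-force transcription of the definition serves as the independent
oracle in the tests (agreement to 1e-12 on a thousand random vectors).

A gene is called *up* when its adjusted p is below $\alpha$ (default 0.05)
and its fold exceeds 1, *down* below 1, otherwise *ns*. Degenerate cases
are reported honestly rather than patched: identical groups give $p = 1$;
zero-variance groups with different means are flagged and given the
machine-minimum p rather than a fabricated statistic. The summary table
arranges genes by enzyme class and clade against comparisons, marks
significant cells, and renders missing gene/comparison cells as no-data.

## qPCR quantification

The relative expression of a gene of interest is computed with the
multiple-sample efficiency-corrected model
$$
\mathrm{Ratio} \;=\;
\frac{E_\mathrm{target}^{\;\Delta Cq_\mathrm{target}}}
     {E_\mathrm{reference}^{\;\Delta Cq_\mathrm{reference}}},
\qquad
\Delta Cq = \overline{Cq}_\mathrm{control} - \overline{Cq}_\mathrm{treat},
$$
so a ratio above 1 means higher expression under treatment, and with both
efficiencies equal to 2 the model reduces to the classical
$2^{-\Delta\Delta Cq}$ (asserted to 1e-12).

Efficiencies and Cq values come from the raw fluorescence curves by
window-of-linearity estimation:

* an additive **baseline** is subtracted. Rather than a fixed early-cycle
  mean, the baseline is chosen to maximize the log-linearity ($R^2$) of the
  exponential-phase fit, alternating window selection with a baseline
  refinement that is anchored by all usable cycles below the window. For a
  plateau curve this converges to the flat ground level; for a curve that
  is exponential from cycle 1 it converges to zero, which keeps the
  analytic identity $F(c) = 0.001 \cdot 2^c$, threshold 1.024
  $\Rightarrow Cq = 10$ exact. The anchoring matters: optimizing the
  baseline against the 4–6 window cycles alone lets the baseline absorb
  plateau curvature and biases the slope for abundant templates.
* the **window**: among baseline-corrected cycles below 90% of the maximum,
  the run of 4–6 consecutive cycles maximizing the $R^2$ of
  $\log_{10} F$ vs cycle; efficiency is $10^{\mathrm{slope}}$. On noiseless
  curves across template abundances spanning two orders of magnitude the
  true efficiency is recovered within ±0.003.
* **Cq** is the fractional cycle where the fitted line crosses a threshold
  shared by all wells of an amplicon (geometric mean of the per-well
  window-bound levels), for comparability across wells.
* wells without amplification (no-template controls, flat curves) are
  flagged negative and excluded rather than given fake values.

Technical replicates are averaged into biological-replicate Cq values;
group means over biological replicates feed the ratio; the per-amplicon
efficiency is the mean of that amplicon's per-well estimates (the
convention of curve-analysis tools that pool per amplicon, which reduces
variance). The control group's own ratio and the reference amplicon's
ratio are exactly 1 by construction. For plates delivering only
precomputed Cq values the same aggregation runs with user-supplied
per-target efficiencies.

The treatment design (cultivar × treatment with ≥2 replicates per cell) is
analysed by a per-gene fixed-effects two-way ANOVA on
$\Delta Cq = Cq_\mathrm{target} - Cq_\mathrm{reference}$, with type-II sums
of squares (via `car::Anova`) so that unbalanced layouts without
interaction-driven imbalance are handled conventionally; a naive
sums-of-squares decomposition on balanced layouts is the test oracle
(agreement to 1e-10).

## The synthetic-data generator

`generate_meta_experiments()` emulates the statistical structure the
meta-analysis assumes, with every distortion the cascade is supposed to
remove planted explicitly:

* per-gene log2 baselines shared across experiments
  (mean 6, sd 1.5 — intensity-scale magnitudes);
* a per-experiment batch scale and a per-sample scale/library-size factor
  (log2 sd 0.5);
* log-normal replicate noise (log2 sd 0.25);
* planted stress signatures per stress type: by default blocks of strongly
  regulated genes (folds 6 and 0.15 for cold, 5 and 0.2 for water
  deficiency), jittered per gene × experiment (log2 sd 0.1), null genes at
  exactly fold 1;
* the housekeeping gene co-varies with batch/sample scale only;
* count platforms draw negative-binomial counts (dispersion 0.05; 0 means
  Poisson) from length-weighted library fractions; intensity platforms emit
  positive reals;
* a configurable fraction of experiments receives **no** signature — their
  stress replicates are statistically control-like, which is precisely the
  failure mode the experiment filter targets. Signature zeroing (rather
  than variance inflation) is used because it creates the
  "stress clusters with controls" geometry directly.

The default configuration deliberately matches the retained-sample shape
the pipeline is designed around: 13 experiments on mixed platforms with 70
control and 130 stress replicates of a 35-gene panel. The null intensity
configuration (all folds 1, zero noise) passes through the cascade to a
panel of exact 1s; for count platforms the same identity holds only in
expectation, since counts are sampled.

`generate_qpcr_plate()` builds four-parameter amplification curves —
additive baseline, plateau, and an early phase satisfying
$F(c) - b \propto N_0 E^{\,c}$ — for a target/reference well layout of
3 biological × 3 technical replicates over 45 cycles, the standard design
of such experiments. Default efficiencies are typical SYBR values (targets
1.8/1.9/2.0, reference 1.9); default planted ratios are magnitudes typical
of cold-stress AOS responses (0.45–3.0). Per-well Cq noise (default sd 0.2
cycles) is applied by scaling the template by $E^{-\epsilon}$, which shifts
the whole curve by exactly $\epsilon$ cycles.

## What the tests do and do not show

Problem sizes used by the test suite and the acceptance script: 20
replications of the full 13-experiment bundle for filter and differential
recovery, 200 small all-null panels for false-call control, 100 simulated
plates for end-to-end ratio recovery, and a thousand random cases for each
closed-form oracle (BY step-up, perfect-doubling ratio, Welch, balanced
ANOVA decomposition).

The simulations demonstrate internal correctness — the pipeline recovers
exactly what was planted under the generator's assumptions. Real data
differ in ways the generator does not model: probe-level microarray
artifacts and background correction, mapping and annotation errors,
correlated gene-gene noise beyond the shared batch factor, partial or
drifting stress responses (the generator's no-response experiments are
all-or-nothing), and amplification inhibitors or melting-curve anomalies in
qPCR. Passing tests therefore validate the method's logic and numerics,
not the biology of any particular dataset.

Under iid per-well Cq noise of 0.2 cycles and a 3 × 3 replicate design, the
sampling standard deviation of the estimated log2 ratio is ≈ 0.12–0.13, so
single ratio estimates land within ±15% of truth roughly 90–93% of the
time — an inherent property of the design, not an estimator deficiency;
the noiseless plates recover ratios to well under 2%.

## Known limitations

* The exclusion filter assumes the clustering is dominated by the
  stress/control contrast; weak signatures close to the noise floor can
  leave stress replicates scattered, and the filter then errs toward
  exclusion.
* Cluster-vs-control comparisons treat replicates as independent; shared
  control-mean noise within an experiment induces mild within-comparison
  correlation, which BY (valid under dependence) absorbs at some cost in
  power.
* The window-of-linearity estimator assumes a single exponential phase;
  biphasic amplification or drifting baselines are not modelled.
* No probe-to-gene mapping, RMA/quantile preprocessing, or GEO retrieval:
  inputs are expected as already-summarized gene × replicate tables.
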