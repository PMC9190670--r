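---
title: "Models and methods behind pedmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pedmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedmeth)
```

`pedmeth` analyzes promoter CpG methylation in pediatric tumor cohorts
against a baseline assembled from several normal cohorts. This vignette
describes the statistical machinery, the choices made where the design
was genuinely open, and what the synthetic-data generator does and does
not emulate.

## Scales and transforms

Array methylation arrives as beta values, the ratio of methylated to
total signal, in [0, 1]. Beta is the interpretable scale but is
heteroscedastic near its boundaries, so all linear modelling happens on
the M scale, M = log2(β / (1 − β)). Because the logit is undefined at
exactly 0 or 1, betas are clamped to [1e−6, 1 − 1e−6] first; `mToBeta()`
is the exact inverse on that domain (round-trip error below 1e−12, which
the test suite checks on 10⁶ values). The clamp width is far below array
measurement resolution, so it never affects a real value.

## Baseline categories

Within one dataset a gene's level is determined by the median beta across
samples — low below 0.2, high above 0.6, medium otherwise — and its
variance category by the coefficient of variation (sample SD with n−1
denominator, divided by the mean), high at CV ≥ 0.5. Two numerical
choices are deliberate:

* **Strict inequalities.** A median of exactly 0.2 is medium and a CV of
  exactly 0.5 is high variance. "Less than" / "greater than" wording
  pins the low/high sides; the boundary itself must land somewhere, and
  assigning it to the middle/high-variance side keeps both rules strict.
* **CV on the beta scale.** The CV of M-values is ill-defined around
  M = 0 (mean near zero), so the variance category uses betas. A
  zero-mean beta vector would make the CV 0/0; it is defined as 0
  (cannot occur after clamping, but the guard keeps the function total).

Cross-dataset consistency generalizes a four-dataset rule to any count:
consistent means the same (level, variance) pair in all datasets,
semiconsistent in all but one, inconsistent otherwise. Modal categories
(used for the normal-versus-tumor change table) break ties by the fixed
order low < medium < high on levels and low < high on variance, so
results are deterministic; ties are rare but must resolve reproducibly.

The pooled-variance track (genes high-variance across all normal samples
combined) is computed on the batch-corrected pool: between-dataset shifts
are exactly what correction removes, and leaving them in would conflate
batch effects with biological variance. Per-dataset categories, by
contrast, are computed on the raw cohorts, since within one dataset there
is no batch to correct.

## Batch adjustment

The normal cohorts come from different tissues, platforms and studies, so
they carry location and scale batch effects. `batchCorrect()` works on
the logit scale: features are standardized against a batch-design fit
(pooled variance with denominator N), per-batch per-feature location
(γ) and scale (δ²) estimates are shrunk toward cross-feature priors — a
normal prior for γ and an inverse-gamma prior for δ², both fit by
moments, solved by the standard iterative EB update to convergence 1e−4 —
and the adjusted values are de-standardized and inverse-logit mapped, so
output betas stay inside (0, 1). With `eb = FALSE` the raw location/scale
estimates are used instead; that mode preserves per-feature grand means
exactly (the shrunk estimates move them by a small amount, typically
below 0.01 M on balanced designs, which is the price of stabilizing
small batches). The test suite checks the EB path against an independent
reference implementation to 1e−8.

## Differential methylation

Per feature, ordinary least squares of M ~ intercept + group + sex. Sex
is a covariate throughout because methylation has strong sex-linked
components and the cohorts are not sex-balanced; samples of unknown sex
are dropped with a logged count, and if sex is constant in the remaining
samples (one real cohort is all male) the covariate is omitted rather
than fit singular. The reported log2 fold change is the group coefficient
— the difference of group means on the M (log2-ratio) scale, the standard
convention for M-value models.

Residual variances are moderated: with d residual df and feature variance
s², the posterior is s̃² = (d₀s₀² + d·s²)/(d₀ + d), where the prior df d₀
and prior variance s₀² are estimated by moment-matching on log s² (mean
and variance of log s² corrected by digamma/trigamma terms; the trigamma
inverse is solved by Newton iteration). The moderated t uses d₀ + d df;
`moderated = FALSE` gives the exact OLS limit (d₀ = 0). Tests are
two-sided (volcano symmetry), BH-adjusted across features, and a feature
is significant only when FDR < α (default 0.05) *and* |log2 FC| ≥ the
threshold (default 2). Features with zero residual variance still get a
finite moderated t as long as d₀ > 0.

Tumor-versus-normal contrasts fit each tumor type against the corrected
normal pool; across-type analysis fits every pair of tumor types as its
own two-group model rather than one joint multi-group model — simpler,
and each pair's variance estimate is then local to that pair.

## Aberration calling

The normal reference stores a per-gene mean and SD (n−1) over all
batch-corrected normal samples. A tumor value is hypermethylated when
z = (value − mean)/SD exceeds 3 strictly, hypomethylated below −3.
Calling operates on the beta scale: z-scores are scale-equivariant under
any fixed monotone-linearized choice, but one scale must be fixed, and
beta keeps the reference interpretable (a gene with reference 0.30 ±
0.05 is hypermethylated above 0.45). Genes with zero reference SD cannot
be z-scored; they are flagged non-callable, never called, and excluded
from per-tumor proportion denominators with a logged count.

## Mutation events and mutual exclusivity

A gene counts as mutated in a tumor when it has at least one damaging
SNV/indel — HIGH impact, or MODERATE with SIFT "deleterious" or PolyPhen
"damaging"/"probably_damaging" — or an RNA fusion with the gene as either
partner. LOW/MODIFIER variants are excluded regardless of SIFT/PolyPhen
evidence: the two keep-rules are treated as exhaustive. No minor-allele-
frequency filter is applied (those values are missing for a large share
of annotated variants in practice); unknown impact strings are treated as
non-damaging with a logged count. The VCF CSQ subfield layout is
configurable because annotation dialects differ.

The mutual-exclusivity test restricts to genes with at least five events
of each type (both inclusive), counts gene×tumor co-occurrences, and
permutes by shuffling each gene's methylation-status vector across tumors
independently while the mutation matrix stays fixed. Per-gene shuffling
(rather than shuffling whole tumor columns) preserves each gene's
marginal event count — the very quantity the ≥ 5 filter conditions on —
so the null stays inside the conditioned event space. The empirical
p-value is left-tailed with the add-one correction,
(#{null ≤ observed} + 1)/(N + 1): mutual exclusivity means *fewer*
co-occurrences than chance, so small p supports exclusivity and an
observed count above the null mean yields a large p. The directional
variant runs the same machinery on oncogene∧hypomethylation and
TSG∧hypermethylation separately, with genes listed as both oncogene and
TSG excluded as ambiguous.

## Probe filters

Four filters precede statistical testing, each emitting a `FilterReport`
(input/output counts and removed ids):

* **Promoter window.** Keep (probe, gene) pairs within 300 bp of a TSS,
  inclusive at the boundary. Probes mapping to several genes contribute
  to each gene's mean independently.
* **Invariant categories.** Drop probes whose per-sample level category
  (0.2/0.6 thresholds on each individual value) is identical across every
  sample of every cohort — they carry no category information.
* **Expression correlation.** Keep probes whose M-values correlate with
  their gene's tumor expression (Spearman, BH at 0.05). Both correlation
  signs are accepted: promoter methylation is canonically repressive
  (negative correlation), but a sign restriction is an extra assumption
  the data can decide instead. Probes with undefined correlations or no
  expression data are removed and counted separately.
* **Cross-normal divergence.** Drop probes significantly different
  (FDR < 0.05, |log2 FC| ≥ 2) between any pair of normal datasets — they
  disagree between supposedly equivalent baselines.

## The synthetic-study generator

`simulationConfig()` fixes the study conditions: 2,000 genes × 2 promoter
probes, 4 normal datasets × 30 samples, 3 tumor types × 40 tumors — a
desk-scale rendering of a multi-cohort 450K study that runs in seconds.
Per gene, an archetype fixes a baseline beta band (low 0.05–0.15, medium
0.32–0.48, high 0.65–0.85 — each band kept clear of the 0.2/0.6 category
boundaries, as a real stable gene's median would be) and a variance
regime. Noise is generated on the M scale and mapped through the inverse
logit (logistic-normal), so betas respect their range. For low-variance
genes the beta-scale SD is the `noiseSD` parameter (default 0.02, a
typical within-cohort spread for a stable promoter); for high-variance
genes fixed M-scale spreads (1.6 for low-level genes, 2.4 for medium)
were calibrated once so the realized CV falls clearly above 0.5. A
high-level/high-variance archetype is not generated: a gene with median
above 0.6 cannot sustain CV ≥ 0.5 on a bounded scale, matching how
vanishingly rare that combination is on real arrays.

Archetype fractions default to roughly two-thirds low/low, with ~19%
high/low and ~8.5% high-variance overall, echoing the composition real
normal cohorts show. Batch shifts are per-gene, per-dataset normal draws
(SD 0.15 M — visible in a PCA, small against category boundaries); 2% of
genes carry a sex effect (SD 0.5 M). Probes of one gene share the
gene-level deviate (promoter probes are biologically correlated) plus a
small probe offset and measurement noise; without that sharing,
gene-level averaging would halve the planted variance and break the
variance archetypes.

Tumors are drawn from the normal generative model without batch shifts,
with within-type noise set to 0.25 of the normal reference SD: the pooled
reference spans four different tissues, so a single tumor type is
substantially more homogeneous than the baseline it is compared against.
Planted aberrations shift a per-tumor random gene subset by ±4 reference
SD on the beta scale (defaults: 5% hyper, 10% hypo, hypomethylation more
common as in real pediatric tumors). Only *eligible* genes are planted —
those where the shifted value still fits inside (0, 1); high-variance
genes cannot represent a 4-SD shift on a bounded scale, and planting an
unrepresentable truth would make recovery metrics meaningless. Mutation
events are Bernoulli per gene×tumor (rate 0.05), emitted through the
package's own VCF/BEDPE writers with a 30% share of benign annotations
(exercising the damaging filter) and 10% of damaging events as fusions;
placement can be independent of, exclusive with, or forced onto the
planted methylation aberrations.

**What passing tests do and do not show.** The generator reproduces the
statistical structure the pipeline assumes — archetypes, batch effects,
sex effects, z-shifted aberrations, rare events — but not array
chemistry: no type I/II probe bias, no detection-p-value failures, no
cross-reactive probes, no copy-number contamination of methylation
signal, and tumor purity is implicitly 100%. Recovery rates on synthetic
data are therefore upper bounds on real-data performance, and the planted
±4 SD shifts are cleaner than the graded dysregulation real tumors show.

## Problem sizes in the test suite

The acceptance-style tests run at the sizes the package treats as its
reference conditions: category recovery on the default 2,000-gene,
4 × 30-sample design; differential calibration on 5,000 features at 20
versus 20 samples (one KS uniformity check and twenty replicate null
runs); aberration recovery on the default design's 120 tumors;
mutual-exclusivity calibration over 200 replicate 20-gene × 40-tumor
studies (2,000 permutations each — p-value granularity of 1/2001 is far
below what a 200-sample KS test can resolve) and power over 40 exclusive
replicates at the full 10,000 permutations, plus an exact enumeration
check on a 1-gene × 5-tumor instance.

## Known limitations

* Raw .idat processing, functional normalization and detection-p masking
  are upstream of this package; inputs are assumed normalized betas.
* The pipeline models batch at the dataset level only; surrogate-variable
  or random-effects structure is out of scope.
* The EB batch adjustment implements the parametric prior form only.
* Gene-level tests use gene-summarized values (mean of probe values);
  probe-level and gene-level significance can disagree for genes with
  heterogeneous promoter probes.
* Copy-number events are not integrated into the mutation matrix.
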