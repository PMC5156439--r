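---
title: "Transcriptome signatures of stress robustness: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome signatures of stress robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustsig)
```

## The problem

Industrial *Lactococcus lactis* starter cultures are routinely spray dried,
which exposes the cells to lethal heat and oxidative stress. How well a
culture survives ("robustness") depends strongly on how it was fermented
beforehand. `robustsig` implements a transcriptome–phenotype matching
pipeline: strains are grown under a small factorial panel of fermentation
conditions (salt, initial pH, temperature, oxygen level), survival under a
lethal stress dose is measured by plate counting at two assay timepoints,
genome-wide expression is measured once (in exponential phase) per
fermentation, and per-gene linear models link expression to the survival
phenotype. Genes whose transcript level tracks robustness across conditions
form a *robustness signature* — candidate process-control markers that can
be read out by qPCR.

## Phenotype model

Robustness is quantified on the log10 scale as the difference of viable
counts after and before stress,

$$ r = \log_{10} N_t - \log_{10} N_0 = \log_{10}(\mathrm{survival}/100), $$

so a 5-log kill gives $r = -5$. All correlations and t-tests operate on this
scale: it is equal up to an additive constant to the log CFU difference, so
t-statistics and Pearson correlations are identical between the two
parameterizations. Technical duplicate CFU counts are averaged on the count
scale *before* the ratio (`compute_survival`); the order is not identifiable
from the published tables, and averaging counts is the natural choice when
duplicates are Poisson-distributed plate counts. Samples where every
duplicate is zero are *censored* (below the plating detection limit) and
raise a typed condition rather than entering the log-scale statistics as
zeros.

Three strain phenotype tables (IL1403, KF147, SK11; 13 fermentations each)
ship with the package (`strain_phenotypes()`). Survival at the second,
non-selected assay timepoint of each stress was published only in
supplementary material that is not packaged; the fixtures therefore carry
one survival column per stress, and the timepoint-selection rule is
exercised non-trivially on multi-timepoint synthetic data.

Growth is summarised by $\mu_{max}$, the steepest sliding-window slope of
$\ln OD_{600}$ versus time (window default 4 points — the fitting procedure
behind the published values is unstated, and a 4-point window is a common
compromise between noise suppression and bias on half-hourly sampling), and
by the final OD.

Fermentation-parameter effects are assessed with Welch two-sample t-tests
(R's `t.test` default). Temperature has three levels and is handled as the
three pairwise contrasts; no ANOVA is attempted because the published
analysis reports t-tests only. Correlations of growth with survival use
log10 survival: on the raw percent scale the SK11 growth/oxidative-survival
correlation is −0.76 rather than the published magnitude 0.79, which the
log scale reproduces (|r| = 0.789). The signed value is negative — faster
growth, poorer oxidative survival — and the package reports the sign;
magnitude is what the published number carries.

## Microarray preprocessing

Two-color arrays are processed from probe-level Cy5/Cy3 intensities:

1. **Floor**: non-positive intensities are raised to 1 (counted, logged);
2. **MA transform**: $M = \log_2(\mathrm{Cy5}/\mathrm{Cy3})$,
   $A = (\log_2 \mathrm{Cy5} + \log_2 \mathrm{Cy3})/2$;
3. **Normalization** (`lowess_normalize`): the intensity-dependent dye bias
   is removed by subtracting a robust *local quadratic* regression of M on A
   (span 0.3, robustness-weighted). Classic degree-1 lowess at the same span
   leaves visible lack of fit when the bias curvature is comparable to the
   span window (residual bin-medians ~0.08 against a planted 0.5·sin(A)
   bias, versus ~0.01 for the local quadratic), which is why degree 2 is the
   default here. The corrected M is then median-centered per array (the
   "scaling" step). A global (across-array) fit is available via
   `global_scale = TRUE`; per-array is the default since dye bias is an
   array-level artifact.
4. **Loop unfolding** (`loop_to_sample_expression`): the hybridization
   scheme is a loop design — two cycles over the day-1 and day-2 samples
   plus one bridging hybridization between the replicated fermentations
   (configurable; the published scheme's exact arrows are only available as
   a supplementary image). Per probe, the least-squares system
   $x_{cy5} - x_{cy3} = M'$ is solved by SVD pseudoinverse; because the
   absolute expression level is unidentifiable from ratios, the minimum-norm
   solution is taken, which fixes the gauge by making each probe's sample
   values sum to zero. Per-gene regressions on robustness are invariant to
   this per-gene additive constant.
5. **Probe aggregation**: the ORF value is the median of its probes.

In the strict noiseless, bias-free limit this chain reproduces the
(row-centered) truth to numerical precision. With signal present, the
normalization necessarily attenuates whatever expression variation is
correlated with A within an array; the planted-bias simulations quantify
that the removal leaves per-bin residual medians < 0.05 while null
association P-values stay uniform (KS < 0.05 after the full chain).

## Association model

For each gene, ordinary least squares of 2-log expression on robustness
(`fit_all_genes`, closed-form normal equations, identical to per-gene `lm`
to 1e-10 and checked against it in the tests); the slope's two-sided
P-value uses $n-2$ degrees of freedom. Expression is regressed on
robustness (the transpose fit would give the same P-values, different
slopes).

A strain's signature (`strain_signature`) keeps genes with p < 0.05 at
*both* assay timepoints **and** a consistent slope sign (a gene flipping
sign between timepoints has no single correlation direction), ranks by the
product of the two P-values, and flags the subset with product < 5×10⁻⁵.
No multiple-testing correction enters the selection — the dual-timepoint
and product filters are the published mechanism — but BH-adjusted columns
are emitted for information.

**A caveat the simulations make explicit:** the two timepoint phenotypes
share the fermentation-factor structure, and the *same* expression matrix
is regressed on both. At realistic phenotype noise (sd 0.3 log10 against a
5-log signal spread) the two regressors correlate at ρ ≈ 0.98, so a null
gene's two P-values nearly coincide and the product filter admits roughly
$P(p < \sqrt{5\times10^{-5}}) \approx 0.7\%$ of null genes (~6–8 per 1000,
median, in the packaged simulations) — far more than the ≤ 1 per 1000 that
would hold if the two P-values were independent. The dual-timepoint product
filter is a *ranking* device, not a false-discovery guarantee; this is an
inherent property of the design (one expression measurement, two correlated
phenotype readouts), not an implementation artifact, and the corresponding
acceptance check is deliberately left failing with this analysis.

The cross-strain generic signature (`generic_rank`) screens orthologous
groups that are complete in all strains, requires every strain's member to
associate at p < 0.2 with a shared direction at that strain's selected
timepoint (the timepoint with the largest survival dynamic range, ties to
the earlier one), and ranks by the average per-strain P-value; the maximum
P-value is reported alongside, and breaks ties, then OG id. Requiring sign
consistency jointly with the threshold is order-independent. OGs missing in
any strain are excluded.

## Synthetic world

The generator suite produces every pipeline input with the statistical
structure the analysis assumes:

* **Design**: the fixed 13-fermentation factorial (`fermentation_design`).
* **Phenotypes** (`generate_phenotypes`): log10 robustness is additive in
  the factor effects plus Gaussian noise (default sd 0.3 — the scale of
  technical variation in log plate counts), with effects rescaled so the
  noise-free spread matches a 5-log dynamic-range target, matching the
  observed "up to five log units". The default profile is dominated by a
  +1.8 log10 oxygen effect on heat robustness, the strongest real
  single-parameter contrast. CFU counts are Poisson draws with
  N0 = 10⁸/ml (absolute counts are never published; 10⁸ is a typical
  exponential-phase culture density) and Nt = N0·10^r, two technical
  duplicates.
* **Expression** (`generate_expression`): planted genes are linear in the
  shared (noise-free) robustness with per-gene slopes |β| ∈ [1.5, 3] and
  noise sd 0.5 on the 2-log scale; the rest is baseline noise.
* **Probe intensities** (`generate_probe_intensities`): ≥ 1 probes per ORF
  with random affinities, true log-ratios from the expression matrix,
  symmetric-in-M dye bias as a function of A, channel intensities
  reconstructed from (M, A).
* **OG map** (`generate_og_map`): one candidate OG per gene index, random
  per-strain membership, configurable completeness fraction.

What the synthetic world does **not** emulate: spatial array artifacts,
RNA degradation, probe cross-hybridization, non-Poisson plating error,
condition×time kill-curve interactions (each timepoint's deviation is
independent noise), and real orthology structure. A green recovery test
therefore establishes that the pipeline's statistics behave as designed on
data satisfying its own assumptions — not that the published gene lists are
reproducible, which would require the deposited raw arrays.

## Numerical choices and degenerate inputs

* Seeds: every generator takes an explicit integer seed; identical seeds
  give byte-identical outputs (tested).
* Zero-variance robustness, disconnected designs, unmapped probes,
  non-positive survival, single-level factors and all-zero CFU duplicates
  raise errors (typed, for censoring) rather than propagating NaN.
* Degenerate t-tests (zero pooled variance, equal means) return t = 0,
  p = 1.
* Timepoint-selection ties break toward the earlier timepoint; generic-
  ranking ties break by maximum P, then OG id.
* The lowess step guards the robust-iteration breakdown when more than half
  the residuals are exactly zero (falls back to unweighted local
  regression).

## Known limitations

* The published per-strain signature tables cannot be recomputed without
  the deposited raw array data; the package validates against the printed
  phenotype statistics and planted-signal simulations instead.
* The original study's array preprocessing software is emulated (lowess +
  per-array median scaling + probe medians), not reimplemented bit-exactly;
  its exact filtering rules are unpublished.
* The fourth strain of the published generic signature (MG1363) has no
  phenotype table in the packaged data; the generic layer is
  strain-count-agnostic and is exercised on four synthetic strains.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 7)
run_pipeline(cfg, "all")       # simulate -> phenotype -> preprocess ->
                               # associate -> generic, all TSV outputs
```

See the README for a phenotype-layer example on the packaged strain tables
with its actual printed output.
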