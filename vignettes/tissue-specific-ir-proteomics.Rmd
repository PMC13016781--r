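---
title: "Tissue-specific insulin resistance and the plasma proteome: methods"
author: "irproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific insulin resistance and the plasma proteome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irproteo)
```

## The scientific problem

Insulin resistance (IR) develops tissue-selectively: some individuals with
overweight or obesity are predominantly resistant in skeletal muscle, others
in the liver, and the two phenotypes carry different metabolic risk
profiles. Both degrees can be estimated in the same person from a standard
five-point oral glucose tolerance test (OGTT; glucose and insulin sampled at
0, 30, 60, 90 and 120 min after a 75 g glucose load), which makes it
feasible to ask, in a large cohort with plasma proteomics, *which circulating
proteins track muscle IR, which track liver IR, and which pathways they
implicate* -- while keeping the two axes mutually adjusted so each
association is independent of the other.

`irproteo` implements that analysis end to end: OGTT-derived IR indices,
mutually adjusted per-protein linear models with empirical-Bayes variance
moderation, Benjamini-Hochberg (BH) false-discovery-rate control, and
hypergeometric pathway overrepresentation analysis (ORA). Because
individual-level cohort data of this kind are typically access-restricted,
the package ships a synthetic-cohort generator with planted ground truth, so
every stage is testable and the whole pipeline can be exercised (and its
operating characteristics measured) without any external data.

## OGTT indices of tissue-specific IR

**HIRI (hepatic IR index).** The 0--30 min glucose and insulin excursions
reflect how poorly insulin suppresses hepatic glucose production. HIRI is

$$\mathrm{HIRI} = \sqrt{\mathrm{AUC}_{glucose,0\text{--}30}\times
\mathrm{AUC}_{insulin,0\text{--}30}}$$

with trapezoidal AUCs, insulin in pmol/L·h and glucose by default in
mol/L·h (`glucose_auc_unit = "mol_l_h"`). A `"mmol_l_h"` mode is exposed
because published HIRI scales vary by unit convention; the two differ
exactly by $\sqrt{1000}$, and since the degrees are min--max scaled within
the cohort afterwards (below), the choice does not affect any downstream
result. Insulin reported in mU/L is converted at a configurable 6.0 pmol/L
per mU/L (conventions range from 6.0 to 6.945).

**MISI (muscle insulin sensitivity index).** The post-peak decline of OGTT
glucose mainly reflects insulin-stimulated uptake by skeletal muscle. The
glucose curve is interpolated with a *natural cubic spline* -- with five
points an interpolating spline is the only estimable choice, and its purpose
is a better between-sample localization of the peak -- and evaluated on a
1-minute grid (`grid_step`). The peak is the grid argmax, the nadir the
argmin at or after the peak (ties towards the earliest time), and the rate
of decline is the magnitude of the ordinary-least-squares slope fitted to
the spline values on the peak-to-nadir grid. MISI is that slope divided by
the mean insulin concentration over the whole test, computed as the
trapezoidal time-average (robust to irregular sampling; an arithmetic-mean
mode is available for strict emulation of the original index). A curve that
never declines is flagged `NO_DECLINE` and assigned MISI 0, which maps to
maximal muscle IR after scaling -- preserving the "0 = sensitive, 1 =
resistant" semantics rather than dropping the subject.

**Scaling to IR degrees.** Within a cohort, HIRI is min--max scaled to
$[0,1]$ (`direction = "resistance"`), and MISI is scaled *reversed*
(`direction = "sensitivity"`), so 0 always means the most
insulin-sensitive subject and 1 the most resistant. No outlier trimming is
applied before scaling. These scaled degrees, not the raw indices, enter the
models, so each model coefficient is the contrast across the full observed
IR range.

Numerical notes: grid refinement from 1 min to 0.1 min changes MISI by well
under 1% on smooth curves (tested); window endpoints of AUCs are linearly
interpolated; duplicate sampling times are an error rather than silently
averaged.

## The per-protein model

For each protein $j$ (log2 abundance $Y_j$):

$$Y_j = \beta_{0,j} + \beta_{1,j}\,\mathrm{IR}_{muscle} +
\beta_{2,j}\,\mathrm{IR}_{liver} + \beta_{3,j}\,\mathrm{Sex} +
\beta_{4,j}\,\mathrm{Age} + \beta_{5,j}\,\mathrm{Centre} +
\beta_{6,j}\,\mathrm{BMI} + \varepsilon_j$$

Both IR degrees enter simultaneously, so $\beta_{1,j}$ is adjusted for liver
IR and vice versa; sex and center are treatment-coded factors (a
single-center cohort drops the center block with a warning -- the model
remains estimable -- whereas perfectly collinear IR axes are an error
because mutual adjustment is then meaningless). `logFC` is the IR-axis
coefficient itself: the log2-abundance difference associated with moving
across the full $[0,1]$ IR range, negative when abundance falls as IR
rises. Missing abundances are handled by per-protein complete-case
deletion, never imputation, with counts reported.

**Variance moderation.** With ~1000 proteins and a shared design, residual
variances are shrunk towards a common prior by empirical Bayes, treating
$s_j^2 \sim s_0^2 F(d_j, d_0)$. The prior $(d_0, s_0^2)$ is estimated by
matching the first two moments of $\log s_j^2$ (digamma/trigamma scale) and
the moderated variances are the standard squeeze
$\tilde s_j^2 = (d_0 s_0^2 + d_j s_j^2)/(d_0 + d_j)$; moderated t statistics
use $d_j + d_0$ degrees of freedom. Edge cases: when observed log-variances
are no more dispersed than sampling alone explains, $d_0 = \infty$ and all
$\tilde s_j^2 = s_0^2$ (a normal reference is used); exactly tied sample
variances put the prior at the common value; `moderation = FALSE` gives
$d_0 = 0$, i.e. classical per-protein OLS t-tests, which the moderated path
reproduces to machine precision in that limit (tested, and cross-checked
against the independent limma implementation).

**Two significance tiers.** The differentially abundant (DA) tier uses
unadjusted $p < 0.05$ and is the input to pathway analysis; the significant
tier applies BH across proteins per axis at $q < 0.05$. Running two tiers
resolves the tension between FDR-controlled headline proteins and the
conventional practice of feeding ORA with nominally significant sets: both
thresholds are explicit parameters (`alpha_nominal`, `alpha_fdr`).

## Pathway overrepresentation

Aptamer identifiers map to genes through an annotation table that is
generally many-to-many: one aptamer can recognize products of several genes
(1:N) and several aptamers can target one gene (N:1). DA aptamers are
mapped, deduplicated, and *counted as genes* (which is why a DA tier of 160
aptamers can become 143 mapped genes); multimapped genes are retained but
flagged, and the flag is propagated to network exports (bold-outline
convention). The universe defaults to the genes mapped from the *entire
measured panel* -- the only defensible sampling frame when the assay, not
the genome, defines what could have been observed -- with a
`universe = "collection"` switch restricting to the gene-set collection's
space.

Each set is tested with the one-sided upper-tail hypergeometric p-value;
BH is applied across the tested sets, separately per IR axis. A pathway is
reported as enriched only if it passes the dual filter: $q < 0.05$ *and* at
least ~5% of the mapped DA genes, implemented as
`floor(coverage_fraction * n)` with an explicit `min_hits` override (no
single rounding rule reproduces every published variant of the 5%
convention, so the threshold is always logged). Gene sets are read and
written in the standard GMT dialect with strict validation (malformed lines
and duplicate set names are errors, duplicate members a warning).

## The synthetic cohort generator

The generator emulates the study conditions the pipeline targets: 535
subjects across 8 centers, 61% female, age 24--63 years (mean 41.9), BMI
25.6--52 kg/m² (mean 34.4), a 1128-aptamer panel, and 5-point OGTT
sampling. Latent muscle and liver IR degrees are marginally Beta(2,2) on
$[0,1]$ -- continuous, partially overlapping phenotypes rather than discrete
groups -- coupled by a Gaussian copula with correlation `latent_rho`. The
default $\rho = 0.3$ is a free parameter (the empirical MISI--HIRI
correlation is not established); the mutual-adjustment tests use
$\rho = 0.5$ to stress cross-axis leakage.

**OGTT curves** are mechanism-light parametric shapes, not a physiological
simulation: only the statistical structure of the derived indices matters
downstream. Insulin starts at $40 + 30l$ pmol/L and peaks at 30 min with
amplitude $200 + 400l$ (liver latent $l$); glucose rises from $5.0 + 0.8l$
mmol/L by $2.0 + 2.5l$ to its 30-min peak and then declines linearly at
rate $\bar I \cdot k(m)$, where $\bar I$ is the subject's mean insulin and
the insulin-normalized uptake rate $k$ interpolates `misi_slope_range`
($1.2\times10^{-4}$ down to $1.5\times10^{-5}$ mmol/L/min per pmol/L) as
the muscle latent $m$ goes from 0 to 1. By construction MISI tracks $k$ and
HIRI is strictly increasing in $l$, so at zero measurement noise the rank
correlations between latents and recovered degrees exceed 0.99. The natural
spline smooths the peak kink and thereby inflates the fitted decline slope
by roughly 10--45% depending on the rise/decline ratio; this affects the
*absolute* MISI scale, not its ordering, which is why the generator's
contracts are stated in rank terms. Additive Gaussian noise (defaults: 0.15
mmol/L glucose, 8 pmol/L insulin) is applied last, with sub-floor values
clipped and counted.

**Proteome.** $Y_j$ is generated exactly from the fitted model's form, with
planted IR coefficients on chosen aptamers (defaults: 50 muscle-axis, 30
liver-axis, 10 both-axis proteins with magnitudes evenly spaced over
0.5--1.0 log2 units and alternating sign) and per-protein residual
variances drawn scaled inverse-chi-square ($d_0 = 4$, $s_0^2 = 0.25$) so
the moderation stage faces realistic heteroskedasticity and its prior
recovery can be tested against generating values. Covariate effects (sex,
age, center, BMI) are drawn per protein at configurable scales; sex and
center are categorical labels so downstream dummy coding must be explicit.

**Annotation and gene sets.** Aptamers draw genes from a pool of 90% of
the panel size (inducing N:1 collapses); 10% of aptamers receive a second
gene (1:N) and are flagged. Planted-enriched sets draw 80% of their members
from planted-effect genes; null sets are uniform. Everything round-trips
through the package's GMT reader.

**What the generator does *not* emulate** -- and hence what passing tests
do not show about real data: assay-level artifacts (plate effects,
hybridization normalization, calibrators), non-linear protein--IR
relations, longitudinal or intervention effects, informative missingness,
and real pathway topology. Recovery results on synthetic cohorts
demonstrate that the statistical machinery is correct and calibrated, not
that any particular biological finding replicates.

## Operating characteristics measured by the test suite

The suite (and `scripts/acceptance.R`) measures, among others: exact
closed-form agreement of HIRI/MISI on analytic curves; OLS coefficients
against brute-force normal equations; prior recovery of the moderation
estimator ($\hat d_0 \in [3,5]$ at $d_0 = 4$ with 5000 proteins);
per-axis p-value calibration and an empty FDR tier on null cohorts (300
subjects × 2000 proteins × 10 seeds); muscle-axis type-I error at nominal
level when effects are planted only on the correlated ($\rho = 0.5$) liver
axis; hypergeometric p-values against exhaustive enumeration for all
universes up to size 12; and, on the default planted cohort across 10
seeds, DA-tier sensitivity ≥ 0.9, realized FDR ≤ 0.1 in the significant
tier and recovery of all planted gene sets. These problem sizes were chosen
as the smallest at which the binomial/Monte-Carlo error bands quoted in the
tests are meaningful.

## Known limitations

* The absolute MISI/HIRI scales depend on unit conventions that published
  cohorts do not always state; only the scaled $[0,1]$ degrees are
  comparable across configurations.
* The generator's OGTT curves are piecewise-linear in their noise-free
  core; spline-based slope estimates are therefore biased upward by a
  bounded factor (see above) while remaining rank-faithful.
* BH q-values for ORA are computed within the tested sets of each axis;
  with very small collections the discreteness of the hypergeometric makes
  the procedure conservative.
* No interaction terms (e.g. sex × IR) and no robust/quantile regression;
  group-based IR phenotyping is deliberately out of scope in favor of the
  continuous two-axis model.
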