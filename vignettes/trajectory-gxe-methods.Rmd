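---
title: "Methods: latent class growth analysis and bias-adjusted G×E regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent class growth analysis and bias-adjusted G×E regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ptstraj` implements a trajectory-based gene-by-environment analysis for
short longitudinal posttraumatic stress (PTS) symptom series: (1) latent
class growth analysis (LCGA) of three-wave PCL-C totals, (2)
fit-statistic-driven class enumeration, and (3) classification-error
adjusted multinomial regression of trajectory class membership on SNP
genotype dosage, childhood physical abuse severity, and their interaction,
with supporting scale scoring, genotype QC, gene–environment correlation,
and cross-tabulation decompositions. Because the motivating cohort data are
not publicly deposited, the package ships a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, so every stage
is verifiable by parameter recovery.

# The model

## LCGA

Let $y_{it}$ be subject $i$'s PCL-C total at wave $t \in \{0, 1, 2\}$
(waves are coded equally spaced; the study waves were approximately one
year apart, and the printed growth coefficients reproduce the printed wave
means under this coding). The model is a $K$-component mixture of quadratic
mean curves,

$$y_{it} \mid C_i = k \;\sim\; \mathcal N\!\big(\beta_{0k} + \beta_{1k} t +
\beta_{2k} t^2,\; \sigma^2_t\big),$$

independent across observed waves given class, with mixing proportions
$\pi_k$. The defining LCGA restriction is that within-class growth-factor
variances are zero: each class is a deterministic curve plus wave noise.
With three waves the quadratic mean is saturated (three coefficients, three
waves), which is exactly why the restriction makes quadratic growth
estimable here; a full growth mixture model (random growth factors) is out
of scope.

Missing waves contribute nothing to the observed-data likelihood (MAR);
wave 1 is required for every subject, mirroring the inclusion rule of the
motivating design.

**Residual structure.** The default is wave-specific, class-invariant
$\sigma^2_t$ (3 free variances) — the conventional default for this model
family, keeping the parameter count small with three waves. A per-class
option (`residual = "class_wave"`) exists. In the package's own recovery
studies the per-class fit at $n = 473$ is noticeably less stable (flexible
variances let the optimizer merge or split classes), so the default is used
throughout the verification experiments.

**Estimation** is multi-start (E)CM: the E-step computes posteriors in log
space; the M-step updates $\pi$, then the growth coefficients by
inverse-variance-weighted least squares given the current $\sigma^2$, then
$\sigma^2$ given the new coefficients (a conditional-maximization cycle,
monotone in the log-likelihood, which the test suite asserts on every
fit). Starts come in three families — k-means on mean-imputed wave scores,
randomly drawn subjects as class-curve seeds, and random perturbations of
the pooled quadratic fit — because mixtures of curves are multimodal and,
when one class dominates, k-means alone keeps splitting the dominant
cluster instead of seeding the small ones.
Convergence is declared at relative log-likelihood change below `tol`
(default `1e-6`, maximum 2000 iterations). A start is abandoned if a class
weight falls below $10^{-6}$ or a residual variance collapses below
$10^{-4}$ — unless classification is already essentially perfect, the
noise-free separated limit, where the boundary solution is the MLE.
Classes are reported in canonical order (descending mean fitted trajectory,
ties by descending intercept) and modal ties are broken toward the lower
canonical index; both rules are arbitrary but fixed, making output
deterministic given the seed.

## Class enumeration

For each candidate $K$ the package reports
$\mathrm{BIC} = -2\ell + p\log n$ and the sample-size-adjusted
$\mathrm{aBIC} = -2\ell + p\log\{(n+2)/24\}$ (the standard adjustment;
"adjusted BIC" is ambiguous in print, so the formula is stated
explicitly), the normalized entropy
$1 - \sum_{ik} (-\tau_{ik}\log\tau_{ik})/(n \log K)$, and each class's
average posterior probability among its modally assigned subjects. The
free-parameter count $p = (K-1) + 3K + \#\{\text{free } \sigma^2\}$ is
always recomputed from the parameter object.

The $k$ vs $k-1$ test is a **parametric bootstrap likelihood-ratio test**:
null data are simulated from the fitted $(k-1)$-class model with the
observed missingness pattern, both models are refit per replicate with
reduced starts, and $p = (1 + \#\{T_b \ge T_{obs}\})/(B + 1)$. The
motivating analysis used the Lo–Mendell–Rubin adjusted test, for which no
complete formula is in general circulation; the bootstrap test is fully
specified and distributionally valid and plays the same role (comparable
in role, not numerically identical — printed LMR p-values are therefore
not reproduction targets). The enumeration table flags the smallest $K$
whose successor fails the test, but the full table is always emitted:
class enumeration is a judgment call and the flag is advisory.

## Three-step covariate regression

Regressing the *modal* class on covariates underestimates associations,
because modal assignment is a noisy version of the latent class. The
package implements the maximum-likelihood three-step correction: from the
fitted posteriors build the classification-error matrix

$$D_{ks} = P(\text{modal} = s \mid C = k)
        = \frac{\sum_i \tau_{ik}\, \mathbf 1(m_i = s)}{\sum_i \tau_{ik}},$$

then maximize
$\sum_i \log \sum_k P(C_i = k \mid x_i; \gamma)\, D_{k, m_i}$
over multinomial-logit coefficients $\gamma$ with a fixed referent class.
With $D = I$ this is exactly standard multinomial regression on the modal
class (asserted against an independent iteratively-reweighted
implementation in the tests); with $D$ from an imperfect classification it
undoes the attenuation, which the test suite demonstrates directly: at
classification entropy near 0.8 the corrected estimator's absolute bias
for a generating log-odds is an order of magnitude below the naive modal
estimator's.

Optimization is BFGS with an analytic gradient on internally standardized
predictors, mapped back to the raw scale; standard errors are the inverse
observed information at the optimum. As in the standard three-step
procedure, they ignore step-1 uncertainty in $D$ — a documented
limitation. All pairwise class contrasts are linear combinations of one
fit's coefficients, so odds-ratio transitivity across referent rotations
holds exactly.

The main-effects design is additive dosage (copies of the minor allele)
plus age, gender, and two ancestry principal components; the interaction
design adds the abuse score on its raw 0–24 scale (uncentered — per-unit
odds ratios are reported and no centering was documented in the motivating
analysis; a centering flag exists) and the dosage-by-abuse product. The
full hierarchical model is fit and every term reported. Covariates are
handled complete-case with a logged drop count. Findings are flagged at
the nominal 0.05 level and at 0.05 divided by the number of SNPs analyzed
(both flags retained).

## Descriptives and QC

PCL-C totals sum 17 items (1–5) to 17–85; the probable-PTSD cut-off is 44.
The boundary convention is genuinely ambiguous ("exceeding" suggests
strict, common practice uses $\ge$): the default counts 44 as probable
(`rule = "gte"`), the strict rule is a flag, and the choice affects
descriptives only. CTS physical-assault totals sum six items (0–4) to
0–24. Genotype QC applies call rate $> 0.95$, MAF $> 0.01$, and exact HWE
$p > 10^{-6}$, with the exact test computed by full enumeration over
heterozygote counts (a chi-square version is kept for cross-checking; note
the exact two-sided tail is asymmetric, so the two agree closely at and
below Hardy–Weinberg-expected heterozygosity but can differ by ~0.1 in
p-value with a heterozygote excess). Gene–environment correlation is
Spearman's rank correlation with midranks (dosages are heavily tied) and a
t-approximation p-value. Median splits assign ties at the median to the
low stratum (undocumented in the motivating analysis; fixed and logged
here). Cross-tabs always carry counts beside percentages so every
percentage is re-derivable.

# The synthetic-data generator

`simulation_spec()` defaults encode the printed structure of the
motivating cohort:

* four classes — low, decreasing, increasing, high — with proportions
  0.681 / 0.173 / 0.080 / 0.066, quadratic coefficients
  (26.60, −0.87, −0.04), (53.53, −33.76, 11.73), (37.85, 19.24, −5.56),
  (70.06, −30.69, 12.77), and per-class wave SDs taken from the printed
  by-class wave SDs;
* biallelic SNPs drawn Binomial(2, MAF) (HWE) at MAFs 0.12 and 0.11;
* abuse scores from a negative binomial truncated to 0–24, calibrated so
  the *truncated* law has mean 3.59 and SD 3.81 (plain truncation shaves
  the SD a few percent); six CTS items are decomposed from the total;
* covariates: 57.5% female, age $\mathcal N(53.35, 15.58^2)$ floored at
  18, ancestry PCs $\mathcal N(0, 0.05^2)$ and $\mathcal N(0, 0.01^2)$;
* class membership from a multinomial logit on dosage, abuse, and their
  product, with intercepts calibrated so class probabilities equal the
  target shares at the covariate means — exact marginal control when all
  effects are zero, without rejection sampling;
* independent per-wave retention 276/473 at wave 2 and 217/473 at wave 3
  (the motivating study reports no dropout mechanism; MCAR is assumed,
  with an optional monotone mode);
* scores are *continuous Gaussians by default, not clipped* to 17–85: the
  LCGA likelihood is Gaussian and clipping would bias recovery
  experiments. A clip flag exists for realism studies.

What the generator does **not** emulate: item-level PCL-C measurement,
informative dropout, linkage disequilibrium between SNPs, and population
structure beyond two Gaussian PC covariates. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under the
stated generating structure, not robustness to these real-data features.

# Verification experiments and their calibration

`recovery_experiment()` simulates 25 cohorts at $n = 473$, refits the
4-class model with 50 starts, and averages: the modal shares of the
matched low and high classes, the decreasing class's linear slope, the
high class's quadratic term, entropy, and mean AvePP.
`or_recovery_experiment()` simulates cohorts of $n = 5000$ with a per-copy
high-vs-low log-odds of $\log 3.64$ (and, for the interaction study, a
per-abuse-unit per-copy log-odds of $\log 1.32$), runs the full
three-step pipeline, and averages the recovered log odds ratio over 10
replicates — the single-replicate Wald SE (~0.12 on the log scale for the
main effect) is comparable to the recovery tolerance, so averaging
suppresses Monte-Carlo noise exactly as the 25-replicate trajectory
experiment does.

Two design points deserve emphasis.

**Label switching** is resolved by matching each fitted class to the
generating class with the nearest trajectory (least squares over the three
wave means). Heuristics such as "the class with the most negative linear
slope" misidentify classes here: the high class's generating slope
(−30.69) is close to the decreasing class's (−33.76), and sampling noise
at 31 expected subjects frequently makes a fitted high-class variant the
steepest.

**Modal shares are not mixture weights.** The generator uses the printed
class shares — which are modal-assignment counts — as mixing proportions,
and the printed by-class wave SDs — which are modal-conditional — as
generating noise. Both choices follow the printed tables, but they have a
measurable consequence: modal assignment under the refitted model inflates
the largest class's share (scoring with the *true* generating parameters
already yields 70.4% against a generating 68.1%) and sharpens posteriors
(truth-scored AvePP 0.89 against the printed 0.87). The recovery
experiments therefore reproduce the growth coefficients, the smallest
class's share, the regression odds ratios, and (near the top of their
bands) entropy and AvePP, while the largest-class share (~71-72% against
a printed 68.1%) sits a little outside, for these structural reasons
rather than estimation error. The numbers are what the package's own
experiments compute; they are not adjustable without abandoning the
printed calibration.

Problem sizes used throughout the test suite (25 × $n=473$ trajectory
replicates; 10 × $n=5000$ regression replicates; 200-replicate bootstrap
calibration at $n = 80$ with 19 bootstrap draws; 200-replicate bias study
at $n = 700$) were chosen as the smallest designs whose Monte-Carlo error
is well below the quantities being checked.

# Reproducible pipeline

`run_pipeline()` chains simulate/load → QC → enumeration → final fit →
three-step models → cross-tabs into a report bundle (tab-separated tables
with counts beside every percentage, a per-subject posterior export, a
trajectory figure, and a manifest with versions, sub-seeds, and a config
hash). Every stage derives its seed by hashing the stage name with the
master seed, so adding a stage never perturbs earlier stages' random
streams, and a fixed master seed reproduces the bundle byte-identically.

# Known limitations

* Three-step standard errors ignore the sampling variability of the
  classification-error matrix.
* The bootstrap LRT is not the LMR test; printed LMR p-values are not
  comparable numerically.
* LCGA assumes MAR given class; informative dropout is neither modeled
  nor simulated.
* With three waves the quadratic mean is saturated, so per-class fit
  cannot be criticized within class; model criticism operates across
  classes via the enumeration statistics.
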