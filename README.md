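# ptstraj

Trajectory-based gene-by-environment analysis of posttraumatic stress:
latent class growth analysis (LCGA) of three-wave PCL-C symptom totals,
fit-statistic-driven class enumeration, and classification-error-adjusted
three-step multinomial regression of trajectory membership on SNP genotype
dosage, childhood physical abuse, and their interaction.

## Who this is for

Epidemiologists and psychiatric-genetics researchers analyzing short
longitudinal symptom panels: cohorts where each subject has a baseline and
one or two follow-up PCL-C totals (follow-ups possibly missing), candidate
SNP genotypes, an abuse-severity exposure, and survey covariates. The
package covers the full workflow — scale scoring, genotype QC, trajectory
modeling, class enumeration, bias-adjusted covariate regression,
cross-tabulation decompositions — plus a synthetic-cohort generator with
the same statistical structure, so the whole pipeline is verifiable by
parameter recovery without restricted data.

## The model

LCGA is a K-component mixture of quadratic growth curves with the
within-class growth-factor variances fixed at zero:

    y_it | C_i = k  ~  Normal(b0k + b1k·t + b2k·t²,  σ²_t),   t = 0, 1, 2

estimated by multi-start EM on the observed-data likelihood (missing waves
drop out under MAR). Class enumeration uses BIC, adjusted BIC
(−2LL + p·log((n+2)/24)), entropy, per-class average posterior
probabilities, and a parametric bootstrap likelihood-ratio test of k vs
k−1 classes.

The regression step avoids the attenuation of regressing on modal class
assignments: from the posteriors τ it builds the classification-error
matrix `D[k,s] = P(modal s | true k)` and maximizes

    Σ_i log Σ_k P(C = k | x_i; γ) · D[k, modal_i]

over multinomial-logit coefficients γ — standard multinomial regression
when D = I, bias-corrected otherwise. Results are reported for every
pairwise class contrast (odds-ratio transitivity holds exactly), with
nominal and Bonferroni-corrected significance flags.

## Worked example

```r
library(ptstraj)

# a synthetic cohort with a per-copy genotype effect on the high-vs-low
# trajectory contrast
spec <- simulation_spec(
  n_subjects  = 2500,
  effect_spec = list(genotype = c(0, 0, 0, log(3.64)), snp = 2L),
  seed        = 19)
cohort <- simulate_cohort(spec)

fit <- fit_lcga(cohort, K = 4, n_starts = 10, seed = 4)
label_trajectories(fit)
#> [1] "high"       "increasing" "decreasing" "low"

res <- run_main_effects_model(cohort, fit, "snp2")
ct  <- res$contrasts
ct[ct$contrast == "high_vs_low" & ct$predictor == "dosage",
   c("or", "ci_lo", "ci_hi", "p_value")]
#>        or    ci_lo    ci_hi      p_value
#> 2 3.42692 2.497869 4.701519 2.278007e-14
```

The generating per-copy odds ratio for membership in the chronically
elevated ("high") trajectory versus the consistently low one is 3.64; the
three-step regression recovers 3.43 with a 95% Wald interval (2.50, 4.70)
at this cohort size. `run_interaction_model()` adds the abuse score and
the dosage-by-abuse product; `enumerate_classes()` produces the
fit-comparison table; `run_pipeline(run_config(...))` chains everything
into a reproducible report bundle under one master seed.

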