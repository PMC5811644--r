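# mesoinvade

Analysis toolkit for substitutive (replacement-series) mesocosm experiments
that test the **biotic resistance** of native plant communities to an
introduced species: does native diversity suppress an invader's ability to
colonize and grow, and if so, through which biodiversity mechanism?

The package is aimed at plant and invasion ecologists running small-scale
diversity–invasibility experiments with a blocked design: a species pool
split into functional groups, treatments spanning bare sediment,
monocultures, two-species communities and a full mixture at constant
planting density, and an invader introduced into every unit. It implements
the full statistical pipeline for such a design and ships a seeded
synthetic-data generator emulating a 12-treatment × 6-block (72-mesocosm)
layout with four natives in two functional groups (rooted: M, P; non-rooted:
C, U) plus a rooted invader, so every stage runs and is testable without any
external data.

## What it computes

**Colonization (exact inference).** Colonization indicators are compared
between groups with the exact conditional test on the 2×2 table: with both
margins fixed, the first cell is hypergeometric under the null, and the
two-sided p is the total probability of tables no more probable than the one
observed. The reported odds ratio is the conditional MLE — the ψ of Fisher's
noncentral hypergeometric distribution maximizing the likelihood of the
observed cell — found by monotone root-finding on the conditional mean
equation E<sub>ψ</sub>[X] = a. Both are implemented from first principles in
log space.

**Growth metrics.** Relative growth rate RGR = (ln W_f − ln W_i)/t
(g g⁻¹ DW day⁻¹), root:shoot ratio, and per-treatment mean ± SD summaries.

**Mixed models.** Random-intercept models with block as the random factor.
The linear mixed model is fitted by profiling the likelihood down to the
variance ratio λ = σ²_block/σ²_resid (closed-form GLS given λ, 1-D search
polished on the analytic score; ML and REML). The logistic mixed model uses
a Laplace approximation with per-block Newton inner steps. Fixed factors are
tested by ML likelihood-ratio tests; treatment contrasts against bare
sediment use containment degrees of freedom; Tukey pairwise comparisons of
functional groups use the studentized-range distribution with a Bonferroni
threshold (4 levels → 6 pairs → 0.05/6 ≈ 0.008).

**Hurdle analysis.** Invader root biomass is zero-inflated: stage 1 models
root presence/absence (logistic mixed model), stage 2 models ln(root mass)
among colonized units (linear mixed model), each with its own LRT.

**Additive partitioning.** The net diversity effect of a mixture,
ΔY = Y_O − Y_E with Y_E = Σᵢ RY_E,ᵢ·Mᵢ and RY_E,ᵢ = 1/N (substitutive
design), is split into

- complementarity effect CE = N · mean(ΔRY) · mean(M), and
- selection effect SE = N · cov(ΔRY, M) (population covariance),

where ΔRYᵢ = Y_O,ᵢ/Mᵢ − RY_E,ᵢ, so CE + SE = ΔY exactly. Percent
overyielding relative to the average monoculture is also reported.

## Worked example

```r
library(mesoinvade)

recs <- simulate_experiment(calibrated_scenario(seed = 42))

compare_colonization(recs)
#> 2x2 exact test: a=6 b=60 c=5 d=1
#>   two-sided p = 0.000199, conditional-MLE odds ratio = 0.022

d <- add_design_factors(recs)
h <- hurdle_analysis(model_spec("invader_root", "richness",
                                fixed_type = "numeric"), d)
round(unname(h$stage1$beta["richness"]), 3)   # -2.66  (LRT p = 2.3e-06)
round(unname(h$stage2$beta["richness"]), 3)   # -0.631 (LRT p = 0.21)

p <- partition_experiment(recs)
round(p$summary[p$summary$treatment_id == 12, ], 3)
#>   treatment_id n delta_Y_mean delta_Y_sd CE_mean CE_sd SE_mean SE_sd
#> 7           12 6          0.1      0.352  -0.484 0.337   0.584 0.113
```

Reading this run: vegetated mesocosms were colonized in 6/66 units against
5/6 bare units — odds of colonization with natives present are ~2% of the
bare-sediment odds (p ≈ 2×10⁻⁴). Root formation drops steeply with richness
(stage-1 coefficient −2.66 per species on the logit scale); conditional root
biomass also trends down but with little power at n = 11 colonized units.
The four-species mixture overyields (ΔY > 0 on average) through a positive
selection effect (SE = 0.58 g: productive rooted species dominate) against a
negative complementarity effect — the qualitative fingerprint the generator
is calibrated to.

A full report bundle (validation, summaries, exact test, hurdle and LMM
tables, Tukey/Bonferroni comparisons, partition, manifest):

```r
run_full_analysis(list(scenario = "calibrated", seed = 42, out_dir = "out"))
```

or from the shell via the installed CLI script:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mesoinvade", package="mesoinvade"))')" \
  run --scenario calibrated --seed 42 --out out/
```

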