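---
title: "Methods and design notes for patgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for patgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models, the tunable parameters and why their defaults are
what they are, the numerical choices, what the synthetic-data generator
does and does not emulate, and the design decisions taken where more than
one reasonable choice existed.

## The model

A GWAS z-score for a standardized trait is `s = β̂ √N / σ̂`, which under
the null is `N(0, 1)`. For one variant observed across `T` traits the
vector `S = (s_1, …, s_T)` is modelled as zero-mean multivariate normal
with covariance `Σ = Σe + Σg`:

- **Environmental covariance** `Σe`: the diagonal is exactly 1 (unit null
  variance of a z-score, by construction). Off-diagonals exist only when
  the same individuals contribute to two traits:
  `Σe[i,k] = (N_shared[i,k]/√(N_i N_k)) · ρe[i,k]`. With disjoint cohorts
  `Σe = I` regardless of how environmentally correlated the traits are.
- **Genetic covariance** `Σg`: under the polygenic model the per-variant
  effect sizes are `β ~ N(0, σg²)` with cross-trait covariances
  `σg[i,k]`; on the z-score scale `Σg[i,k] = √(N_i N_k) · σg[i,k]`.
  Sample overlap does not enter `Σg`.

The omnibus test (PAT) is the likelihood ratio of
`N(0, Σe + Σg)` against `N(0, Σe)`, kept and compared in **log space**
throughout: at genome-wide-significant z-scores the raw ratio overflows
double precision. Rejection is strict (`stat > κ`); a statistic exactly
equal to the critical value is not significant. When there is no
environmental correlation PAT is comparable to a Wald test, and at
`T = 1` the statistic is a monotone function of `z²`, so the test
reproduces the classical two-sided z-test exactly — a property the test
suite exploits as an oracle.

Both `Σe`'s ingredients (`ρe`, overlap counts) and `σg` are **inputs**,
typically from cross-trait LD-score regression; the package deliberately
does not estimate them. The model matrices are constant across the
genome; per-variant sample sizes are supported in the data structures,
but the default treats `N` as constant per trait (the median over
variants) — rebuilding `Σe`/`Σg` per unique `N`-tuple is possible but
rarely changes results materially, and a constant-`N` model keeps one
calibration valid for all variants.

## Calibration by importance sampling

Analytic tail approximations for the LR statistic (a χ² mixture) are
avoided in favour of null simulation. Plain Monte Carlo needs on the
order of `10/α` draws to resolve level `α`; at `α = 5×10⁻⁸` that is
prohibitive. Instead draws come from the fattened proposal
`V ~ N(0, rΣe)` and each is weighted by
`w = P(V|0,Σe) / P(V|0,rΣe)` (computed in log space). The tail
probability of a threshold `t` is then `Σ{w_i : stat_i ≥ t} / Σ w_i`.

- `r = 1` reduces to plain Monte Carlo with all weights exactly 1 (the
  code special-cases nothing: the identity falls out of the formula).
- Defaults `n = 10⁶`, `r = 2`: this operating point resolves
  `α = 5×10⁻⁸` stably; the test suite checks that two independent
  calibrations imply each other's critical value within 50% relative
  error in p, and that the weighted estimator is unbiased against plain
  Monte Carlo for `r ∈ {1.5, 2, 3}`.
- `r < 1` is rejected (the proposal must fatten, not thin, the tails).
- p-values are a conservative step function: ties at the threshold count
  toward the tail, and no interpolation is performed between adjacent
  simulated statistics (the choice is conservative and the simplest to
  reason about).
- The smallest achievable p-value, `min(w)/Σw`, is returned (flagged)
  instead of 0 when an observed statistic exceeds every draw.
- A calibration records the model matrices it was built under and
  refuses to serve a different model.

The MI GWAS baseline (reject when `max_i |s_i|` exceeds a threshold) is
calibrated the same way. Its null simulations use `Σ = I` by default even
when overlap exists, because the method is defined for disjoint cohorts;
a flag (`migwas_use_sigma_e`) opts into the overlap-aware null. The
Bonferroni alternative `z = Φ⁻¹(1 − α/2T)` is provided in closed form.

## M-values and the causal-count rescaling

For interpretation, each of the `2^T` effect configurations `c` gets the
posterior predictive density `N(S; 0, Σe + (M/Q)·Σg(c))`, where `Σg(c)`
zeroes rows/columns of traits without an effect. The m-value of trait
`i` is the mass fraction of configurations with `c_i = 1`. Choices:

- **Uniform prior over configurations.** The sum is unweighted; the
  all-zero (global null) configuration stays in the denominator. This is
  stated explicitly because a non-uniform prior would be equally
  defensible; the unweighted sum is the convention adopted here.
- **Strict threshold.** `m_i > 0.9` is "associated", `m_i = 0.9` is
  ambiguous. The 0.9 is a convention, not a frequentist error rate —
  though simulations in the test suite confirm it behaves as a very
  conservative bound on the false-assignment rate.
- **Rescaling `Σg` by `M/Q`.** Under the polygenic model with millions of
  variants, `Σg + Σe ≈ Σe` and configurations are indistinguishable. `Q`
  (the effective number of causal variants) is fitted by maximizing
  `Σ_i log N(S_i; 0, (M/Q)Σg + Σe)` over thinned significant variants.
  Thinning takes one uniformly-sampled significant variant per **fixed
  100 kb genomic bin** (coordinates converted to 0-based half-open
  internally). Fixed bins rather than variant-anchored intervals: the
  choice is documented because either reading is defensible; fixed bins
  are deterministic given the seed and independent of variant order.
- **Grid.** 512 geometrically spaced integer candidates over `[1, M]`
  (geometric because `M/Q` acts as a scale parameter), deduplicated,
  then one linear refinement pass between the geometric neighbours of
  the best point. Ties break toward the smallest `Q` — the most
  polygenic, hence most conservative, reading.
- **One global `Q`** shared by all traits; per-trait causal counts are a
  known limitation.
- Each configuration's covariance is Cholesky-factorized once and reused
  for all variants; the mass ratios use log-sum-exp. Enumeration is
  guarded at `T ≤ 15`.

## Numerical choices

- **Cholesky everywhere**: log-determinants and quadratic forms come from
  one `chol()` per covariance; nothing is ever explicitly inverted. The
  test suite checks the optimized path against a naive
  dense-inverse/determinant oracle at 10⁻¹⁰.
- **PSD repair**: externally estimated covariance matrices are routinely
  indefinite at rounding level. Eigenvalues in `(−10⁻⁸·λmax, 0)` are
  clipped to zero with a warning; anything more negative is a hard error
  — silent large repairs hide upstream bugs.
- `Σe`'s diagonal is forced to exactly 1 whatever the input, because
  z-scores have unit null variance by construction.
- Degenerate inputs fail fast with named errors: `r < 1`, `α` below the
  calibration floor, missing positions for clumping, `β_disc = 0` in the
  directional replication test, non-square or misordered trait matrices.

## Harmonization rules

Variants join across traits on chromosome, position, and the unordered
allele pair (robust to RSID drift); per-trait z (and β) are negated when
ref/alt are swapped relative to the first trait; variants matching
neither orientation are dropped and counted. QC keeps biallelic SNPs
with `MAF > 1%` and `INFO > 80%`, drops strand-ambiguous pairs
(A/T, C/G), and treats records missing MAF/INFO as failing an enabled
filter (fail-closed, overridable) — the conservative reading. Flips are
an involution and harmonization is idempotent; both are property-tested.

## Replication analytics

- **Clumping**: greedy, best score first (largest m-value, or smallest
  p-value under the p-rule), suppressing everything on the same
  chromosome within a 1 Mb window *centered* on the lead
  (`[lead − 500kb, lead + 500kb)`, half-open). "Within a 1 Mb region" is
  ambiguous; the centered half-open reading is documented and the greedy
  result is verified against exhaustive selection. Score ties break to
  the smaller coordinate.
- **Directional test**: `z_rep = sign(β_disc)·β_rep/se_rep`,
  `p = 1 − Φ(z_rep)`, Bonferroni-adjusted per set of leads.
- **Concordance**: exact binomial upper tail via `pbinom` (the printed
  p-values of interest, down to 10⁻¹⁸⁴, are far beyond the normal
  approximation; `pbinom` performs the exact summation in stable form).
- **Power**: standardized-trait model, genotype variance `2·maf(1−maf)`,
  non-centrality `|β|·√(2·maf(1−maf)·N_rep)`; labelled approximate
  because MAF often comes from a reference panel rather than the
  replication cohort itself. When both cohorts report MAF the
  replication cohort's value is used.

## The synthetic-data generator

`gen_zscores()` draws rows i.i.d. from the marginal
`N(0, Σe + mask_c(√(N_i N_k)·σh²[i,k]/causal))`. Drawing from the
marginal is distributionally identical to drawing per-variant effects and
adding unit noise, and one matrix product per block is far cheaper; the
generator's sample moments are verified against the target covariance.

What it emulates: the covariance structure of z-scores across traits
under configurable effect configurations, sample overlap, and effect
sizes expressed as "heritability spread over `causal` variants"
(`Σh²/causal` per variant, so fewer causal variants means larger
effects). What it does **not** emulate: linkage disequilibrium between
variants (rows are independent; synthetic positions are only used to
exercise windowing logic), allele-frequency-dependent effect sizes,
genotyping/imputation artefacts, and population stratification. Passing
simulation-based tests therefore demonstrates the statistical machinery
under the stated model, not robustness to those real-data features.

The four-trait covariance panel used by the test suite and the
acceptance script is a **synthetic stand-in** emulating large-biobank
anthropometric and blood-pressure traits: heritabilities
(0.25, 0.15, 0.45, 0.15), genetic correlations of 0.75 between the two
blood-pressure traits and ~0.1–0.3 elsewhere, environmental correlations
of 0.65 between the blood-pressure traits and ~0.05–0.25 elsewhere, one
fully overlapping cohort of 360,000. These are field-typical magnitudes
chosen once when the panel was designed; they are not estimates from any
particular dataset, and experiment outcomes under this panel (power
counts in particular) characterize the panel, not any published cohort.

The layered power design simulates a 90% null block plus all 15
non-empty configurations of four traits at three effect-size levels
(`causal` = 40k, 24k, 16k; block sizes 5k/3k/2k before scaling), with
the analysis model deliberately polygenic (`Σg = Σh²/total variants`) —
i.e. misspecified relative to the sparse generative truth, as in real
GWAS. The tests and the acceptance script run this design at 1/10 scale
(150,000 variants) and the m-value accuracy experiments at 10⁶ (script)
or 2×10⁵ (tests) variants with calibrations of 10⁶ draws; these sizes
give comfortable Monte-Carlo resolution for the rates being checked
while keeping a full run in the tens of seconds.

Power-targeted experiments (e.g. "PAT power = 50%") calibrate the
genetic-scale multiplier by bisection using common random numbers — one
fixed standard-normal draw reused across candidate multipliers, making
the estimated power monotone in the multiplier and the search
deterministic under its seed.

## Known limitations

- One global covariance structure genome-wide; local (per-region)
  `Σe`/`Σg` would be a straightforward extension since every variant is
  tested independently, but is not implemented.
- m-values do not control a frequentist false-assignment rate; they are
  an interpretive posterior quantity.
- Exact configuration enumeration limits interpretation to moderate `T`.
- No winner's-curse correction in the replication power calculation; the
  expected replication counts are optimistic for newly significant
  variants.
- INDELs, multi-allelic sites, VCF input and liftover are out of scope
  for the harmonizer.
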