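---
title: "Analysing magnitude-estimation experiments with magscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing magnitude-estimation experiments with magscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magscale)
```

## The scientific problem

In a magnitude-estimation experiment an observer rates the perceived
intensity of test stimuli relative to a constant reference stimulus (the
*modulus*), which is arbitrarily assigned the value 10. A stimulus
perceived twice as intense as the reference should be rated 20; one half
as intense, 5. The classical summary of such data is Stevens' power law,

$$\psi(I) = k\,I^{a},$$

where $\psi(I)$ is perceived intensity, $I$ physical intensity, $a$ the
exponent (compressive below 1, expansive above 1) and $k$ a
proportionality constant. Because ratings are *ratios* to the modulus, a
long-standing methodological worry is that observers struggle with the
asymmetry of the response scale: below the reference only the interval
(0, 10) is available, above it the whole half-line. Observers who think
in *differences* rather than ratios will compress their below-reference
ratings, which biases the fitted exponent.

`magscale` packages the full analysis chain used to study this question:

1. a trial-level simulator of rating experiments under per-participant
   power laws, for four response formats (standard, reversed scale,
   two-step unidirectional, and a binary-choice-then-standard control);
2. the preprocessing rules for such data (zero-flooring, reciprocal
   recoding onto the standard scale, direction-error exclusion, log
   transform);
3. repeated-measures and mixed 2 × 8 ANOVA with Greenhouse–Geisser
   correction and generalized $\eta^2$;
4. hierarchical Bayesian power-law and linear mixed models with fixed
   priors, fitted by MCMC;
5. bridge-sampling marginal likelihoods, log Bayes factors, WAIC and
   PSIS-LOO;
6. posterior predictive checks and a single-call pipeline.

## Stimulus sets and scale conventions

Two stimulus sets are built in, mirroring their colorimetric tables
column for column: nine achromatic luminances (1.0–100.0 cd/m²,
reference 10.0 cd/m², four test stimuli on each side of the reference)
and nine red patches of constant lightness and hue whose CIE LCh
saturation ranges from 15 % to 85 % nominal (reference 50 %). The
saturation of a colour is computed from chroma and lightness as
$S = C^*/\sqrt{C^{*2} + L^{*2}} \times 100$, the standard LCh saturation
measure; it is scale-invariant and monotone in chroma.

All modelling happens on normalized scales: the response is the rating
divided by 100 and the predictor is the luminance as a fraction of the
maximum presented luminance (so the reference sits at $x = 0.1$) or the
nominal saturation fraction (reference $x = 0.5$). With these
conventions the population constant of the power model is pinned near
$0.1\,x_{\mathrm{ref}}^{-a}$ by the modulus, and fitted parameter
magnitudes are directly comparable across the two stimulus dimensions.
This normalization is a package convention chosen so that parameters,
marginal likelihoods and information criteria live on interpretable,
dimension-free scales.

## The synthetic-participant generator

`population_spec()` describes a participant population: means and
standard deviations of $k$ and $a$ (both drawn from normals truncated at
zero), residual noise on the normalized response scale, the number of
participants and repetitions (8 test stimuli × 5 repetitions = 40 trials
per condition), and a seed. `study_population(study, method)` returns
the conditions of each experimental arm the package emulates:
16–20 participants per arm, exponent populations centred at 0.44/0.55
(luminance) or 1.99/1.73 (red saturation) with between-participant SDs
of 0.18–1.01, residual SDs of 0.03–0.05, and direction-error rates of
0.14 %–2.22 % for the formats with a binary judgment. These values are
the package's fixed emulation targets, not tuning knobs.

Three properties of the generator deserve emphasis:

* **The constant $k$ cancels.** A rating is
  $10\,\psi_j(I)/\psi_j(I_{\mathrm{ref}})$, so any participant-specific
  proportionality constant divides out — this is exactly what the
  modulus is for. Between-participant variation in the *fitted*
  intercept therefore arises from exponent variation, not from $k$.
* **Response formats are algebraically linked.** With zero noise the
  reversal rating is $100/r_{\mathrm{standard}}$ trial for trial, and
  the unidirectional rating is $10\max(f, 1/f)$ with a direction flag,
  so the preprocessing back-transforms can be tested exactly.
* **Format constraints are enforced.** Unidirectional ratings are
  clipped at the modulus (the format only admits magnitudes of at least
  10); the other formats are truncated at zero. Zeros in the simulated
  standard format arise from noise truncation at low intensities, which
  produces somewhat more zeros than human observers typically type —
  the zero-flooring stage is exercised either way.

An explicit *anchoring bias* transform operationalizes
difference-thinking: for below-reference trials the unbiased rating
$10f$ is blended with a difference-responder's rating
$\max(0, 10 - c(1/f - 1))$ with weight $1-\lambda$. The functional form
is an invention of the package (the hypothesis it encodes is verbal in
the literature); $\lambda$ and $c$ are simulator knobs with no empirical
estimates behind them, and $\lambda = 1$ is exact identity.

The generator does **not** model adaptation, trial-order effects, range
or location effects, individual lapses, or digit preferences in numeric
entry. Passing tests on generated data therefore demonstrate the
correctness and calibration of the estimators under the stated
generative model, not robustness to everything real observers do.

## Preprocessing

The pipeline order is fixed: floor exact zeros to 0.001 (so that
reciprocal recoding and the log transform are defined), exclude trials
whose binary direction judgment contradicts the objective intensity
relation to the reference, recode reversal ratings (all trials) and
below-reference unidirectional ratings by $r' = 100/r$, then take
natural logs. The reciprocal recode is an involution with fixed point
10. The direction-error criterion — disagreement with the objective
relation — is the single documented rule; trials at the reference
intensity cannot occur because the reference is never a test stimulus.
A `preprocess_report` carries the bookkeeping (zeros floored, trials
excluded, fractions) alongside every cleaned dataset.

## ANOVA

The ANOVAs operate on participant × method × stimulus cell means of the
log ratings (the mean of the five repetitions), the standard unit for
repeated-measures analyses of such designs; trial-level ANOVA is a
deliberate non-goal. Three designs are supported: fully within
(method × stimulus both within, as when each participant works both
formats), mixed (method between, stimulus within; group sizes may
differ), and one-way within. Sums of squares are computed by projection
onto orthonormal within-subject contrasts; with unequal group sizes the
within-subject main effect tests the unweighted mean of the group
profiles — the Type-III convention of R's standard mixed-ANOVA tooling
(the car package), against which the implementation is tested.

Sphericity is handled by the Greenhouse–Geisser estimate
$\hat\varepsilon = \mathrm{tr}(A)^2 / ((L-1)\,\mathrm{tr}(A^2))$, with
$A$ the covariance of orthonormalized contrast scores: each
within-subject effect gets its own $\hat\varepsilon$ in fully-within
designs, and the pooled within-group covariance is used in mixed
designs (so stimulus and interaction share one estimate). Corrected
degrees of freedom multiply both df by $\hat\varepsilon$; two-level
factors are never corrected ($\hat\varepsilon = 1$ identically).

Effect sizes are generalized eta squared,
$\eta_g^2 = SS_{\mathrm{effect}} / (SS_{\mathrm{effect}} + \sum
SS_{\mathrm{error}})$, summing over *all* subject-related error strata,
the convention recommended for designs with measured factors. It is
invariant to shifting all responses by a constant, and the F statistics
are invariant under affine rescaling.

## The hierarchical models and priors

Two models compete, both with normal likelihoods on the normalized
scales and participant-level coefficients:

**Power law**
$$y_{ij} \sim \mathcal N(b_{0j}\,x_i^{\,b_{1j}},\ \sigma_e^2), \qquad
  b_{0j} = b_0 + u_{0j}, \quad b_{1j} = b_1 + u_{1j},$$
with priors $b_0 \sim \mathcal N(0, 5)$, $b_1 \sim$ half-$\mathcal
N(1, 0.5)$ (a normal truncated to positive support), independent
$u_{0} \sim \mathcal N(0, \sigma_{u_0}^2)$,
$u_{1} \sim \mathcal N(0, \sigma_{u_1}^2)$, and
half-Student-t$(3, 0, 2.5)$ priors on all standard deviations.

**Linear**
$$y_{ij} \sim \mathcal N(\beta_{0j} + \beta_{1j} x_i,\ \sigma_e^2),$$
with $\beta_0 \sim \mathcal N(0,5)$, $\beta_1 \sim \mathcal N(0,1)$,
*correlated* participant effects
$(u_0, u_1) \sim \mathrm{MVN}(0, \Sigma)$ where $\Sigma$ is built from
$\sigma_{u_0}, \sigma_{u_1}$ and a correlation $\rho \sim
\mathrm{LKJ}(1)$ — uniform on $(-1, 1)$ for a 2 × 2 correlation matrix —
and the same half-t scale priors. The second argument of every normal
prior is a standard deviation. The linear model has one more random-
effect parameter ($\rho$) than the power model; the Bayes factor
penalizes that flexibility automatically.

Sampling uses JAGS with the *centered* hierarchical parameterization
($b_{0j} \sim \mathcal N(b_0, \sigma_{u_0}^2)$ rather than explicit
deviations). For Gibbs/slice samplers this form gives the population
means conjugate updates and mixes far better on these models than the
non-centered form (which is the right choice for Hamiltonian samplers);
the posterior is identical either way, and the draws are re-expressed
as deviations $u_{0j} = b_{0j} - b_0$ for reporting and bridge
sampling. Default settings mirror the emulated studies: four chains,
2,000 burn-in iterations per chain, 20,000 post-warmup draws in total.
Split-chain R-hat and effective sample sizes are computed for every
parameter and a convergence warning is raised if any population-level
R-hat exceeds 1.01; the pointwise log likelihood of every draw ×
observation is retained. Runs are exactly reproducible given the seed:
each chain receives a deterministic RNG stream derived from it.

Degenerate inputs are rejected rather than repaired: nonpositive
intensities, log-scale responses passed to the fitting routine, or
missing design cells are errors.

## Marginal likelihoods, Bayes factors, WAIC and LOO

The log marginal likelihood is estimated with the iterative
optimal-bridge (Meng–Wong) estimator. Draws are first mapped to an
unconstrained scale — log for standard deviations and the power-law
exponent, $\mathrm{atanh}$ for $\rho$ — with the corresponding Jacobian
terms added to the joint density. Half of the posterior draws
(moment-matching half) fit a multivariate-normal proposal; the other
half enter the bridge identity together with an equal number of fresh
proposal draws. The fixed-point iteration runs to a relative tolerance
of $10^{-10}$ (at most 1,000 iterations; failure to converge is an
error, never a silent result). The estimate is repeated ten times under
study settings, re-drawing proposal samples while reusing the posterior
draws, and the log Bayes factor is the per-repetition difference of two
such estimates, reported with its mean and SD. On a conjugate
normal–normal test model the estimator is accurate to well below 0.001
log units at 20,000 draws (verified against the closed form in the test
suite).

WAIC is $-2(\mathrm{lppd} - p_{\mathrm{waic}})$ with $p_{\mathrm{waic}}$
the summed posterior variances of the pointwise log densities. LOO uses
Pareto-smoothed importance sampling: per observation the inverse
likelihood ratios are stabilized by fitting a generalized Pareto
distribution (Zhang–Stephens profile estimator) to the largest
$\min(0.2S, 3\sqrt S)$ ratios, replacing them by fitted quantiles
truncated at the raw maximum. Standard errors for both criteria are
$\sqrt{n\,\mathrm{var}}$ of the observation-wise contributions on the
deviance scale — the convention that makes the SE directly comparable
to the criterion itself. Pareto shape diagnostics are reported but
never used to refuse a result. With a single posterior draw both
criteria collapse to $-2\sum_i \log p(y_i\mid\theta)$ exactly, a
degeneracy the tests assert.

## Posterior predictive checks and the pipeline

`posterior_predictive()` draws (by default) ten posterior draws and
simulates a full replicate response vector from the likelihood at the
observed design points; the overlay plot compares kernel densities of
observed and replicate responses pooled over stimuli, with the
bandwidth fixed to Silverman's rule on the observed data so that output
is deterministic. `run_pipeline(pipeline_config(...))` chains
simulate/load → preprocess → ANOVA → fit both models per arm → bridge
comparison → PPC, writes JSON/CSV artifacts stamped with the
configuration hash and seed, and reproduces itself exactly when re-run.

## Problem sizes used in the tests

The test-suite and acceptance script run the full chain at reduced MCMC
sizes — typically 2–4 chains with 300–500 warmup iterations and
1,000–4,000 retained draws, and 2–10 bridge repetitions — which is
ample for sign and recovery checks on these small hierarchies while
keeping a complete run in the minutes range; the package defaults
remain the full study settings. Parameter-recovery checks compare the
population-exponent posterior to the *truncated*-normal population mean
implied by the generator (with large exponent SDs the truncation shifts
the population mean visibly, e.g. 1.7 → 1.77 at SD 0.91). Calibration
checks use 20 seeded replicates per condition (recovery, model-selection
sign) and 1,000 replicates for the ANOVA type-I rate under a
non-spherical null.

## Known limitations

* The generator's noise is additive normal on the normalized response
  scale — matching the fitted likelihood by design — rather than
  multiplicative/lognormal, which some rating data suggest.
* Models are fitted per condition; a joint two-condition model with an
  exponent contrast is out of scope.
* Default ANOVA Bayes factors (multivariate-Cauchy priors on effects)
  are not computed; the classical GG-corrected ANOVA is reported and a
  BF-ANOVA is a natural extension.
* The linear model's near-singular random-effect correlation
  ($\rho \to -1$ when the truth is a power law) mixes more slowly than
  the other parameters; at the default draw counts this affects
  convergence diagnostics for $\rho$ before it affects the marginal
  likelihood.
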