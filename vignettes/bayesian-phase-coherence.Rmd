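---
title: "A hierarchical Bayesian model of phase coherence for frequency-tagged EEG/MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical Bayesian model of phase coherence for frequency-tagged EEG/MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecoh)
```

## The problem

In a frequency-tagged EEG or MEG experiment the stimulus is presented at a
fixed rate, so a stimulus-locked neural response concentrates at that
frequency. The classical summary is the inter-trial phase coherence (ITPC):
for each participant, condition and electrode, the phase
$\theta_{pcek}$ of the complex Fourier coefficient at the tag frequency is
extracted per trial, and the ITPC is the modulus of the trial-averaged unit
phasor,

$$R(p,c,e) = \Bigl|\tfrac{1}{K}\textstyle\sum_k e^{i\theta_{pcek}}\Bigr|.$$

The ITPC has two structural drawbacks. First, it is a two-stage summary:
trials are collapsed into one number per cell before any statistics are run,
so the items in the group analysis are participants, not trials. Second, it
is positively biased: with $K$ incoherent trials, $\mathbb{E}\,R^2 = 1/K$,
so the ITPC of pure noise is strictly positive and decreases only as
$K^{-1/2}$. Both problems bite hardest exactly where frequency tagging is
used — weak effects, few trials (semantic satiation limits repetitions in
language experiments), and modest participant counts.

`phasecoh` implements a trial-level Bayesian alternative: an explicit
generative model of the phases whose posterior quantifies condition effects
on the coherence scale, together with the full frequentist baseline (ITPC
tables, Wilcoxon signed-rank comparisons, cluster-based permutation tests)
and the validation machinery needed to trust the model (prior recovery,
grid-posterior oracles, an estimation-bias study, simulation-based
calibration, and data-efficiency curves).

## The generative model

Each trial phase is wrapped Cauchy,

$$p(\theta \mid \mu, \gamma) = \frac{1}{2\pi}
  \frac{\sinh\gamma}{\cosh\gamma - \cos(\theta - \mu)},$$

chosen over the wrapped Gaussian because its density is closed-form and its
mean resultant is simply $e^{i\mu - \gamma}$: the coherence of a cell is
$R = e^{-\gamma}$ and the circular variance is $S = 1 - e^{-\gamma}$.
Internally the density is evaluated in the Poisson-kernel form with
$q = e^{-\gamma}$,
$\log p = \log(1-q^2) - \log(1 + q^2 - 2q\cos(\theta-\mu)) - \log 2\pi$,
which is numerically stable for arbitrarily large $\gamma$ (no
`cosh`/`sinh` overflow, no switch-over point). Sampling wraps a real-line
Cauchy draw, which is exact and rejection-free.

The dispersion of each (participant, condition, electrode) cell is driven by
a linear model through a double link:

$$\gamma_{pce} = -\log(1 - S_{pce}), \qquad
  S_{pce} = \mathrm{logistic}(\upsilon_{pce}), \qquad
  \upsilon_{pce} = \alpha_c + \beta_{pc} + \delta_{ce}.$$

* $\alpha_c$ is the condition effect; the per-condition coherence reported
  everywhere is $R_c = 1 - \mathrm{logistic}(\alpha_c)$.
* $\beta_{pc}$ are participant slopes (attentiveness): a full row per
  participant with a multivariate Student-t prior (df $\nu$, scale
  $\mathrm{diag}(\sigma_\beta)\,\Omega\,\mathrm{diag}(\sigma_\beta)$),
  pooling within and across conditions; the heavy tails keep one
  exceptionally strong or inattentive participant from dominating.
* $\delta_{ce}$ are electrode slopes with a Normal$(0, \sigma_{\delta,c})$
  prior, pooled within condition only (cross-condition pooling of
  electrodes did not earn its keep, and the per-condition scale
  $\sigma_{\delta,c}$ is itself a quantity of interest).

### The circular location and the ring prior

The mean phase $\mu_{pce}$ is scientifically uninteresting but must be
estimated per cell, and it lives on a circle. A uniform prior on the
*interval* $[-\pi,\pi)$ has the right density but the wrong topology:
a gradient-based sampler cannot step from just below $\pi$ to just above
$-\pi$ without traversing the whole interval. The standard fix is to give
each cell a planar coordinate pair $(x, y)$ and use only its angle,
$\mu = \mathrm{atan2}(y, x)$. The pair gets a rotation-invariant "ring"
(Bundt-tin shaped) density whose radial profile is the gamma log-density of
$\rho = \sqrt{x^2+y^2}$ with shape = rate = 100 (radius concentrated at 1,
sd 0.1). Two deliberate choices here:

* The exact radial profile is immaterial — only the angle enters the
  likelihood, and rotational symmetry makes the angle exactly uniform for
  *any* profile; the ring merely keeps the sampler away from the origin
  (where the angle is undefined) and from wandering radially.
* Adding the gamma log-density of $\rho$ to the planar joint does not give
  $\rho$ a Gamma(100, 100) marginal: the polar-area Jacobian contributes a
  factor $\rho$, so the implied radial marginal is Gamma(101, 100) (mean
  1.01, sd ≈ 0.1). `draw_params_from_prior()` samples from that implied
  marginal so that prior draws and the sampler's prior density agree
  *exactly* — a requirement for simulation-based calibration, not a
  cosmetic detail.

### Priors and their defaults

* Baseline circular variance $S_c = \mathrm{logistic}(\alpha_c)$:
  Beta(5, 2) — frequency-tagged effects are weak, so most prior mass sits
  above $S = 1/2$ (coherence below 0.5). Setting Beta(1, 1) recovers a
  uniform prior on $S$, which the bias study uses to make the ground truth
  uniform on coherence.
* $\sigma_\beta$, $\sigma_\delta$: half-normal(1) — weakly informative on
  the logit scale.
* Slope correlation $\Omega$: LKJ(2), mildly favouring independence.
* $\nu$: fixed at 30 by default; small participant numbers make an
  estimated $\nu$ prone to divergent transitions, and 30 keeps the
  robustness of the t while staying near normality. `prior_config(nu =
  "estimate")` instead gives $\nu - 2$ a Gamma(2, 0.1) prior.

The LKJ prior is implemented through the C-vine representation: the
canonical partial correlations that build the Cholesky factor are
independent scaled Beta$(b_j, b_j)$ variables with
$b_j = \eta + (C-1-j)/2$, which is exactly equivalent to LKJ$(\eta)$ on the
correlation matrix. This gives an analytic unconstrained transform and
gradient, and — because the prior sampler uses the identical vine — exact
agreement between `draw_params_from_prior()` and the density the sampler
targets.

## Posterior computation

The package ships its own No-U-Turn sampler (the recursive-doubling,
slice-variable formulation) over a hand-derived joint gradient:

* Non-centred parameterisation for $\beta$ (through standard-normal
  innovations, the vine Cholesky factor, and a per-participant
  Gamma$(\nu/2,\nu/2)$ t-mixing variable) and for $\delta$, avoiding funnel
  geometry when slope scales are small.
* Diagonal mass-matrix adaptation over two warmup windows with
  dual-averaging step-size tuning (target acceptance 0.9), warmup = half
  the iterations, defaults of 4 chains × 4000 iterations.
* Divergences (log-joint error > 1000) and Hamiltonian energies are
  recorded per iteration; `diagnostics()` reports split-chain R-hat,
  FFT/Geyer effective sample sizes, E-BFMI and the divergence count.
  For E-BFMI the package uses the standard estimator
  $\sum_n (E_n - E_{n-1})^2 / \sum_n (E_n - \bar E)^2$, which is ≈ 2 for
  independent energies and small (< 0.3) when momentum resampling cannot
  traverse the energy distribution.

Model fits are validated two independent ways in the test suite: on a
single-cell model (hierarchy switched off through vanishing slope-scale
hyperpriors) the sampled posterior of $\gamma$ matches a dense 2-d grid
posterior; and in prior-only mode the sampler reproduces the Beta,
half-normal and LKJ prior moments.

`map_estimate()` gives the fast companion: the penalised-likelihood mode in
the unconstrained space (L-BFGS-B, best of several jittered starts), mapped
over a frequency grid by `map_trace()`. A caveat that the tests make
explicit: the joint mode of a hierarchy is not the marginal mode — with
loose slope hyperpriors the slopes can compensate the intercept and pull
$\hat R_c$ toward the prior. Point traces are useful for spotting spectral
peaks, not as a substitute for the posterior.

## Posterior summaries

All condition-level results are reported on the coherence scale:
`condition_resultant()` transforms $\alpha_c$ draws to $R_c$,
`condition_difference()` gives $\Delta R$ draws with mean, median, sd,
highest density interval and $P(\Delta R > 0)$ (the fraction of positive
draws), and `electrode_difference()` gives the per-electrode analogue
$[1-\mathrm{logistic}(\alpha_{c_1}+\delta_{c_1e})] -
[1-\mathrm{logistic}(\alpha_{c_2}+\delta_{c_2e})]$, flagged when the 95%
HDI excludes zero. HDIs are the narrowest *contiguous* window —
`floor(mass·n) + 1` sorted draws, leftmost on ties (multimodal draws make
the HDI non-unique; the tie-break makes results reproducible). Printed
summaries are rounded to three decimals; returned values are not.

## The frequentist baseline

`itpc_table()`, `electrode_condition_difference()` (with optional
mean-centring across electrodes, which compensates the display for the
ITPC's upward bias), `wilcoxon_signed_rank()` (exact enumeration to n = 25,
normal approximation with continuity correction above, Hodges–Lehmann CI;
zero differences dropped and counted) and `cluster_permutation_test()`
implement the standard pipeline. The cluster test follows the
Maris–Oostenveld scheme: a paired statistic per electrode (t by default,
Wilcoxon z optionally), a two-sided forming threshold (default p < 0.05),
connected supra-threshold sets of common sign under a user-supplied
adjacency graph (a k-nearest-neighbour builder from montage coordinates is
provided, default k = 4; no montage is hard-coded), cluster mass = summed
statistic, and a max-mass permutation null built by sign-flipping
within participant, $p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$.
Electrodes inside a significant cluster are *not* individually significant;
the cluster is the inferential unit.

## Validation machinery

**Bias study** (`run_bias_study()`): ground-truth coherences
$R_1, R_2 \sim U(0,1)$ (uniform baseline replacing the Beta), two-condition
datasets of 5 participants × 10 trials × 8 electrodes simulated from the
generative model, and the ratio (estimated $\Delta R$)/(true $\Delta R$)
recorded for the electrode/participant-averaged ITPC difference and for the
Bayesian posterior median. The ITPC arm's detection rule is a paired
two-sided Wilcoxon at 0.05 — which, with 5 participants, can never reject
(the smallest exact two-sided p at n = 5 is 0.0625); the Bayesian rule is
zero outside the 95% HDI. This asymmetry at small n is precisely the
data-efficiency phenomenon the study quantifies.

**Simulation-based calibration** (`run_sbc()`): parameters from the prior,
data from the model, posterior refit, and the rank of the true
$\Delta R$ among 50 thinned posterior draws; correct computation makes the
ranks uniform. `ecdf_band()` compares the rank ECDF with the uniform CDF
inside a simultaneous Monte-Carlo band (the band is a max-deviation
quantile, so its own false-alarm rate equals one minus its coverage — the
test suite checks this calibration of the calibration). As a negative
control the fitted likelihood can be corrupted by scaling its wrapped
Cauchy scale (`gamma_scale`); the control used in the tests *shrinks*
$\gamma$ in the fitted likelihood (scale 1/4), equivalent to data far more
dispersed than the model believes, which drives the implied coherences
toward $R^4$ and breaks rank uniformity decisively at a hundred
simulations. The direction matters: *inflating* $\gamma$ in the fit maps
coherences to $\sqrt R$, and because
$\sqrt{R_1}-\sqrt{R_2} \approx R_1 - R_2$ for the coherences this prior
favours, that corruption is nearly invisible to $\Delta R$ ranks —
choosing a detectable break is the point of a negative control.

**Data efficiency** (`participant_efficiency_curve()`,
`trial_efficiency_curve()`): the condition comparison repeated while
participants (or trials) are dropped from the end of the recording order,
tabulating the Wilcoxon CI and p against the Bayesian HDI and
$P(\Delta R < 0)$. All efficiency and bias fits fix $\nu = 30$.

## What the synthetic-data generator does and does not emulate

`simulate_dataset()` draws i.i.d. wrapped Cauchy trials per cell from the
model's own hierarchy; the presets mirror the two published designs this
package targets (16 participants × 6 conditions × 32 electrodes × 24 trials
at the 1.5625 Hz phrase rate; 39 × 2 × 64 at the 1.33 Hz pseudoword rate,
with 66 trials per cell standing in for the three 44-trial blocks split
over two conditions). What it deliberately does not reproduce: spatial
correlation between neighbouring electrodes, block/session effects,
trial-order drift, artifacts, or any misspecification of the wrapped
Cauchy shape. Green tests therefore certify the *inferential machinery*
(bias, calibration, efficiency under the model's own assumptions), not the
adequacy of the model for any particular recording; the cluster test and
ITPC baseline are the model-free cross-checks for real data.

## Numerical choices and degenerate inputs

* Phases are radians in $[-\pi, \pi)$ everywhere; every public entry point
  wraps on input, and missing trials are an explicit mask, never a sentinel
  angle.
* $\gamma = 0$ (point-mass phases) is rejected by density code and
  available in the simulator only behind an explicit `degenerate` flag.
* A cell circular variance that saturates to 0 or 1 in double precision is
  a numerical-domain error in the R-level likelihood and a rejected
  (divergent) state inside the sampler.
* Problem sizes in the test and acceptance suites are chosen for a desktop
  run: recovery at 8 participants × 8 electrodes × 20 trials over 20 seeds,
  bias study at 100 datasets, SBC at 200 simulations with 2 × 400-iteration
  fits, cluster null calibration at 1000 replicates; the full-size defaults
  (4 × 4000 iterations) remain the recommendation for real analyses.

## Known limitations

* Per-frequency fits are independent; harmonically related responses are
  not modelled jointly.
* Electrode slopes are spatially independent a priori.
* The joint MAP is prior-sensitive in hierarchies (see above); use the
  posterior for inference.
* Cluster-test details beyond the Maris–Oostenveld core (forming
  threshold, statistic, mass definition) are conventions, all
  config-exposed.
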