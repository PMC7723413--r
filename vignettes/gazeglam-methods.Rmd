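---
title: "Goal-relevant gaze-weighted accumulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-relevant gaze-weighted accumulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeglam)
```

This vignette documents the models implemented in `gazeglam`, the
conventions and defaults they rely on, what the synthetic-data generators do
and do not emulate, and the design decisions taken where more than one
reasonable implementation existed.

## The accumulation model

Binary choices are modelled as a race between two linear stochastic
accumulators, one per option, each integrating at a constant trial-specific
rate until a fixed boundary (1) is hit. The rate for option $i$ is
$\nu R_i$, where $R_i$ compresses three ingredients:

1. **Relative gaze** $g_i = DT_i/(DT_1 + DT_2)$, the share of the trial's
   dwell time spent on option $i$ (`relative_gaze()`).
2. **Gaze-weighted average absolute evidence**
   $A_i = g_i r_i + (1-g_i)\gamma r_i$: evidence accrues at the full rate
   while fixated and at the $\gamma$-discounted rate otherwise
   (`average_absolute_evidence()`). $\gamma = 1$ removes the gaze asymmetry;
   $\gamma < 0$ means unattended evidence leaks. The discount is
   *multiplicative* in $r_i$ — this is load-bearing: it is what makes the
   balance of evidence sensitive to the summed magnitude of the options
   (see the confidence section).
3. **Binary relative evidence and logistic scaling**:
   $R_i^* = A_i - A_j$ (so $R^*_{right} = -R^*_{left}$) and
   $R_i = 1/(1+e^{-\tau R_i^*})$. The sensitivity $\tau$ converts
   participant-scale evidence units into rate separation; $\tau = 0$
   renders the race insensitive to evidence.

**Goal-relevant evidence.** In frames whose goal opposes the raw scale the
evidence is mirrored before accumulation: $r_{dislike} = 3 - r_{like}$ on
the £0–3 bid scale and $r_{fewest} = 133 - r_{most} + 40$ on the 40–133 dot
scale (`goal_relevant_evidence()`). Both transforms are involutions and map
the scale onto itself. The package's central empirical contrast is between
models fitted with and without this transform (`transform_evidence` in
`fit_glam()`).

### Units and the first-passage likelihood

Because $R_i$ is constant within a trial, each accumulator's first-passage
time is Wald (inverse-Gaussian) with mean $b/(\nu R_i)$ and shape
$(b/\sigma)^2$, and the (choice, RT) likelihood is the winner's density
times the loser's survival, mixed with a contaminant component
(`trial_likelihood()`). **One time unit is one millisecond.** This
convention is forced by the prior $\nu \sim U(10^{-10}, 0.01)$: with the
boundary at 1, realistic response times of roughly 1–4 s require drifts of
order $10^{-3}$ per ms (mean FPT $= 1/(\nu R)$ ms). RTs are stored in
seconds in the trial tables (`rt_s`) and converted internally. The CDF's
second term is evaluated on the log scale, since its
$\exp(2\lambda/\mu)$ factor overflows for small $\sigma$. There is no
non-decision-time parameter.

The contaminant process (weight 0.05 by default) draws a uniform choice and
an RT uniform within the participant's observed RT range. It is applied in
both simulation and — by default — inside the likelihood
(`contaminant_in_likelihood`); whether the original fitting procedure placed
it inside the likelihood is not documented, so both modes are exposed.
Trials with zero dwell time on both options cannot enter the likelihood
(`relative_gaze()` errors; exclude them upstream).

### Estimation

`fit_glam()` estimates $(\nu, \gamma, \sigma, \tau)$ per participant under
independent uniform priors ($\nu \sim U(10^{-10}, 0.01)$,
$\gamma \sim U(-1,1)$, $\sigma \sim U(10^{-10}, 5)$, $\tau \sim U(0,5)$;
$\gamma$ can optionally be restricted to $[0,1]$). Two modes:

* **MAP** (default in examples and tests): multi-start L-BFGS-B inside the
  prior box with five fixed, dispersed starts; deterministic and roughly
  half a second per participant. WAIC is computed from a Laplace
  approximation around the optimum (200 draws, truncated to the prior box).
* **MCMC**: component-wise adaptive random-walk Metropolis within the prior
  box (out-of-bounds proposals are rejected, which is the correct move
  under a flat prior). Proposal scales adapt toward a 0.44 acceptance rate
  during tuning. The documented default matches the reference regime of 4
  chains, 1000 tuning and 2000 posterior draws; the test suite runs 2
  chains with a few hundred draws to stay fast, and the vignette notes this
  size as the package's own choice for desk-scale checks. Convergence is
  flagged (not errored) via the split Gelman–Rubin statistic
  ($|\hat R - 1| < 0.05$) and effective sample size (ESS > 100, Geyer
  initial-positive-sequence estimator). This sampler has no divergent
  transitions; the `n_divergences` field exists for interface parity and
  is always 0.

Model fitting conventionally uses even-numbered trials only and
out-of-sample prediction odd-numbered trials (`even_trials()`,
`odd_trials()`; `trial_index` is 1-based, so "odd" includes the first
trial). Perceptual-task fits drop RT outliers (>3 within-participant SDs or
>20 s, `filter_rt_outliers()`).

Parameter recovery at the experimental scale (240 trials) is good for
$\nu$, $\sigma$ and $\tau$ and noticeably weaker — though rank-preserving —
for $\gamma$, which is a known soft spot of gaze-discount models: the
discount only matters through the product with the dwell-share imbalance,
so datasets with mild gaze dispersion carry little information about it.
`recovery_study()` tabulates this.

### Simulation and the balance of evidence

`simulate_choice_rt()` samples the race analytically (two Wald draws via
the Michael–Schucany–Haas transformation). `simulate_paths()` runs the
explicit Euler–Maruyama race (default step 10 ms, increments
$\nu R_i\,dt + N(0, \sigma\sqrt{dt})$) and records the **balance of
evidence** $\Delta e = |E_{right} - E_{left}|$ at the crossing — the
package's confidence proxy. The two simulators are cross-checked against
each other and against the analytic likelihood in the tests; the Euler
scheme's first-passage bias is $O(\sqrt{dt})$ (it misses within-step
crossings), so oracle comparisons use a 1–2 ms step while the default
10 ms step is kept for the bulk Δe protocol, where the bias is common to
all conditions. If both accumulators cross within one step the larger
overshoot wins — a measure-zero tie in the continuum, resolved
deterministically for reproducibility. Paths that fail to cross within
100 s (possible in the $\tau \approx 0$, tiny-$\nu$ corner of the prior)
are resampled once and then raise an error.

The out-of-sample protocol repeats each odd trial 50 times
(`out_of_sample_predict()`); the Δe protocol repeats each odd trial 10
times (`delta_e_table()`), which at the study scale of 31 participants
× 120 odd trials gives 37,200 simulated trials (33,600 for the 28
perceptual-fit participants). Δe regressions use covariates computed from
**raw** (untransformed) evidence, so the summed-value effect is
interpretable across frames; contaminated repetitions have no defined Δe
and are excluded from the regressions but retained (flagged) in the table.
The no-gaze-bias counterfactual (`no_gaze_bias`) fixes both gaze shares at
0.5 while keeping everything else.

Why the sum of evidence inflates Δe only under gaze bias: with gaze mostly
on the goal-relevant item, $R^* = c_1\Delta r + r_{low}(2g-1)(1-\gamma)$ —
the second term grows with the options' magnitude, widening the rate
separation and hence the final gap between accumulators. An additive
discount has no such term (the worked identity $2 - 1\times0.3 = 1.7$ vs
$10 - 9\times0.3 = 7.3$, equal under additive attention, is asserted
exactly in the tests). Under the generator's default conditions the pooled
regression t-values for this effect at the 37,200-trial scale are modest
(|t| ≈ 1–2, signs stable) — much smaller than with participant-fitted
parameters in the original study — because the default noise level
($\sigma = 0.02$) leaves Δe strongly diffusion-dominated. The acceptance
suite therefore asserts the sign pattern and the no-bias null, not a
significance level.

## Synthetic data

The generators produce the *statistical structure* the analyses assume, not
a full psychophysical simulation.

* **Value design** (`generate_value_design()`): 60 items with bids drawn
  Uniform(0, 3) rounded to £0.01 (a Beta(2,2) alternative is provided; the
  empirical bid distribution is not documented, and uniform maximises
  design feasibility). Median split, then 15 high–high, 15 low–low and 30
  mixed pairs; each pair appears once per side arrangement per frame (120
  trials per frame) in 6 alternating-frame blocks of 40; a block's last
  pair never opens the next block (enforced by a single swap).
* **Perceptual design** (`generate_perceptual_design()`): 3 numerosity
  levels (50, 80, 110 target dots) × 10 difference levels (2–20% in 2%
  steps); circle counts are `round(N(1 ± d/200))` (half-up), so the circles
  differ by d% of N — e.g. a 110-dot, 20% pair splits 99/121, 22 dots
  apart — and all counts stay inside the 40–133 transform range. The split
  rule is the package's own choice; the source text does not state one.
  Distractors are 80% of the level's target count (40/64/88). 120 trials
  per frame in 40-trial alternating blocks, matching the published block
  structure (each side arrangement of each pair repeats twice per frame).
* **Gaze** (`generate_gaze()`): alternating fixations with Gamma durations
  (mean 350 ms, shape 4, minimum 50 ms). The first 600 ms are split evenly
  between the options — emulating forced early exploration under a
  gaze-contingent display — after which dwell favours the goal-relevant
  item; the trial-level goal-dwell share is Beta-distributed with mean 0.60
  (concentration 12, giving the wide dispersion seen in per-trial gaze
  data). The share drawn for a trial is used both as the model's $g$ and as
  the realised dwell split, so fitted and generating quantities agree. In
  trials shorter than the window, or with extreme target shares, the whole
  sequence is rescaled instead, so pooled early-bin gaze is only
  approximately unbiased.
* **Behaviour** (`generate_behaviour()`, `generate_dataset()`): choices and
  RTs come from the Euler race on the transformed evidence; confidence is
  an affine map of Δe (default `1 + 4·Δe` plus N(0,1) noise, rounded and
  clipped to a 1–10 integer scale — the experiments' rating bar has no
  documented numeric range, so the endpoints are declared, not inferred);
  a 5% contaminant fraction receives uniform choice/RT/confidence. Master
  seed + participant-index streams make runs bit-reproducible, and adding
  participants never perturbs earlier ones.

What the generator does **not** emulate: item identity and satiety, saccade
kinematics, the empirical joint distribution of bids and gaze, non-decision
time, or any relation between confidence and subsequent behaviour. Passing
tests therefore certify the pipeline's internal consistency — the analyses
recover the structure the generator put in — not fidelity to any real
dataset; participant-level statistics from the original experiments are out
of reach by construction.

## Behavioural analyses

All group-level inference is **two-stage**: a per-participant GLM on
within-participant z-scored predictors, then a one-sample t test of each
coefficient across participants. This preserves every sign/flip inference a
hierarchical mixed model would deliver at this scale without committing to
a mixed-model solver. Participants whose logistic fit separates are re-fit
with a small L2 (ridge) penalty via penalised IRLS and flagged.

* `choice_regression()`: P(choose right) on ΔValue, RT, ΣValue, ΔDT and
  confidence. The headline pattern on generated data: the ΔValue slope is
  positive in like/most and negative in dislike/fewest, while ΔDT stays
  positive in all frames.
* `confidence_regression()`: two-stage for trial confidence (|ΔValue|, RT,
  ΣValue, ΔDT, GSF); pooled (single) linear regression for Δe tables
  (Δe ~ |ΔValue| + simulated RT + ΣValue, all z-scored within participant),
  where the ΣValue sign flip between frames is the quantity of interest.
* `gaze_influence()`: mean residual choice probability after removing the
  ΔValue-logistic prediction, sign-aligned with the dwell-time difference;
  positive scores mean gaze predicts choice beyond evidence.
* `last_fixation_analysis()`: per-participant logistic slope of
  P(last fixation = chosen) on the last-fixated option's evidence
  advantage; the slope flips sign between frames. A companion,
  `dwell_excluding_last()`, recomputes ΔDT without the final two fixations
  for the robustness re-analysis (dropping two, not one, avoids the
  artefact that the penultimate fixation is biased toward the unchosen
  option).
* `fixation_timeseries()` / `permutation_frame_test()`: gaze position
  (0 = left, 1 = right) is binned at 10 ms over the first 2000 ms, trials
  pooled across participants, and correlated with ΔValue per bin. The
  between-frame difference is tested with 200 permutations and
  Benjamini–Hochberg FDR at q ≤ 0.01, flagging only runs of ≥ 6
  consecutive bins (60 ms). The permuted unit is the **trial's frame
  label** (the stricter exchangeable null); shuffling instantaneous
  samples within bins is available as an alternative mode because the
  original description is ambiguous between the two. BH (not BY) is used,
  matching the plain "FDR" designation. Bins with fewer than 10
  contributing trials per frame are reported but never flagged; p-values
  are bounded below by 1/(n_perm + 1).

## Optimal information acquisition

`sampling_problem()` fixes the normative setting: $n$ options with values
i.i.d. $N(\mu, \sigma_\mu^2)$, one noisy signal each
($x_i = v_i + \epsilon_i$, $\epsilon_i \sim N(0, \sigma_\epsilon^2)$),
conjugate-normal updating, and one extra signal to allocate. The expected
utility of resampling item $i$ is, for the selection goal, the expected
maximum posterior mean after the second signal, and for the elimination
goal the expected mean of the kept items after optimally discarding one.

Because the updated posterior mean of the resampled item is Gaussian and
the utility is piecewise linear in it, both expectations reduce to normal
partial moments ($E[\max(X, c)] = \mu\Phi(a) + c\Phi(-a) + s\phi(a)$,
$a = (\mu - c)/s$) and are computed **exactly**. Gauss–Hermite quadrature
over the predictive distribution of the second signal is retained as an
alternative method, but the kink at the max makes it accurate only to about
$10^{-3}$ — demonstrably insufficient for the equality assertions — which
is why the closed form is the default; a $10^6$-draw Monte-Carlo oracle
cross-checks both in the tests. `verify_propositions()` checks, for each
signal configuration: the top-two (selection) and bottom-two (elimination)
items are exactly tied — an equality that holds *conditionally on the
signals*, since $E[\max(N(m_1, s), m_2)]$ is symmetric in $(m_1, m_2)$ —
and strictly dominate all other items for $n > 2$. Strictness is asserted
beyond a $10^{-12}$ relative floating-point margin: genuinely strict gaps
can be astronomically small when the best item dominates (the advantage of
resampling the runner-up decays as $\Phi((m_2-m_1)/s)$), and such
unmeasurable-but-positive gaps are reported as near-ties rather than
failures. With $n = 2$ both strategies are exactly indifferent.

## Problem sizes and numerical choices

The test and demonstration runs use desk-scale sizes chosen as the
package's own defaults: MAP fitting throughout (full 4×1000+2000 Metropolis
runs are available but take minutes per participant), 10⁵ paths for the
likelihood-vs-simulation oracle at a 1–2 ms Euler step, the full
37,200-trial Δe protocol with 31 synthetic participants, 5-point recovery
grids at 240 trials, 30 synthetic participants for the WAIC comparison, and
10 seeded runs for the permutation-test null calibration. Quadrature for
analytic choice probabilities integrates the winner-density × loser-survival
product to 50 times the slower accumulator's mean FPT at `rel.tol = 1e-8`.

## Known limitations

* $\gamma$ is weakly identified at 240 trials; interpret individual-level
  gaze-bias estimates with care and prefer the rank structure across
  participants.
* The Metropolis sampler is a conservative stand-in for gradient-based
  samplers: it attains the required diagnostics but needs longer chains
  for the same effective sample size.
* The Euler Δe protocol inherits an $O(\sqrt{dt})$ first-passage bias at
  the default 10 ms step; it cancels in between-condition contrasts but
  should not be treated as an unbiased RT simulator.
* Two-option races only; the multi-alternative generalisation of the
  relative-evidence term is not implemented.
* The generators make no attempt to mimic empirical effect *sizes* — only
  directions and orderings; quantitative agreement with published
  participant-level statistics is explicitly out of scope.
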