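---
title: "Racing diffusion models with a timer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Racing diffusion models with a timer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`timerace` fits two sequential-sampling accounts of two-alternative
forced-choice (2AFC) behaviour to trial-level choice and response-time
(RT) data: the racing diffusion model (RDM), in which two independent
single-boundary diffusion accumulators race, and the timed racing
diffusion model (TRDM), which adds a third, stimulus-independent
"timer" accumulator. When the timer reaches threshold first, a choice
is emitted that depends on the accumulated evidence only partially — a
principled model of fast guessing. The package also generates complete
synthetic sessions of a contrast-discrimination task (stimuli, reward,
punishment delays, intertrial intervals, on-line bias correction), so
the whole pipeline can be exercised and validated without animal data.

## The generative model

Each accumulator's first-passage time follows the Wald (inverse
Gaussian) law. With drift $\rho$, within-trial noise $\sigma$,
threshold $\alpha$ and non-decision time $t_0$ (all times in seconds),

$$f(t) = \frac{\alpha}{\sigma\sqrt{2\pi\tau^3}}
  \exp\left(-\frac{(\alpha-\rho\tau)^2}{2\sigma^2\tau}\right),
\qquad
F(t) = \Phi\!\left(\tfrac{\rho\tau-\alpha}{\sigma\sqrt\tau}\right)
 + e^{2\alpha\rho/\sigma^2}
   \Phi\!\left(-\tfrac{\rho\tau+\alpha}{\sigma\sqrt\tau}\right),$$

with $\tau = t - t_0$. For $\rho \le 0$ the distribution is defective:
the boundary is reached only with probability
$e^{2\alpha\rho/\sigma^2}$. `dwald()`, `pwald()` and `rwald()`
implement this triple; the sampler uses the exact
Michael–Schucany–Haas inverse-Gaussian generator and, for negative
drifts, the reflection identity (conditional on crossing, the
first-passage law equals that of $|\rho|$), rather than rejection —
exact and $O(1)$ per draw.

Stimulus contrasts $s_l, s_r \in [0,1]$ enter through a linear drift
link (`drift_rates()`):
$\rho_{l} = v_0 + v_d(s_l - s_r) + v_s(s_l + s_r)$ and mirrored for
$\rho_r$, so $v_d$ carries discrimination and $v_s$ the overall
stimulus energy.

The TRDM likelihood of a left response at time $t$ multiplies the
winning density by the survivor functions of the two losers, plus the
timer route:

$$\mathrm{PDF}_{left}(t) = f_{E,l}(1-F_{E,r})(1-F_T)
 + P_T\, f_T (1-F_{E,l})(1-F_{E,r}), \quad
P_T = \gamma F_X(0) + \tfrac12(1-\gamma),$$

where $X$ is the normal difference of the accumulated evidence totals.
The RDM is the first term with the timer factors removed. These are
*defective* densities: integrated over time per choice they sum to the
choice probabilities.

## Conventions the data did not pin down

Several details of this model family admit more than one reading; the
package fixes each one explicitly and exposes the alternative where
reasonable:

* **Bias.** The bias parameter $\omega \in (0,1)$ enters as
  complementary thresholds $\alpha_l = 2\omega$,
  $\alpha_r = 2(1-\omega)$ (`biased_thresholds()`), preserving the
  fixed threshold 1.0 at $\omega = 0.5$ and conserving
  $\alpha_l + \alpha_r = 2$. A start-point or drift offset would be
  equally defensible; the threshold form is the simplest that is
  monotone in choice probability.
* **$\gamma$-mixture variance.** The evidence-difference variable is
  implemented with variance $2(\eta_c t)^2$ by default — under which
  $P_T$ is independent of the crossing time — with
  `gamma_variance = "diffusion"` switching to the Brownian-difference
  variance $2\eta_c^2 t$.
* **Timer clock.** The timer shares the single non-decision time
  $t_0$ with the evidence accumulators (all three run on the shifted
  clock); `timer_t0 = "zero"` leaves the timer unshifted.
* **Densities are floored** at $10^{-300}$ before logging, so one
  impossible trial yields a very negative but finite log-likelihood
  instead of derailing the sampler.
* **Equal-contrast trials** are scored exactly like the others: the
  likelihood conditions on the observed choice, never on the randomly
  assigned "correct" label.
* **Never-terminating RDM races** (both drifts negative) are resampled
  by the simulator with a warning: the task is free-response, so
  observed data contain only completed trials.
* **$\rho$ near zero** is floored at $|\rho| = 10^{-10}$ for sampling,
  the $\rho \to 0$ limit being well-defined but heavy-tailed.

## Priors and posterior sampling

The free parameters and their priors (location and scale of the
underlying normal):

| parameter | meaning | prior | support |
|---|---|---|---|
| $\omega$ | response bias | IL(0, 1.4) | (0, 1) |
| $t_0$ | non-decision time (s) | IL(0, 1.4) | (0, 1) |
| $v_0, v_d, v_s$ | drift-link coefficients | LN(1.56, 1.5) | (0, ∞) |
| $\eta_c$ | evidence noise | LN(1.56, 1.5) | (0, ∞) |
| $\rho_t$ | timer drift (TRDM) | LN(1.56, 1.5) | (0, ∞) |
| $\eta_t$ | timer noise (TRDM) | LN(1.56, 1.5) | (0, ∞) |
| $\gamma$ | evidence weight of timer choices (TRDM) | IL(−1, 1.0) | (0, 1) |

IL$(m,s)$ means the parameter is `plogis(z)` with
$z \sim N(m,s)$; LN$(m,s)$ means $\log\theta \sim N(m,s)$. These are
the standard readings of two-number parameterisations; the LN prior
median $e^{1.56} \approx 4.8$ puts typical decision times near
$\alpha/\rho \approx 0.2$ s at threshold 1, matching fast animal RTs.
The asymmetric $\gamma$ prior (median $\approx 0.27$) leans toward
mostly-random timer choices.

Sampling (`run_demcmc()`, wrapped by `fit_race()`) happens on the
unconstrained scale (logit/log), where each prior is exactly normal —
so differential-evolution proposals, which are additive, are natural.
The population holds 10 chains per free parameter (60 RDM, 90 TRDM),
with 200 burn-in and 500 retained iterations by default; proposals are
$\theta_i + g(\theta_a - \theta_b) + \epsilon$ with
$g = 2.38/\sqrt{2d}$, $\epsilon \sim U(\pm 10^{-4})$, accepted by the
Metropolis rule. No thinning: all post-burn-in samples are kept.

### Making a short schedule work

These posteriors are multimodal. A prominent minor mode sets the
evidence machinery to zero ($v_0, v_d, \eta_c \to 0$) and explains RTs
with the timer alone and accuracy with the $\gamma$ mixture (as
$\eta_c \to 0$ the mixture becomes a step-function psychometric with a
lapse rate) — structurally the "lapse" account the timer model is
meant to supersede. Plain DE-MCMC started from raw prior draws
reliably stalls there on short schedules. Three standard measures fix
this, all confined to initialisation and burn-in so the retained
sampling phase remains plain Metropolis with symmetric proposals:

1. **Refined initialisation:** a pool of `20 × chains` prior draws is
   ranked by posterior; Nelder–Mead multi-start from the best five
   polishes them, and the population starts over-dispersed around the
   best optimum (jitter SD 0.15 per unconstrained coordinate).
   Over-dispersion errs on the safe side: burn-in contracts a spread
   population far more readily than it expands a collapsed one.
2. **Burn-in migration:** with probability 0.1 per burn-in iteration,
   the worst 5% of chains are reset to jittered copies of randomly
   chosen top-quartile chains.
3. **Mode-jumping proposals:** 10% of iterations use difference scale
   0.98 instead of $2.38/\sqrt{2d}$ (a symmetric proposal, hence valid
   in both phases), letting chains traverse between modes along
   population difference vectors.

The first 30% of burn-in accepts greedily (improvements only), the
remainder by the exact Metropolis rule.

## The synthetic task

`generate_session()` reproduces the session structure of the tree-shrew
contrast-discrimination experiment the models were built for: six
contrast levels evenly spaced on $[0.08, 0.99]$ crossed into 36 ordered
pairs; 550 trials per session (the animals did 500–600 per day);
truncated-normal intertrial intervals ($0.6$ s, SD 1, bounds
$[0.5, 0.7]$ — nearly uniform on its bounds, implemented as specified);
truncated-normal reward durations ($0.1$ s, SD $0.06$, bounds
$[0.2, 0.4]$ — the location below the lower bound is unusual but
well-defined, and its mean of $\approx 0.22$ s at 150 µl/s reproduces
the nominal 33 µl reward); and one of two punishment schemes for
errors: a fixed 4 s delay (+0.8 s per blank-screen lick, capped at
8 s) or an exponential-decay delay
$T = (1/s)\,e^{-(RT - l)/s}$ with $l = 0.1$, $s = 1.7$ (+1.5 s per
lick, uncapped), which punishes fast errors hardest. Real-time bias
correction sets the probability of a rightward trial to one minus the
recent rightward-choice fraction (10-trial window); it is on by
default, as during data collection with biased animals. Blank-screen
licks have no behavioural model (the task description gives none), so
sessions take a configurable lick-count distribution defaulting to
zero licks. Training-stage curricula (easy/hard ratio adjustment) are
out of scope: the generator samples the full grid as in formal data
collection.

### Reference agents

Two TRDM parameter sets emulate the two observed behavioural
phenotypes. Both share the evidence machinery
($v_0 = 1.4$, $v_d = 0.8$, $v_s = 0.3$, $\eta_c = 0.45$, $t_0 = 0.1$,
unbiased), so the phenotypes differ only in the timer — mirroring the
conclusion that the delay scheme acts on the time accumulator:

* `agent_fast_timer()` (fixed-delay phenotype): $\rho_t = 0.4$,
  $\eta_t = 3$. The timer's effective speed here comes from its
  *noise*: a high $\eta_t/\alpha$ ratio concentrates a large share of
  crossings very early while leaving a heavy tail that spares the
  later evidence mode. This is the only corner of the parameter space
  that actually produces the observed phenotype — a bimodal RT
  distribution whose early mode is at near-chance accuracy with the
  late mode accurate, and a timer-induced choice fraction in the
  30–66% range. A *tight* fast timer (high $\rho_t$, small $\eta_t$)
  cannot: being first and narrow, it wins nearly every race and the RT
  distribution collapses to one early mode.
* `agent_slow_timer()` (exponential-delay phenotype): $\rho_t = 0.3$,
  $\eta_t = 0.4$. The timer almost never wins (fraction well below
  5%, typically a few per thousand — "near zero" on the scale of the
  fixed-delay phenotype), RTs are unimodal and log-normal-like, and
  accuracy is above chance across the whole RT range.

What the generator deliberately does *not* emulate: session-level
non-stationarity (fatigue, state switching), lick dynamics,
stimulus-rendering detail, and training curricula. Tests passing on
synthetic sessions therefore validate the estimation pipeline and the
internal consistency of the models, not the biological claims.

## Preprocessing and summaries

* `boxcox_cull()`: Box–Cox $\lambda$ by profile maximum likelihood
  (via `MASS::boxcox` on an intercept-only model, grid $[-3, 3]$ step
  0.01), then a 3-SD cut on the transformed RTs. Estimated per
  animal-dataset, not pooled. Zero-variance input keeps everything
  with a warning.
* `psychometric()`: rightward-choice proportion by signed contrast
  difference with Wilson intervals (well-behaved at proportions near 0
  and 1); `rt_by_difficulty()`: mean RT by $|\Delta|$ with
  normal-approximation intervals, optionally split by correctness.
* `accuracy_vs_rt()`: accuracy in 50 ms RT bins, fitted by
  count-weighted least squares with a logistic whose lower asymptote
  is fixed at the 2AFC chance level 0.5 and upper asymptote bounded by
  1. The 50 ms default balances bin occupancy against resolving the
  fast-guess regime in sub-second RT distributions.
* `reward_rate()`: $RR(t) = Acc/(Acc\,t + (1-Acc)(t+Delay))$, taking
  accuracy and delay as numbers or functions of $t$. Under a constant
  4 s delay and a rising sigmoid accuracy this is unimodal in $t$ —
  the structure that makes intermediate RTs optimal.
* The group-level mixed-effects regression of RT on difficulty is not
  reimplemented (it belongs to inferential group analysis of real
  data); `rt_slope()` provides a per-dataset least-squares slope as a
  descriptive diagnostic only.

## Model comparison

`compare_models()` computes $BIC = k\ln(n) - 2\ln L(\hat\theta)$ per
model and $\ln BF_{ij} = -\tfrac12(BIC_i - BIC_j)$, with $k = 6$ (RDM)
or $9$ (TRDM) and $n$ the trial count after culling (likelihood terms
are per trial). $\ln L(\hat\theta)$ is taken as the maximum likelihood
over all sampled parameter vectors, burn-in included, and the
componentwise posterior-median vector — the standard MCMC surrogate
when no separate optimisation is run, guaranteed to dominate the
median point estimate.
Evidence categories follow the conventional $|\ln BF| > 1, 3, 5$
thresholds (positive / strong / very strong), signed by direction.

One structural consequence worth keeping in mind when reading
slow-timer comparisons: as the timer's contribution to the data
vanishes, the two models' maximised likelihoods coincide and
$\ln BF \to -\tfrac{3}{2}\ln n \approx -10$ to $-12$ for desk-scale
$n$ — the comparison is then driven entirely by the complexity
penalty on the TRDM's three extra parameters, and "very strong"
evidence for the RDM means only that the timer was unnecessary, not
that it was contradicted.

## Problem sizes and numerical choices

The test-suite and acceptance runs use desk-scale versions of every
expensive check, chosen as the smallest sizes at which the quantities
of interest are stable: $10^5$ draws for simulator-vs-density
Kolmogorov–Smirnov checks (1% critical value), quadrature tolerances
of $10^{-4}$ on total choice mass and $10^{-6}$ on nesting identities,
Euler–Maruyama path oracles at $\Delta t = 10^{-3}$ with a
Brownian-bridge within-step crossing correction (removing the
$O(\sqrt{\Delta t})$ bias of the naive scheme) and $10^4$–$3\times10^4$
paths, 3000–5000-trial synthetic sets, and a reduced DE-MCMC schedule
(100 burn-in + 250 retained) for the end-to-end fits. Parameter
recovery targets the drift and timer parameters that carry the
scientific conclusions ($v_0$, $v_d$, $\rho_t$) at ±25%, aggregating
posterior medians across replicate datasets: on the $v_0$–$v_s$–$t_0$
ridge the per-dataset median varies by more than its bias (its
marginal posterior SD is about 0.3 at 5000 trials), so only the
aggregate isolates systematic error. Credible-interval coverage is
checked per dataset.

## Known limitations

* The maximum-over-samples BIC surrogate underestimates the true
  maximum likelihood slightly; since both models share the surrogate,
  the comparison is fair, but absolute BIC values are approximate.
* Multimodality means short schedules depend on the refined
  initialisation finding the dominant basin; the multi-start is
  effective but not guaranteed. Longer schedules (the 200/500 default)
  are recommended for real analyses.
* Fitting is per dataset (per animal); there is no hierarchical
  pooling across animals.
* The sampler reports no automated convergence decision; inspect
  `summary()` quantiles and the log-likelihood traces.
```
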