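---
title: "Multi-state step selection: model, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state step selection: model, estimation and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmssf)
```

## The model

Animal telemetry rarely reflects one homogeneous movement process.  A
foraging ungulate alternates between an *encamped* mode — short,
tortuous steps inside a resource patch — and a *travelling* mode —
long, directed steps between patches.  `hmmssf` fits a hidden-Markov
multi-state step selection function (HMM-SSF): the latent mode $S_t \in
\{1,\dots,K\}$ follows a Markov chain with constant transition matrix
$\Gamma = (\gamma_{ij})$, and, given the mode, the observed step is a
discrete choice among $J+1$ candidates (the observed step plus $J$
random steps sharing its start point),

$$
P(Z_t \mid S_t = k) \;=\;
  \frac{\exp(x_{0t}^\top \beta^k)}
       {\sum_{j=0}^{J} \exp(x_{jt}^\top \beta^k)},
$$

where $x_{jt}$ stacks movement covariates (cosine of the turning angle,
step length, log step length) and habitat covariates evaluated at the
candidate endpoint, and $\beta^k$ is the mode-specific selection
vector.  The likelihood of a trajectory is computed by the scaled
forward recursion, started at the stationary distribution of $\Gamma$
(a uniform start is available via the `delta` argument).

**Gaps and irregular sampling.**  Telemetry schedules leave holes.
`segment_trajectories()` cuts each individual's fix series wherever the
sampling interval deviates from the nominal one by more than a
tolerance (default 10%), drops segments shorter than three fixes, and
the likelihood treats segments as independent blocks: each restarts the
forward recursion at the initial distribution and the block
log-likelihoods add.  No imputation or resampling is attempted.

**Population pooling.**  Individuals are fitted separately and combined
by fixed-effect inverse-variance averaging: with $\hat\beta_n$ and
$\hat V_n$ the per-individual coefficient vectors and variance
matrices,
$\hat\beta_{\mathrm{Pop}} = (\sum_n \hat V_n^{-1})^{-1} \sum_n \hat
V_n^{-1}\hat\beta_n$ and $\hat V_{\mathrm{Pop}} = (\sum_n \hat
V_n^{-1})^{-1}$, the closed form of the weighted-least-squares solve on
the stacked-identity design.  Fits are excluded from the pool when they
did not converge, when their variance matrix is unusable, or when a
state claims fewer than 5% of the decoded steps (and at least 10): an
individual that essentially never visited a mode carries no information
about that mode's coefficients, yet would enter the average with a
finite, meaningless weight.

**Step-length implication.**  Random steps are drawn *uniform in
distance* (distance $\sim U(0, R]$, angle uniform).  Under that
availability convention, coefficients on step length and its log imply
a gamma step-length distribution with shape $1+\beta_{\log SL}$ and
rate $-\beta_{SL}$, hence a mean step of
$(1+\beta_{\log SL})/(-\beta_{SL})$ — the quantity
`mean_step_gamma()` reports and the package uses to order states
(state $K$ = fastest = travelling).  Outside the gamma-valid region
(`beta_sl >= 0` or `beta_logsl <= -1`) the density is truncated to
$(\varepsilon, R]$ and `mean_step_metropolis()` estimates the mean with
a Metropolis chain (20,000 draws, last 10,000 averaged).  The chain
alternates log-scale random-walk moves with log-uniform independence
jumps: a plain random walk mixes too slowly across densities that spike
at the truncation point, and any fixed lower cutoff in the integrable
region biases the mean upward for small gamma shapes, so there
$\varepsilon$ defaults to 0.

## Estimation choices

* Direct numerical maximization (BFGS) of the forward log-likelihood;
  transition rows use a multinomial-logit transform.  Emission and
  forward computations are in compiled code.
* Initialization: the coefficients of a single-state SSF fit, perturbed
  by $N(0, 0.5^2)$ per restart, with a diagonally dominant (0.9)
  starting transition matrix; 5 restarts by default, best optimum kept.
  A deterministic "split by step length" start was tried and rejected:
  it steered low-travel replicates into degenerate optima that split
  the abundant encamped mode instead of finding the rare travelling
  one.
* The variance matrix is the inverse of the numerical Hessian of the
  negative log-likelihood, reported for the selection-coefficient
  block (what pooling needs); transition-parameter uncertainty is not
  pooled.
* Label switching is resolved by the *decoded empirical* mean step
  length (filtered-probability-weighted mean of observed step lengths
  per state), not the closed-form gamma mean: a near-degenerate fitted
  state (gamma shape near zero) makes the closed form meaningless while
  the decoded mean stays interpretable.
* Convergence: BFGS relative tolerance $10^{-9}$, at most 400
  iterations; non-convergence and unusable Hessians are flagged, and
  such fits are excluded from pooling.

## State decoding, cross-validation and transitions

`state_probs()` returns predictive probabilities
$P(S_t = k \mid \mathcal{F}^0_{t-1})$ and filtered ones
$P(S_t = k \mid \mathcal{F}^0_{t})$; `decode()` applies the $\ge 0.5$
rule for two states and the argmax in general.  Recovery of *known*
(simulated) states is scored on the filtered probabilities: a
transition at step $t$ is only revealed by the emission at $t$, which
the one-step-ahead predictive probability excludes by construction, so
predictive ROC curves sit several points below filtered ones however
well the model fits.  Forward-looking uses — flagging migration onset, classifying
encamped-to-travelling transitions — keep the predictive rule.

`kfold_cv()` implements the state-specific k-fold procedure: sample 80%
of individuals, pool their fits, decode each held-out individual's
states from its *own* fit, split its strata by decoded state, score all
$J+1$ candidates of each stratum with the pooled state coefficients,
and rank them so that a higher rank means a higher selection
probability.  The Spearman correlation between the rank index
$1,\dots,J+1$ and the frequency of the observed step's rank is positive
for a model that predicts well; the same correlation for one randomly
sampled random candidate per stratum is the null reference.  Two
properties of this statistic are worth knowing.  First, it is capped
below 1 whenever several ranks have tied (for instance zero)
frequencies, so small test sets cannot reach 1 even under a perfect
model; values near 1 require enough strata that every rank is
populated.  Second, a degenerate model that always ranks the observed
step first concentrates all frequency mass on one rank, and the
Spearman correlation of $1{:}21$ against such a one-point mass is
$\approx 0.37$, not 1 — the statistic rewards *graded* monotone
frequency profiles, which is what fitted selection models produce on
real-sized test sets.

`classify_transitions()` labels consecutive step pairs as
encamped-to-travelling transitions ($Y=1$: encamped probability above
the threshold at $t$, at or below its complement at $t+1$),
non-transitions ($Y=0$: above the threshold at both), and discards
ambiguous pairs.  `fit_transition_model()` relates $Y$ to covariates
with a binomial logit mixed model (scalar random intercept per
individual, Laplace approximation, via `lme4::glmer`), with the
predator distance entering as the truncated index
$\tilde d = \min(d, d_{\mathrm{threshold}})$;
`profile_d_threshold()` locates the threshold by the log-likelihood
profile over a grid (default 50 points on 0.1–5 km).  The day-period
factor uses the three-level clock partition (dawn-dusk 03:00–06:59 and
16:00–21:59; day 07:00–15:59; night 22:00–02:59); a four-level variant
is available.

## The two simulators

**State-specific SSF walkers** (`simulate_ssf_agent`).  The landscape
is a square of 700 km² with 500 circular patches of 25 ha (radius 282
m) placed uniformly — one landscape per scenario, shared by all
replicates — with integer qualities drawn from 1–10 (overlaps take the
maximum) and quality 0 outside patches.  At each step the walker's true
mode is a deterministic function of position: encamped inside a patch,
travelling outside; in the predator scenario the mode is forced to
travelling whenever a single-state SSF predator (which tracks the
prey's resource) is within 500 m at the step start.  Twenty candidate
steps are drawn uniformly over a 2-km disk (uniform in area) and the
next location is one multinomial draw over the candidates with softmax
weights given by the mode's coefficient vector over (cos turn, step
length, log step length, quality, and, for the migrant, the cosine of
the deviation from the heading to a target at the top centre of the
map).  The walker's proposals are area-uniform deliberately:
distance-uniform proposals pile candidates around the current position,
and at these coefficients (quality weights up to $e^{10}$) that drops
the per-step probability of escaping a patch to a few per mille, leaving
a quarter of the replicates trapped in a single patch for their whole
trajectory — behaviour incompatible with the bimodal encamped/travelling
activity the scenarios are meant to produce.  The fitting availability
sample (`draw_random_steps()`) remains uniform in distance, the
convention under which the step-length coefficients imply the gamma
speed formula.  Walkers start anywhere on the map (southernmost 20% band for
migrants) with a random initial heading; candidates are reflected at
the map edge.  Because the transition rule depends on covariates, the
generated modes deliberately violate the constant-transition Markov
assumption of the fitted model — the robustness the study probes.

*Availability conditioning.*  The walker chooses among 20 finite
proposals, so the exact conditional likelihood of its decisions is the
softmax over those same 20 candidates.  `sim_choice_strata()` exposes
the recorded choice sets, and parameter-recovery analyses fit on them;
fitting against freshly re-drawn random steps (the only option with
field data, `draw_random_steps()`) is *not* the generative likelihood
of a finite-proposal walker and visibly attenuates coefficients.
Cross-validation, by contrast, uses fresh 21-candidate strata, which is
both the field design and what gives the rank support $1,\dots,21$.

**Consumption–regeneration–memory BCRW** (`simulate_bcrw`).  A
50×50-cell Gaussian random field (exponential covariance, variance 1,
nugget 0; presets low $(\mu_Q,\gamma_Q)=(-1.5,2)$, intermediate
$(-0.5,2)$, high $(1,10)$; negatives truncated to 0, field normalized
to sum 1) is grazed by a walker whose resource field obeys
$\dot Q = (R - C)\,Q$ with logistic regeneration
$R = \beta_R(1 - Q/Q_0)$ and consumption $C = \beta_C f_c(|z - Z|)$
($f_c$ an isotropic bivariate-normal kernel), clamped to $[0, Q_0]$.
Long- and short-term memory fields learn toward $Q_0$ under their own
kernels and decay exponentially; the memory map is
$M = L - \psi_M S$, so a just-visited cell is transiently repulsive.
The walker feeds (slow, tortuous correlated walk) until its
instantaneous intake drops below its running mean intake, then searches
(fast, straighter biased-correlated walk whose bias points to the cell
maximizing $M$ weighted by an exponential distance kernel — remembered
productive patches that are also close), and switches back when intake
recovers.  The continuous-time equations are discretized by explicit
Euler with $\Delta t = 0.1$ of a recorded step (10 substeps per step,
500 recorded steps); the search target is re-evaluated once per
recorded step.  The exact parameter values of the original
continuous-time implementation were not available, so defaults were
chosen once to satisfy the model's qualitative constraints — searching
faster than feeding (2.8 vs 0.7 cells per step) and straighter (heading
noise 0.25 vs 1.2 per unit time), short-term memory learning and
decaying faster than long-term — and are recorded in `bcrw_params()`.
Runs log their parameters via the run manifest.

## What the studies show (and what they do not)

`scenario_study()` and `bcrw_study()` run the replicated desk-scale
studies: 50 forager replicates of 500 steps for coefficient recovery
and cross-validation, 30 replicates per scenario (300 steps for the
migrant) for state recovery, 30 BCRW replicates per patchiness preset.
These sizes keep a full study on one CPU within minutes while leaving
the acceptance bands attainable; they are stated here as the package's
reference configuration.

The simulations emulate mode-switching selection with covariate-driven
(non-Markov) transitions, depletion, and memory, but not GPS error,
habitat measured with noise, irregular fix success, or
individual-level heterogeneity in the coefficients themselves (the
pooling is fixed-effect).  Passing the studies therefore demonstrates
internal consistency and robustness to the transition-rule
misspecification — not that field estimates are unbiased under
measurement error or real behavioural heterogeneity.

## Numerical and degenerate-input conventions

* Coordinates are planar kilometres; all geometry is Euclidean; angles
  are radians from the +x axis wrapped to $(-\pi, \pi]$.
* Raster lookup is nearest-cell with the origin at the lower-left cell
  corner and half-open cell intervals; one convention, used everywhere.
* Step lengths are floored at $10^{-6}$ km before taking logs; exactly
  zero step lengths are jittered to the same floor in the movement
  model of the 2-step baseline.
* The first step of every segment is excluded from strata (its turning
  angle is undefined).
* Candidate score ties in cross-validation are broken by seeded jitter.
* Strata with any candidate endpoint off a needed raster are dropped
  and counted.
* Every RNG-consuming operation takes an explicit seed and logs a run
  manifest (seed plus a configuration hash).

## The 2-step baseline

`fit_hmm_crw()` fits the comparison estimator's first stage: a 2-state
gamma/von Mises hidden Markov movement model whose transition
probabilities are logit-linear in supplied covariates;
`decode_crw()` smooths (forward–backward) and dichotomizes at 0.5; the
second stage re-draws random steps per decoded state with the
state-specific 99th-percentile radius and fits single-state conditional
logistic regressions (`survival::clogit`) with cluster-robust sandwich
variances, one cluster per individual.  Because the first stage sees
only step metrics, its decoding errors propagate into the per-state
selection estimates — the contrast the joint model is designed to
avoid.

## Known limitations

* Transition probabilities inside the HMM-SSF are constant; covariate
  effects on switching are assessed post hoc via the transition GLMM.
* The pooled estimator is fixed-effect: it estimates the
  precision-weighted population mean, not a between-individual variance
  component.
* The k-fold Spearman statistic is scale-dependent (see above); its
  values are comparable only at similar test-set sizes.
* Decoded-state contamination biases travelling-mode coefficients
  toward the encamped ones by a small amount even at the study's
  scale; supervised fits on the true-state strata recover the
  generating values within Monte-Carlo error, so the residual bias is
  attributable to hidden-state estimation, not to the likelihood.
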