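---
title: "Single- versus dual-process diffusion models of memory-based decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single- versus dual-process diffusion models of memory-based decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memddm)
```

## The scientific problem

When people choose between two options whose values must be recalled from
memory, they show a *memory bias*: the option they remember is preferred
over the forgotten one even when its remembered value is mediocre. Two
computational accounts can produce this bias inside the drift-diffusion
framework:

* **Single-process model (SPDM).** Every decision is one evidence-
  accumulation process whose drift compares the remembered option's value
  $V_{rem}$ against a *reference value* $\gamma$:
  $\nu = d \, [Rem_{right}(V_{right}-\gamma) - Rem_{left}(V_{left}-\gamma)]$.
  If $\gamma$ sits below the average option value, the remembered option
  wins more often than utility maximization would allow — a biased
  valuation, but a single process.
* **Dual-process model (DPDM).** Each trial is governed either by a
  *utility* process (drift $d_U \, s \, (V_{rem}-V_{avg})$, unbiased) with
  probability $\Delta$, or by a value-blind *heuristic* process (constant
  drift $d_H$ toward the remembered option) with probability $1-\Delta$.
  The likelihood is the $\Delta$-weighted mixture of two Wiener densities
  sharing the threshold $a$, start point $z$ and non-decision time
  $T_{er}$.

Both accounts shift the *choice* curve in favor of remembered options and
are nearly indistinguishable from choices alone. They differ in their
*response-time* signature: the SPDM's inverted-U RT curve peaks at
$V_{rem} = \gamma < 0$, whereas the DPDM's peak stays at $V_{avg} = 0$
because the heuristic component is flat in $V_{rem}$. The package's
qualitative battery quantifies the peak location with a hierarchical
shifted-quadratic regression on log-z RTs,
$RT = \beta_0 + \beta_1 (V_{rem} + \beta_2)^2$, and tests the group shift
$\mu_{\beta_2}$ against the nested dual-process null
$\mu_{\beta_2} = 0$ with a Savage–Dickey density ratio (Gaussian KDE,
bandwidth 0.1, standard-normal prior).

## Diffusion-parameter conventions

All closed forms and densities use the **symmetric-boundary convention**:
`boundary_separation` $a$ is the evidence distance from the unbiased
starting point to each boundary (the full span between the absorbing
boundaries is $2a$), so that

$$P(\text{upper}) = 1 - \frac{1}{1+e^{2\nu a/\sigma^2}}, \qquad
E[RT] = T_{er} + \frac{a}{\nu}\tanh\!\frac{\nu a}{\sigma^2},$$

and the defective first-passage densities are the exact joint refinement
of these two formulas (their upper-boundary integral equals the choice
probability at $z = 0.5$; tested by quadrature). Fits published under the
full-separation convention correspond to roughly twice our $a$. The
diffusion noise $\sigma$ is fixed at 1 as the scaling convention but kept
as an explicit argument. The upper boundary is the *right* response
throughout, so $z > 0.5$ is a right-side start bias.

Density evaluation uses the small-time/large-time series expansions of
the Wiener first-passage density with automatic switching and a per-term
truncation tolerance of $10^{-9}$. Positive parameters ($a$, $T_{er}$,
drift scalings) are estimated through $\exp$, interval parameters ($z$,
$\Delta$) through the standard-normal CDF, and $\gamma$ untransformed;
group-level normals live on the unconstrained scale.

## Simulation

`simulate_trials()` uses an Euler–Maruyama walk (default `time_step`
$10^{-3}$ s, `max_time` 10 s). Discrete-time walks systematically
overshoot first-passage times, so the boundaries are shrunk inward by
$0.5826\,\sigma\sqrt{dt}$ (the Broadie–Glasserman/Gobet continuity
correction); with this correction simulated choice fractions and mean RTs
agree with the closed forms within Monte-Carlo error at $10^4$ trials.
Walks that exceed `max_time` are recorded as omitted responses; the
empirical task's omissions have an unknown mechanism, so this is a
stand-in, not a claim about the task.

## The synthetic study generator

`simulate_study()` emulates the remember-and-decide structure: per
participant, option values are drawn from $N(0, \text{value\_sd})$ and
centered to an exact zero mean (so $V_{avg}=0$ on the model scale);
remembered flags are i.i.d. Bernoulli(`memory_accuracy`) per option and
independent of value; all trial types occur, but only mixed trials (one
remembered, one forgotten) are analyzed. Contamination mimics the
empirical exclusions: 2.0% omissions and 1.4% anticipatory RTs uniform on
(0.05, 0.2) s, each flagged in a `provenance` column.

Default design: 30 participants × 100 trials, value sd 1, memory accuracy
0.66 — about 45 analyzed mixed trials per participant (the empirical
study averaged 89.2 analyzed trials from a larger session). Group-level
ground truth mirrors the empirical fits where the quantity is
scale-free: $T_{er} \approx 0.29$ s, $z \approx 0.52$, $a \approx 0.9$
(i.e. $\approx 1.8$ separation), $\gamma = -0.54$, $\Delta \approx 0.55$.
The drift *scalings* are denominated in value units and the empirical
rating scale is unknown, so they are calibrated behaviorally rather than
transplanted: $d$ is set so that a 1-sd value difference yields roughly
73–77% choice accuracy ($d_{SPDM} = 0.6$, $d_{Utility} = 1.1$, preserving
their fitted ratio), which also reproduces the observed memory-bias
choice intercept of about $0.3$–$0.6$ log-odds. The heuristic drift
(scale-free) defaults to $0.8$, a clearly separated fast value-blind
process. These are defaults of the generator, not claims about the
empirical population; what passing tests show is that the *method*
separates the accounts when the ground truth is known, not that any
particular empirical dataset does.

## Estimation

Posteriors are sampled by an adaptive Metropolis-within-Gibbs scheme
implemented in C++: per-parameter random-walk updates for subject-level
draws (step sizes adapted toward 0.44 acceptance during warmup only),
conjugate Gibbs updates for group means, random-walk updates on log group
scales, and an interweaved (ancillarity–sufficiency) rescaling move per
scale that jointly moves a scale and its subject effects in the
non-centered frame — without it, small group scales mix poorly in any
centered scheme. A gradient-based sampler was considered and rejected:
the Wiener density's parameter gradients add substantial complexity for
little benefit at these model sizes, and the Gibbs structure admits exact
conjugate updates for half the group-level parameters. For the same
reason the *centered* parameterization is used: non-centering targets
Hamiltonian funnel pathologies, while here the interweaving move plays
that role.

Priors: group locations $N(0, 2)$ on the unconstrained scale and group
scales half-$N(0,1)$ for the diffusion models (the original hyperpriors
are not published; this is a documented divergence risk), standard normal
/ standard half-normal for the regression models. Chains are initialized
from jittered prior means, with subject non-decision times started below
each participant's minimum RT. Default sampling is 4 chains × 10,000
iterations (50% warmup); tests and recovery studies run reduced settings
(2–3 chains × 1,000–8,000) chosen as the smallest runs that keep split
R-hat near 1 for the quantities under test. Convergence is judged by
split-chain R-hat ≤ 1.01; recovery reports flag (rather than hide)
fits exceeding it.

Model comparison uses WAIC, $-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, from
stored pointwise log-likelihoods; differences carry the standard error
$\sqrt{n}\,\mathrm{sd}$ of pointwise differences and a standardized
effect (difference / SE). Bayes factors for the nested RT-shift null use
the Savage–Dickey ratio with a fixed KDE bandwidth of 0.1 as specified;
the bandwidth smooths the posterior density at 0, which makes the BF
conservative when the posterior is tight relative to 0.1.

## Validation surface

* **Posterior predictive checks** simulate replicate experiments (default
  500), drawing one posterior parameter vector per agent per replicate
  and re-simulating every trial (DPDM trials re-draw their governing
  process), then compare empirical bin means of choice rate and RT
  against 95% HDIs across replicates in 8 equal-count $V_{rem}$ bins
  (equal-width available).
* **Parameter recovery** refits the generating model to a synthetic study
  and reports group-level HDI coverage and subject-level Spearman
  correlations. At the default 30 × 100 design the per-subject mixture
  weight $\Delta_s$ rests on ~45 trials, so its true-versus-recovered
  correlation hovers around 0.7 — a genuine identifiability limit, not a
  sampler failure.
* **Model recovery** fits both models to datasets from each generator and
  tabulates WAIC winners; at the default separability settings the
  generating model wins the large majority of datasets, and accuracy
  grows with trials per participant.

## Numerical choices and limitations

* RT standardization is the natural log followed by a *population*
  (1/n) z-score, per participant by default (the downstream regressions
  are hierarchical); pooled mode exists for sensitivity checks.
* The 200 ms fast-guess cutoff uses strict `<`; exclusions apply in the
  fixed order omissions → fast RTs → trial type, and the report always
  reconciles.
* Quantile bin edges deduplicate when the data are too discrete, so fewer
  than 8 bins can occur in degenerate inputs.
* The Bayesian correlation standardizes its inputs internally and places
  a uniform prior on the correlation over $(-1, 1)$ (sampled through
  $\tanh$ with the appropriate Jacobian) with weakly informative
  location/scale priors.
* Across-trial variability parameters (drift, start point, non-decision
  time) are deliberately absent — the models under study do not include
  them. Trials where both options are remembered or both forgotten are
  generated but never modeled; the generating formulas degrade gracefully
  there (plain value comparison / zero drift).
* Synthetic data inherit every assumption of the generator: memory
  status independent of value, exactly centered values, Wiener-true RTs.
  Real data violate these in unknown ways; passing recovery here shows
  method validity, not empirical truth.
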