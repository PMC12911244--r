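---
title: "Bayesian treatment selection for two-arm randomised phase II trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian treatment selection for two-arm randomised phase II trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ph2select)
```

## The selection problem

Randomised phase II "pick-the-winner" trials compare two candidate
treatments A and B on a binary endpoint (tumour response, or a
progression-free-survival indicator at a landmark time) and must decide
which arm, if either, advances to a confirmatory phase III trial.  A
distinctive feature of selection designs in the Sargent–Goldberg
tradition is an explicit *ambiguous* zone: when the two response rates
are within a clinically meaningful difference $d$ of each other, the
primary endpoint alone should not force the choice, and secondary
factors — toxicity, cost, ease of administration, quality of life —
take over.

`ph2select` implements a Bayesian version of this logic.  Each arm's
response rate gets a conjugate Beta prior,
$\pi_i \sim \mathrm{Beta}(\alpha_i, \beta_i)$, so that after observing
$S_i$ responders among $n_i$ patients,

$$\pi_i \mid S_i, n_i \sim \mathrm{Beta}(\alpha_i + S_i,\;
  \beta_i + n_i - S_i).$$

With arm A nominated as the (anticipated) better treatment, the design
works with three posterior quantities:

* $P_{\mathrm{Corr}}^{*} = \Pr(\pi_A - \pi_B > d \mid \text{data})$,
  the posterior probability that A is better by more than $d$
  ("correct selection");
* $P_{\mathrm{Amb}}^{*} = \Pr(-d \le \pi_A - \pi_B \le d \mid
  \text{data})$, the posterior probability of the ambiguous zone;
* $\lambda^{*} = P_{\mathrm{Corr}}^{*} + \rho\, P_{\mathrm{Amb}}^{*}$,
  the decision criterion.

The weight $\rho \in [0, 1]$ is the probability that an ambiguous
outcome would still lead to the proper arm being selected: $\rho = 1/2$
treats ambiguity as a fair coin toss (the classical two-arm
convention), $\rho = 0$ is conservative, and $\rho = 1$ turns the rule
into $\lambda^* = \Pr(\pi_A - \pi_B \ge -d)$, a non-inferiority-style
criterion.  Arm A is selected outright when $\lambda^{*} > \theta$
(strictly); otherwise the recommendation is to weigh secondary factors.
$\theta$ defaults to 0.90 throughout the package and should be a large
fraction such as 0.80 or 0.90.

```{r criteria}
post_a <- beta_update(beta_params(1, 1), arm_outcome(40, 22))
post_b <- beta_update(beta_params(1, 1), arm_outcome(40, 16))
lambda_star(post_a, post_b, design_params(d = 0.10, rho = 0.5, theta = 0.90))
```

## Numerical evaluation of the criteria

$P_{\mathrm{Corr}}^{*}$ is the integral
$\int_0^{1-d} \{1 - F(x + d;\, \alpha_A + S_A, \beta_A + n_A - S_A)\}
f(x;\, \alpha_B + S_B, \beta_B + n_B - S_B)\,dx$ with $F$ and $f$ the
Beta cdf/pdf, and $P_{\mathrm{Amb}}^{*}$ is the difference of the two
tail integrals at shifts $-d$ and $+d$.  Two implementation routes
share these definitions:

* the scalar route (`prob_correct()`, `prob_ambiguous()`) uses adaptive
  quadrature (`stats::integrate`, absolute tolerance well below 1e-8)
  on the effective support of the $\pi_B$ posterior;
* the grid route (`lambda_star_grid()`) evaluates all responder-count
  pairs for one per-group $n$ at once with 240-node Gauss–Legendre
  quadrature, vectorising the Beta survival function across the
  $(n+1)^2$ posteriors.

In both routes the integrand's kinks — where the clamped cdf argument
crosses the support boundary at $x = d$ and $x = 1 - d$ — are split out
analytically; the piece below $x = d$ reduces to a closed-form Beta cdf
mass.  Each piece is then smooth, so both routes agree to ~1e-12 in the
test suite, and the integrals are exact at tiny $n$ where the
integrands are polynomials.  Degenerate inputs behave as the
definitions dictate: $d = 0$ gives $P_{\mathrm{Amb}}^{*} = 0$ exactly
(a continuous difference hits a point with probability zero) and
$d \ge 1$ makes correct selection impossible; validation rejects
$d \ge 1$ at the design level.  All probabilities are carried at full
precision and rounded to two decimals only in human-readable reports.

## Sample-size determination

Both algorithms assume equal allocation $\tilde n_A = \tilde n_B =
\tilde n$ and need anticipated response rates $\tilde\pi_A >
\tilde\pi_B$, the decision constants $d$ and $\rho$, and a design-stage
threshold $\gamma^*$.

**Deterministic method.**  For each candidate $\tilde n$ the expected
responder counts $\tilde x_i = \mathrm{round}(\tilde n \tilde\pi_i)$
are plugged into the update and $\lambda^*(\tilde n)$ computed.
Because the counts are integers, $\lambda^*(\tilde n)$ is a sawtooth:
it jumps each time a rounded count increments.  The minimal size is
therefore defined with a stays-above rule — the smallest $\tilde n$
from which $\lambda^* > \gamma^*$ holds at *every* larger candidate up
to the search cap — rather than a first crossing, which would return a
transient peak.  Rounding is R's `round()` (half-to-even); this is the
convention under which the search reproduces the design's reference
size tables cell for cell, and it is consistent with the worked example
$\tilde n = 30$, $\tilde\pi_A = 0.25 \Rightarrow \tilde x_A = 8$.

```{r deterministic}
req <- ss_request(0.30, 0.15, d = 0.05, rho = 0.5, gamma_star = 0.90,
                  n_max_search = 150)
find_nmin_deterministic(req)
```

**Simulation-based method.**  The deterministic plug-in ignores the
sampling variability of the counts, and its sawtooth makes small-sample
behaviour unstable.  The second method treats the counts as random,
$x_i^* \sim \mathrm{Binomial}(\tilde n, \tilde\pi_i)$, and thresholds
$\bar\lambda^* = E[\lambda^*]$, estimated by `lambda_bar_mc()` from $m$
replicates or computed exactly by `lambda_bar_exact()` as the
pmf-weighted sum over the count grid.  The resulting curve is smooth
and increasing, so a plain first crossing of $\gamma^*$ is used — a
deliberate asymmetry with the deterministic search.  Sizes from
$\bar\lambda^*$ are generally larger: the extra randomness must be
overcome.

```{r simulated}
find_nmin_simulated(req, method = "exact")
```

Monte Carlo draws for candidate $\tilde n$ use a substream seeded
deterministically from (root seed, $\tilde n$), so a trace does not
change when the search range does, and `lambda_bar_mc()` reduces to a
lookup in the memoised `lambda_star_grid()` — only $(\tilde n + 1)^2$
distinct posterior pairs exist, which keeps $m = 100{,}000$ replicates
per candidate inexpensive.  Near-threshold cells are genuinely
borderline for any Monte Carlo run: at $(\tilde\pi_A, \tilde\pi_B) =
(0.30, 0.15)$, $\rho = 0$, $\gamma^* = 0.90$ the exact expectation
crosses at $\tilde n = 114$ with margin $2\times 10^{-4}$ — about one
Monte-Carlo standard error at $m = 100{,}000$ — so two valid runs can
disagree by $\pm 1$ there.  The enumeration backend is the package's
arbiter for such cells.

Defaults: search range 2–1000 (a `NOT_FOUND` sentinel beyond, reported
with the maximum criterion achieved), $m = 10{,}000$ replicates in
interactive use.  Within a fixed $\rho$, raising $\gamma^*$ never
lowers the required size; allowing ambiguity ($\rho > 0$) never raises
it.

## Operating characteristics

Given *true* rates $(\pi_A, \pi_B)$, per-arm size $n$, and the analysis
priors, the package evaluates the design's frequency behaviour:
$\xi$, the proportion of trials with $\lambda^*_j > \theta$ (arm A
advanced on efficacy alone), and $\nu = 1 - \xi$ (decision deferred to
secondary factors).  `oc_simulate()` mirrors the reference procedure —
$k = 100{,}000$ seeded binomial replicates pushed through the memoised
$\lambda^*$ grid — while `oc_exact()` computes the same quantity
exactly as
$\sum_{S_A, S_B} \mathrm{Bin}(S_A)\,\mathrm{Bin}(S_B)\,
\mathbf{1}\{\lambda^*(S_A, S_B) > \theta\}$.
Because both backends share one grid, the Monte Carlo estimate
converges on the enumerated value by construction; the test suite
asserts 3-standard-error agreement at $k = 10{,}000$, a replicate count
chosen to keep the default test run fast while leaving the Monte-Carlo
error (about half a percentage point) far below the effects being
checked.

```{r oc}
oc_exact(oc_scenario(0.30, 0.15, n_per_arm = 39, d = 0.05, rho = 0.5))
```

Two qualitative patterns are worth knowing when specifying priors.
When the prior means match the true rates, increasing the prior
effective sample size $\alpha + \beta$ raises $\xi$ — prior-data
synergy.  When the truth is "no difference" but the prior asserts one,
strong priors erode the design's deferral behaviour: with equal true
rates 0.30 and priors Beta(15, 35)/Beta(5, 45) at $n = 39$, $\nu$
falls from ~92% (vague) to ~45%, i.e. the misled design increasingly
"selects" an arm on efficacy.  Prior information should stay modest
relative to the trial data unless it is genuinely trustworthy.

## The frequentist comparator

The Sargent–Goldberg design defines correct selection and ambiguity on
*observed* rates: with $x_i \sim \mathrm{Binomial}(n, \pi_i)$,
$P_{\mathrm{Corr}} = \Pr(\hat p_A - \hat p_B > d)$ and
$P_{\mathrm{Amb}} = \Pr(|\hat p_A - \hat p_B| \le d)$, combined as
$\lambda = P_{\mathrm{Corr}} + \rho P_{\mathrm{Amb}}$.
`sg_probabilities()` evaluates these by exact double-binomial
enumeration, comparing counts in integer arithmetic ($x_A - x_B$
against $d\,n$, snapped to the nearest integer when within 1e-9) so
boundary outcomes are never misclassified by floating point.  The
(strict correct, inclusive ambiguous) convention is pinned by the
reference configuration: rates 0.55 vs 0.40, $d = 0.10$, $n = 40$ give
$\lambda = 0.8128 \to 0.81$, against $\lambda^* = 0.82$ for the
Bayesian criterion with vague priors and expected counts — the two
frameworks agree closely when the prior is uninformative.

`sg_sample_size()` scans $n$ with the same stays-above stabilisation,
using $\lambda \ge$ threshold (attainment counts).  Candidates are
restricted to sizes where $d\,n$ is a whole count, so the decision
boundary is exactly attainable: at other sizes the inclusive/exclusive
asymmetry makes $\lambda$ drop every time $\lceil d\,n \rceil$ steps,
and "smallest $n$" would be an artefact of that sawtooth (at the
reference configuration it would return 32 while the design's
published answer is 40, reached over candidates 10, 20, 30, 40).  With
$d = 0$, or when no admissible candidate exists in range, every
integer is scanned.

## What the generators emulate — and what they do not

All simulations draw responder counts from independent binomials at
fixed true rates, which is exactly the sampling model the design
assumes.  Passing tests therefore certify the internal consistency of
the machinery (quadrature vs sampling oracles, Monte Carlo vs
enumeration, search rules vs reference tables), not robustness to the
ways real trials depart from the model: drop-out and unevaluable
patients, time trends, endpoint misclassification, non-1:1 allocation,
or interim looks (selection designs of this family follow all patients
to the end before deciding).  Robust mixture priors and dynamic
prior-data-conflict handling are likewise out of scope.

## Problem sizes used in the checks

The bundled tests and the acceptance script keep everything
desk-scale: sample-size searches are capped at 150–300 candidates
(the reference tables stay under 165, and the stays-above rule is
stable to the cap — the last dip below $\gamma^* = 0.90$ occurs by
$\tilde n = 71$ in the vague-prior cells), the sampling oracles use
$10^6$ Beta draws, operating characteristics use exact enumeration
(deterministic) plus $k = 10{,}000$ Monte Carlo cross-checks, and the
simulation-based searches use the enumeration backend.  The reference
$m = k = 100{,}000$ procedures remain available through the same
functions.

## Known limitations

* Two arms only; multi-arm or multi-subgroup selection is not covered.
* Equal per-arm sizes at the design stage (analysis accepts unequal
  $n_i$).
* The deterministic search is only as meaningful as its plug-in
  counts; for small trials prefer the $\bar\lambda^*$ method, and when
  both are feasible compute both (`run_design(method = "both")`).
* Enumeration backends are quadratic in $n$ per candidate; they are
  comfortable into the hundreds per group but not designed for
  thousands.
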