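---
title: "Exact estimation and design choice in two-stage binomial trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact estimation and design choice in two-stage binomial trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phase2est)
```

## The model

A single-arm phase II trial observes a binary response (success/failure)
with unknown probability $p$. The standard treatment's response rate $p_0$
is taken as known, and the experimental treatment is interesting when
$p \ge p_1 > p_0$, the smallest clinically relevant improvement. A
two-stage design $\Omega = (n_1, l_1, u_1, n_2, u_2)$ recruits $n_1$
patients, observes $S_1$ responses, and

* stops for futility (accepts $H_0\colon p = p_0$) if $S_1 \le l_1$,
* stops for efficacy (rejects $H_0$) if $S_1 \ge u_1$,
* otherwise recruits $n_2 - n_1$ further patients and rejects $H_0$ iff
  the total $S_2 \ge u_2$.

Designs with $u_1 = n_1 + 1$ cannot stop early for efficacy (the
Simon-type family); designs with $u_1 \le n_1$ allow both stops (the
Shuster-type family). One set of formulas covers both because the
binomial mass $h(n, v, p)$ is defined to be exactly zero outside
$0 \le v \le n$ (`binom_pmf()`).

All operating characteristics are exact binomial sums, not
approximations: with $H(n, s, p) = P(\mathrm{Bin}(n,p) \ge s)$,

$$P(\text{reject} \mid p) = H(n_1, u_1, p) + \sum_{x=l_1+1}^{u_1-1}
h(n_1, x, p)\, H(n_2 - n_1, u_2 - x, p),$$

which is the type I error at $p_0$ and the power at $p_1$, and

$$E[N \mid p] = n_1 + (n_2 - n_1) \sum_{x=l_1+1}^{u_1-1} h(n_1, x, p).$$

The rejection probability is non-decreasing in $p$, so checking the error
constraints at $p_0$ and $p_1$ controls them on the whole null and
alternative ranges.

## The T statistic and the stage-wise ordering

Estimation after a sequential stopping rule is the delicate part: the
terminal outcome is a pair (stage $M$, responses $S$), and the sample
space needs a total order by strength of evidence before p-values,
median-unbiased estimates or confidence bounds make sense. The package
uses the stage-wise (Fairbanks–Madsen) ordering through an injective map
onto a single integer $T \in \{0, \dots, n_2\}$:

* $T = S_1$ for a futility stop (region $T \le l_1$),
* $T = S_2$ for a stage-2 outcome ($l_1 + 1 \le T \le (n_2-n_1)+u_1-1$),
* $T = S_1 + (n_2 - n_1)$ for an efficacy stop ($T \ge (n_2-n_1)+u_1$).

Larger $T$ always means stronger evidence against $H_0$. The p-value
function $K(t, p) = P(T \ge t \mid p)$ has closed forms in each region
(`fm_pvalue()`); it is computed from those forms, not by summing the pmf
of $T$ — the identity $K(t,p) = \sum_{t' \ge t} P(T = t' \mid p)$ is kept
as a test, which checks the two independent code paths against each
other. A continuation-region boundary subtlety: at
$t = (n_2-n_1)+u_1$ the continuation formula's sum is empty and coincides
with the efficacy formula, so the continuation region is taken to end at
$(n_2-n_1)+u_1-1$ and either assignment would give identical numbers.

## The five estimators

All estimators are expressed as functions of $T$ (`estimate_p()`):

* **MLE** — the observed proportion at termination. Biased by the
  stopping rule: early futility stops truncate low outcomes, efficacy
  stops truncate high ones.
* **Bias-corrected MLE** — the value $q^\*$ at which the exact
  expectation of the MLE equals the observed MLE (Whitehead's relation
  $\hat p = q^\* + b(q^\*)$). The expectation
  $E_q[\mathrm{MLE}]$ is evaluated by the tower property over the stage-1
  count, $\sum_{x\ \mathrm{stop}} \tfrac{x}{n_1} h(n_1,x,q) +
  \sum_{x\ \mathrm{cont}} \tfrac{x + (n_2-n_1)q}{n_2} h(n_1,x,q)$, which
  is algebraically the expectation over the pmf of $T$ but costs $O(n_1)$
  per evaluation. The root is found by a sign-scan on a grid followed by
  bracketed root-finding; if several roots exist (the relation does not
  guarantee uniqueness) the one closest to the observed MLE is returned,
  and if no root lies in $[0,1]$ the closer boundary is returned with a
  warning.
* **UMVUE** — the Rao–Blackwellisation $E[S_1/n_1 \mid M, S]$ of the
  unbiased stage-1 proportion given the complete sufficient pair. On the
  stop regions it equals the MLE; on continuation it is a ratio of
  binomial-coefficient window sums, evaluated in log space with a
  log-sum-exp reduction so that designs with hundreds of patients cannot
  overflow. It is exactly unbiased over the whole design.
* **UMVCUE** — the analogous construction conditional on reaching stage
  2, built from the stage-2 increment $(S_2 - S_1)/(n_2 - n_1)$; defined
  only on the continuation region, exactly conditionally unbiased. The
  **c-UMVCUE** composite extends it with the stage-1 MLE on the stop
  regions so that it can always be reported.
* **MUE** — the median unbiased estimate
  $(p^+ + p^-)/2$ with $K(t, p^+) = 0.5$ and $K(t+1, p^-) = 0.5$. $K$ is
  strictly increasing in $p$ between its 0 and 1 plateaus, so each root
  is unique and bracketed on $(0,1)$. At the sample-space edges the
  defining equations have no root ($K(0,\cdot) \equiv 1$ and, by the
  convention $K(n_2+1,\cdot) := 0$, the upper one); the package sets
  $p^+ := 0$ at $t = 0$ and $p^- := 1$ at $t = n_2$. These edge values
  are a choice, not forced by the definition; they matter only through
  the negligible pmf mass at the extreme outcomes.

Inverting $K$ at $\alpha/2$ and $1 - \alpha/2$ instead of $0.5$ gives
conservative confidence bounds (`confidence_bounds()`) whose exact
coverage — a sum of pmf mass over outcomes whose interval covers $p$ —
is at least the nominal level; this is asserted in the tests.

`twostage_estimate()` bundles the estimators, the p-value $K(t, p_0)$ and
the confidence bounds for one observed trial into a classed object with
`print()`, `summary()`, `coef()` and `confint()` methods.

## Exact performance and scenarios

For a design and estimator, bias and MSE are exact expectations against
the pmf of $T$ (`estimator_bias()`, `estimator_mse()`), optionally
conditional on reaching stage 2 — the estimator values do not depend on
$p$, so a performance curve over $p$ costs one pmf evaluation per point.
Conditional quantities never involve $u_2$, which the tests exploit as an
invariance check.

Uniform-prior averages $\frac{1}{p_1-p_0}\int_{p_0}^{p_1} f(p)\,dp$ use
Gauss–Legendre quadrature with $n_2 + 3$ nodes. Unconditional bias, MSE
and ESS are polynomials in $p$ of degree at most $n_2$, so this rule is
exact to rounding; conditional curves are smooth rational functions and
get a larger fixed rule (at least 81 nodes). Average *absolute* bias is
not smooth at sign changes, so the bias curve's roots are located first
(sign scan on a 401-point grid plus root polishing) and each signed piece
is integrated exactly. When the whole curve is below $10^{-13}$ the
estimator is uniformly unbiased to rounding and the average is reported
as exactly 0. Two definitions of averaged "|bias|" are conceivable —
$\int |b(p)| dp$ and $|\int b(p) dp|$; the package's averaged profiles
use the former, which is the definition under which the published
uniform-scenario tables for the bias-corrected MLE reproduce exactly,
and the latter remains available as
`abs(averaged_criterion(..., f = "bias"))`.

An `eval_scenario()` fixes where ESS and the estimation criteria are
evaluated (a point or a uniform prior), whether the criteria are
conditional, and which estimators compete. Presets: `"1"` (ESS at $p_0$,
criteria at $p_1$, unconditional, composite c-UMVCUE), `"2"` (everything
uniform-averaged), `"4"` (criteria conditional on stage 2 with the plain
UMVCUE). The unconditional-conditioning variant sometimes labelled
scenario 3 coincides with preset 1 when combined with point evaluation,
so it has no separate preset.

## The admissible search

`admissible_search()` enumerates every design tuple within the bounds
that meets the error constraints exactly, evaluates all
(design, estimator) pairings at (|bias|, MSE, ESS), rescales each
criterion onto $[0,1]$ over the feasible set (the |bias| minimum is
anchored at 0 because an exactly unbiased estimator is always present),
and minimises $\omega_1 |b|^* + \omega_2 \mathrm{MSE}^* +
\omega_3 \mathrm{ESS}^*$ over a simplex grid of weights (default step
0.01, 5151 vectors). The union of minimisers is the admissible set, and
the full weight-to-pairing map is returned (the data behind
weight-region plots).

Two numerical design choices deserve comment.

* **Tie handling.** At boundary weights a zero component blanks out whole
  criteria: with all weight on bias, every exactly unbiased pairing
  scores zero, and taking "all tied pairings" literally would declare
  hundreds of thousands of pairings admissible. Ties in the weighted
  score are therefore broken lexicographically on
  (MSE\*, ESS\*, |bias|\*); pairings tied on the full key — notably
  designs differing only in $u_2$, whose estimation criteria are
  identical — are all recorded. With all weight on bias this selects the
  unbiased pairing with the smallest MSE, which is also the natural
  statistical choice.
* **Degenerate designs.** The feasible set legitimately contains designs
  whose stopping rules almost never trigger (for instance $l_1 = -1$
  with a barely reachable efficacy bound). On such designs the MLE is
  (nearly) unbiased and, with all $n_2$ patients almost surely observed,
  has a small MSE, so they can be admissible near the all-bias corner.
  They are not filtered out: any non-vacuity threshold would be
  arbitrary, and on exactly-single-stage classes the MLE and UMVUE
  coincide and tie. Users who consider them artefacts can exclude them
  through the search bounds.

The search bounds default to $n_1 \ge 5$ and $n_2 \le 60$ and are fully
user-configurable; published admissible sets for the same constraints
were evidently derived from narrower candidate sets, and an exhaustive
enumeration can find designs with smaller null-ESS that displace
individual published pairings while leaving every per-pairing criterion
value reproducible. Membership of the admissible set therefore depends
on the bounds in a way that per-design numbers do not.

The per-class criteria evaluation and the weight-grid argmin are
implemented in C++ (the feasible set at the default bounds has ~260,000
estimation classes; the full Shuster search runs in about 2–3 minutes on
one CPU, the Simon search in seconds). The R implementations of the same
quantities are the reference path, and a test asserts the two agree to
$10^{-8}$.

## The trial simulator

`simulate_trials()` draws $S_1 \sim \mathrm{Bin}(n_1, p)$, applies the
stopping rules, and adds an independent $\mathrm{Bin}(n_2 - n_1, p)$
increment when the trial continues. Both stage draws are made for every
replicate whether or not they are used, so replicate $i$ always consumes
the same random variates and a longer run extends a shorter one
replicate-for-replicate under the same seed. The simulator emulates the
trial mechanics only — no accrual timing, covariates, or interim-timing
jitter — so agreement between simulated and exact quantities validates
the probability algebra, not the realism of any particular trial. It
serves as the independent Monte-Carlo oracle in the test suite
(rejection rates, ESS, estimator means and MSEs within four standard
errors at $10^6$ replicates; chi-square goodness of fit of the $T$
frequencies).

## Numerical choices, tie-breaks, tolerances

* Binomial pmf/tails come from `stats::dbinom`/`stats::pbinom` in R; the
  compiled search path recomputes the pmf by a mode-anchored ratio
  recurrence (one `exp` per vector, no underflow) and was checked against
  the R path.
* Root-finding: `stats::uniroot` at tolerance $10^{-12}$ in R; a
  safeguarded regula-falsi (Illinois) iteration to $10^{-10}$ in the
  compiled path. MUE half-roots increase with $t$, and the compiled path
  starts each root at the previous one.
* Sums $K$, pmf normalisation and unbiasedness hold to $10^{-10}$ or
  better on a $p$ grid; small-design quantities match exhaustive
  $2^{n_2}$-path enumeration to $10^{-12}$.
* Degenerate inputs: $t = 0$ and $t = n_2$ use the MUE/bound edge
  conventions above; a design whose continuation region is empty is
  rejected at construction; conditional quantities error when the
  continuation probability is zero.

## Problem sizes used in the checks

The bundled tests evaluate full profiles for designs up to $n_2 = 60$,
run the complete admissible searches at the default bounds, use
$10^6$-replicate simulations for the Monte-Carlo agreement checks, and
$2^{n_2}$-path enumeration for designs with $n_2 \le 8$. These sizes were
chosen so the entire suite exercises every code path at the scale the
method is actually used at (phase II trials rarely exceed a few dozen
patients per stage).

## Known limitations

* Only the stage-wise ordering is implemented; likelihood-ratio or
  MLE orderings of the sample space would give different p-values and
  MUEs.
* Two-stage designs only: the T mapping generalises to more stages, but
  nothing here implements that.
* The admissible set (not the per-pairing values) depends on the
  enumeration bounds and on the weight-grid step; refining the grid can
  only enlarge it.
* Exact binomial computation throughout; no large-sample approximations
  are available or needed at these sample sizes.
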