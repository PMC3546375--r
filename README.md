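# phase2est

Exact design and estimation for single-arm two-stage phase II trials
with a binary endpoint.

Two-stage designs stop early for futility (and optionally for efficacy),
which makes them cheaper and more ethical than single-stage trials with
the same error rates — but the stopping rule biases the usual response
rate estimate $\hat p$, sometimes substantially, and most for the very
designs that minimise expected sample size. This package provides, with
exact binomial computation throughout:

* **Designs and operating characteristics.** A design
  $\Omega = (n_1, l_1, u_1, n_2, u_2)$ stops at stage 1 if $S_1 \le l_1$
  (futility) or $S_1 \ge u_1$ (efficacy), otherwise recruits to $n_2$
  and rejects $H_0\colon p = p_0$ iff $S_2 \ge u_2$. Exact type I error,
  power, expected sample size, and exhaustive enumeration of all designs
  meeting given $(\alpha, \beta)$ constraints.
* **The T statistic.** The terminal (stage, responses) pair is mapped
  injectively onto an integer $T \in \{0, \dots, n_2\}$ ordering the
  whole sample space by evidence against $H_0$ (stage-wise /
  Fairbanks–Madsen ordering), with exact pmf and p-value function
  $K(t, p) = P(T \ge t \mid p)$.
* **Five point estimators on the T scale** — MLE, bias-corrected MLE
  (Whitehead's relation), UMVUE (Rao–Blackwell), UMVCUE (conditionally
  unbiased, stage 2 only) with its composite extension, and the median
  unbiased estimate from $K(t,p^+) = K(t+1,p^-) = 0.5$ — plus exact
  confidence bounds by inverting $K$.
* **Exact estimator performance**: bias and MSE over the whole design or
  conditional on reaching stage 2, at a point or averaged over a
  Uniform$(p_0, p_1)$ prior (Gauss–Legendre, exact for the polynomial
  integrands).
* **Admissible design-and-estimator pairings**: every feasible design ×
  estimator is scored on rescaled (|bias|, MSE, ESS) and minimised over
  a simplex grid of weights; the pairings winning somewhere form the
  admissible set, with the full weight-to-pairing map.
* A Monte-Carlo **trial simulator** (the independent oracle in the test
  suite) and a thin **CLI** (`inst/cli/phase2est`) with `estimate`,
  `evaluate`, `search`, `admissible`, `simulate` subcommands driven by a
  YAML config.

## Worked example

A design requiring at most 5% type I error at $p_0 = 0.2$ and at least
90% power at $p_1 = 0.4$:

```r
library(phase2est)
d <- two_stage_design(n1 = 19, l1 = 4, u1 = 14, n2 = 54, u2 = 16)
summary(d, p0 = 0.2, p1 = 0.4)
#> Two-stage design (n1=19, l1=4, u1=14, n2=54, u2=16) -- Shuster-type (futility and efficacy stops)
#>   stage 1: stop for futility if S1 <= 4, for efficacy if S1 >= 14; continue if 5 <= S1 <= 13
#>   stage 2: reject H0 if S2 >= 16 (out of 54)
#>   exact type I error at p0=0.2 : 0.04817
#>   exact power       at p1=0.4 : 0.90447
#>   E[N] at p0: 30.43   E[N] at p1: 51.46   P(stop at stage 1 | p0): 0.6733
```

The trial runs, continues past stage 1, and ends with 20 responses out
of 54. What is $p$?

```r
fit <- twostage_estimate(d, stage = 2, responses = 20, p0 = 0.2)
fit
#> Two-stage trial outcome: stage 2, 20 responses (T = 20, continuation region)
#>          estimate
#> mle        0.3704
#> bc_mle     0.3818
#> umvue      0.3826
#> c_umvcue   0.3637
#> umvcue     0.3637
#> mue        0.3734
#> p-value K(t, p0=0.2) = 0.00264
#> 95% exact CI (stage-wise ordering): [0.2441, 0.5179]
```

The naive proportion 20/54 = 0.370 underestimates: outcomes this high
would sometimes have triggered the efficacy stop, and conditioning on
*not* stopping pulls the MLE down. The UMVUE (0.383) removes that bias
exactly; the p-value 0.0026 and the exact 95% interval come from the
stage-wise ordering of the sample space.

How much does estimator choice matter for this design class, and which
design/estimator combinations are jointly efficient?

```r
pr <- performance_profile(two_stage_design(11, 2, 5, 31, 10), "bc_mle",
                          standard_scenario("1", p0 = 0.2, p1 = 0.4))
unlist(pr)
#>          ess     abs_bias          mse
#> 17.643777536  0.008251926  0.017863666

adm <- admissible_search(0.2, 0.4, alpha = 0.1, beta = 0.2,
                         family = "shuster")  # ~2-3 min, exhaustive
unique(adm$pairings$estimator)
#> [1] "bc_mle" "umvue"
```

At these constraints only the bias-corrected MLE and the UMVUE survive
the three-criteria trade-off anywhere on the weight simplex: the UMVUE
where bias matters most, the BC-MLE where MSE does.

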