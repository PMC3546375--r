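#' Exact bias and mean squared error of an estimator under a design
#'
#' `estimator_bias()` is the exact expectation of the estimator minus `p`,
#' computed by summing estimator values against the exact distribution of
#' the T statistic; `estimator_mse()` replaces the estimator value by its
#' squared deviation from `p`. With `conditional = TRUE` the expectation is
#' taken over the continuation region only, against the distribution of T
#' conditional on the trial reaching stage 2. The UMVCUE exists only
#' conditionally; asking for its unconditional bias is an error (use
#' `"c_umvcue"` for the composite that covers the stop regions).
#'
#' @param d a [two_stage_design()].
#' @param estimator an estimator id (see [estimate_p()]).
#' @param p true response probability (vectorised).
#' @param conditional condition on reaching stage 2?
#' @return Signed bias (or MSE), vectorised over `p`.
#' @export
estimator_bias <- function(d, estimator, p, conditional = FALSE) {
  moment_vs_pmf(d, estimator, p, conditional, what = "bias")
}

#' @rdname estimator_bias
#' @export
estimator_mse <- function(d, estimator, p, conditional = FALSE) {
  moment_vs_pmf(d, estimator, p, conditional, what = "mse")
}

moment_vs_pmf <- function(d, estimator, p, conditional, what) {
  d <- as_design(d)
  estimator <- match.arg(estimator, ESTIMATOR_IDS)
  if (estimator == "umvcue" && !conditional)
    stop("the UMVCUE has no unconditional moments; use estimator 'c_umvcue'",
         call. = FALSE)
  ev <- estimator_values(d, estimator)
  moment_curve(d, ev, p, conditional, what)
}

## bias/MSE at p for a precomputed vector of estimator values over 0..n2;
## the values do not depend on p, so callers that sweep p (quadrature, the
## admissible search) compute them once
moment_curve <- function(d, ev, p, conditional, what) {
  if (conditional) ev <- ev[t_regions(d)$continuation + 1L]
  vapply(p, function(pp) {
    w <- t_pmf(d, pp, conditional = conditional)
    if (what == "bias") sum(ev * w) - pp else sum((ev - pp)^2 * w)
  }, numeric(1))
}

## Gauss-Legendre nodes/weights on [a, b]
gl_rule <- function(n, a, b) pracma::gaussLegendre(n, a, b)

#' Criteria averaged over a uniform prior on p
#'
#' \eqn{\frac{1}{b-a}\int_a^b f(p)\,dp} for `f` one of the exact criterion
#' curves: signed bias, absolute bias, MSE, or expected sample size.
#' Unconditional bias, MSE and ESS are polynomials in `p` (the estimator
#' values do not depend on `p`), so Gauss–Legendre quadrature with
#' `n2 + 3` nodes integrates them exactly to rounding. Conditional curves
#' are smooth rational functions and are integrated with a larger fixed
#' rule. Absolute bias is handled by locating the sign changes of the bias
#' curve first and integrating each signed piece exactly, so
#' `averaged_criterion(..., f = "abs_bias")` is the average of `|bias(p)|`;
#' the magnitude of the average signed bias is available as
#' `abs(averaged_criterion(..., f = "bias"))`.
#'
#' @param d a [two_stage_design()].
#' @param f criterion: `"bias"`, `"abs_bias"`, `"mse"` or `"ess"`.
#' @param estimator estimator id (ignored for `f = "ess"`).
#' @param prior numeric `c(a, b)` with `0 <= a < b <= 1`.
#' @param conditional condition bias/MSE on reaching stage 2?
#' @return The averaged criterion value.
#' @export
averaged_criterion <- function(d, f = c("bias", "abs_bias", "mse", "ess"),
                               estimator = NULL, prior, conditional = FALSE) {
  d <- as_design(d)
  f <- match.arg(f)
  stopifnot(length(prior) == 2L, prior[1] >= 0, prior[1] < prior[2],
            prior[2] <= 1)
  a <- prior[1]; b <- prior[2]
  n_nodes <- if (conditional) max(d$n2 + 3L, 81L) else d$n2 + 3L
  if (f == "ess") {
    fun <- function(p) ess(d, p)
  } else {
    if (is.null(estimator))
      stop("an estimator is required for bias/MSE criteria", call. = FALSE)
    estimator <- match.arg(estimator, ESTIMATOR_IDS)
    if (estimator == "umvcue" && !conditional)
      stop("the UMVCUE has no unconditional moments; use 'c_umvcue'",
           call. = FALSE)
    ev <- estimator_values(d, estimator)
    what <- if (f == "mse") "mse" else "bias"
    fun <- function(p) moment_curve(d, ev, p, conditional, what)
  }
  if (f != "abs_bias") {
    r <- gl_rule(n_nodes, a, b)
    return(sum(r$w * vapply(r$x, fun, numeric(1))) / (b - a))
  }
  ## |bias|: split [a, b] at the sign changes of the bias curve, then each
  ## piece is integrated with the same (piecewise-exact) rule
  grid <- seq(a, b, length.out = 401L)
  g <- vapply(grid, fun, numeric(1))
  if (max(abs(g)) < 1e-13) return(0)  # uniformly unbiased to rounding
  cross <- which(g[-1L] * g[-length(g)] < 0)
  cuts <- vapply(cross, function(i)
    stats::uniroot(fun, lower = grid[i], upper = grid[i + 1L],
                   tol = 1e-13)$root, numeric(1))
  br <- c(a, cuts, b)
  total <- 0
  for (k in seq_len(length(br) - 1L)) {
    r <- gl_rule(n_nodes, br[k], br[k + 1L])
    total <- total + abs(sum(r$w * vapply(r$x, fun, numeric(1))))
  }
  total / (b - a)
}

#' Evaluation scenarios for design-and-estimator performance
#'
#' A scenario says where the expected sample size is evaluated, where the
#' estimation criteria (|bias|, MSE) are evaluated — a point `p` or a
#' `Uniform(a, b)` prior — whether the criteria are conditional on reaching
#' stage 2, and which estimators compete. Three presets cover the standard
#' cases:
#' * `"1"` — ESS at `p0`, bias/MSE at `p1`, unconditional, estimators
#'   `{mle, bc_mle, umvue, c_umvcue, mue}` (the composite covers early
#'   stops);
#' * `"2"` — everything averaged over `Uniform(p0, p1)`, unconditional,
#'   same estimator set;
#' * `"4"` — ESS at `p0`, bias/MSE at `p1` conditional on reaching stage 2,
#'   estimators `{mle, bc_mle, umvue, umvcue, mue}` (the plain UMVCUE,
#'   defined there). Conditioning with point evaluation and the composite
#'   estimator is exactly preset `"1"`, which is why there is no separate
#'   preset `"3"`.
#'
#' @param ess_eval a single `p` or `c(a, b)` for a uniform prior.
#' @param perf_eval as `ess_eval`, for bias and MSE.
#' @param conditional logical.
#' @param estimators character vector of estimator ids.
#' @return An object of class `eval_scenario`.
#' @export
eval_scenario <- function(ess_eval, perf_eval, conditional = FALSE,
                          estimators = c("mle", "bc_mle", "umvue",
                                         "c_umvcue", "mue")) {
  chk <- function(x, nm) {
    if (!length(x) %in% 1:2 || any(x < 0) || any(x > 1) ||
        (length(x) == 2L && x[1] >= x[2]))
      stop(sprintf("%s must be a probability or an increasing pair in [0,1]", nm),
           call. = FALSE)
    x
  }
  estimators <- match.arg(estimators, ESTIMATOR_IDS, several.ok = TRUE)
  if ("umvcue" %in% estimators && !conditional)
    stop("the UMVCUE can only enter a conditional scenario; use 'c_umvcue'",
         call. = FALSE)
  structure(list(ess_eval = chk(ess_eval, "ess_eval"),
                 perf_eval = chk(perf_eval, "perf_eval"),
                 conditional = isTRUE(conditional),
                 estimators = estimators),
            class = "eval_scenario")
}

#' @rdname eval_scenario
#' @param preset one of `"1"`, `"2"`, `"4"`.
#' @param p0,p1 null and target response probabilities.
#' @export
standard_scenario <- function(preset = c("1", "2", "4"), p0, p1) {
  preset <- match.arg(as.character(preset), c("1", "2", "4"))
  switch(preset,
    "1" = eval_scenario(p0, p1, conditional = FALSE),
    "2" = eval_scenario(c(p0, p1), c(p0, p1), conditional = FALSE),
    "4" = eval_scenario(p0, p1, conditional = TRUE,
                        estimators = c("mle", "bc_mle", "umvue", "umvcue",
                                       "mue")))
}

#' @export
print.eval_scenario <- function(x, ...) {
  fmt <- function(e) if (length(e) == 2L)
    sprintf("Uniform(%.3g, %.3g)", e[1], e[2]) else sprintf("p = %.3g", e[1])
  cat(sprintf("Evaluation scenario: ESS at %s; %s bias/MSE at %s\n",
              fmt(x$ess_eval),
              if (x$conditional) "conditional (stage 2)" else "unconditional",
              fmt(x$perf_eval)))
  cat("  estimators:", paste(x$estimators, collapse = ", "), "\n")
  invisible(x)
}

#' Performance profile of a (design, estimator) pair under a scenario
#'
#' Assembles the triple (ESS, |bias|, MSE) that the admissible search
#' trades off. For point evaluation |bias| is the magnitude of the exact
#' bias; for uniform evaluation it is the average of `|bias(p)|` (see
#' [averaged_criterion()]).
#'
#' @param d a [two_stage_design()].
#' @param estimator estimator id.
#' @param scenario an [eval_scenario()].
#' @return A list with `ess`, `abs_bias`, `mse`.
#' @examples
#' d <- two_stage_design(11, 2, 5, 31, 10)
#' sc <- standard_scenario("1", p0 = 0.2, p1 = 0.4)
#' performance_profile(d, "bc_mle", sc)
#' @export
performance_profile <- function(d, estimator, scenario) {
  d <- as_design(d)
  stopifnot(inherits(scenario, "eval_scenario"))
  estimator <- match.arg(estimator, ESTIMATOR_IDS)
  if (estimator == "umvcue" && !scenario$conditional)
    stop("the UMVCUE requires a conditional scenario; use 'c_umvcue'",
         call. = FALSE)
  ess_v <- if (length(scenario$ess_eval) == 2L) {
    averaged_criterion(d, "ess", prior = scenario$ess_eval)
  } else ess(d, scenario$ess_eval)
  if (length(scenario$perf_eval) == 2L) {
    ab <- averaged_criterion(d, "abs_bias", estimator, scenario$perf_eval,
                             scenario$conditional)
    ms <- averaged_criterion(d, "mse", estimator, scenario$perf_eval,
                             scenario$conditional)
  } else {
    ab <- abs(estimator_bias(d, estimator, scenario$perf_eval,
                             scenario$conditional))
    ms <- estimator_mse(d, estimator, scenario$perf_eval,
                        scenario$conditional)
  }
  list(ess = ess_v, abs_bias = ab, mse = ms)
}
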