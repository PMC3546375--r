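ESTIMATOR_IDS <- c("mle", "bc_mle", "umvue", "umvcue", "c_umvcue", "mue")

## log-sum-exp over a vector of log terms (all terms non-negative on the
## natural scale); keeps hypergeometric-style binomial-coefficient ratios
## stable for n2 up to several hundred
lse <- function(lx) {
  lx <- lx[lx > -Inf]
  if (!length(lx)) return(-Inf)
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

## ---- per-design value vectors over t = 0..n2 ------------------------------

mle_values <- function(d) {
  t <- 0:d$n2
  shift <- d$n2 - d$n1
  reg <- t_region_of(d, t)
  ifelse(reg == "futility", t / d$n1,
         ifelse(reg == "efficacy", (t - shift) / d$n1, t / d$n2))
}

umvue_cont_value <- function(d, t) {
  lim <- t_limits(d, t)
  x <- lim$lb:lim$ub
  m <- d$n2 - d$n1
  num <- lse(lchoose(d$n1 - 1L, x - 1L) + lchoose(m, t - x))
  den <- lse(lchoose(d$n1, x) + lchoose(m, t - x))
  exp(num - den)
}

umvcue_cont_value <- function(d, t) {
  lim <- t_limits(d, t)
  x <- lim$lb:lim$ub
  m <- d$n2 - d$n1
  num <- lse(lchoose(d$n1, x) + lchoose(m - 1L, t - x - 1L))
  den <- lse(lchoose(d$n1, x) + lchoose(m, t - x))
  exp(num - den)
}

umvue_values <- function(d) {
  v <- mle_values(d)
  for (t in t_regions(d)$continuation) v[t + 1L] <- umvue_cont_value(d, t)
  v
}

c_umvcue_values <- function(d) {
  v <- mle_values(d)
  for (t in t_regions(d)$continuation) v[t + 1L] <- umvcue_cont_value(d, t)
  v
}

## expected MLE as a function of the true probability q, by the tower
## property over the stage-1 count: stopping values contribute x/n1, each
## continuation value x contributes E[(x + Bin(n2-n1, q))/n2] = (x + m q)/n2
expected_mle <- function(d, q) {
  x <- 0:d$n1
  m <- d$n2 - d$n1
  cont <- x >= d$l1 + 1L & x <= d$u1 - 1L
  W <- matrix(stats::dbinom(rep(x, times = length(q)), d$n1,
                            rep(q, each = d$n1 + 1L)), nrow = d$n1 + 1L)
  stop_part <- colSums(W[!cont, , drop = FALSE] * (x[!cont] / d$n1))
  cont_part <- colSums(W[cont, , drop = FALSE] *
                         outer(x[cont], m * q, `+`) / d$n2)
  stop_part + cont_part
}

bc_mle_values <- function(d, tol = 1e-11) {
  mv <- mle_values(d)
  qs <- seq(0, 1, length.out = 201L)
  Eg <- expected_mle(d, qs)
  vapply(mv, function(target) {
    g <- Eg - target
    sgn <- sign(g)
    ## grid points hitting the target exactly
    hit <- which(g == 0)
    if (length(hit)) return(qs[hit[1L]])
    ch <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
    if (!length(ch)) {
      warning("bias-corrected MLE: no root in [0, 1]; returning boundary",
              call. = FALSE)
      return(if (abs(g[1L]) < abs(g[length(g)])) 0 else 1)
    }
    roots <- vapply(ch, function(i) {
      stats::uniroot(function(q) expected_mle(d, q) - target,
                     lower = qs[i], upper = qs[i + 1L],
                     tol = tol)$root
    }, numeric(1))
    roots[which.min(abs(roots - target))]
  }, numeric(1))
}

## root of K(t, p) = target in p; K is strictly increasing in p wherever it
## is inside (0, 1), with K(t, 0) = 0 and K(t, 1) = 1 for 1 <= t <= n2
k_root <- function(d, t, target) {
  if (t <= 0) stop("K(0, p) is identically 1; no root", call. = FALSE)
  if (t > d$n2) stop("K(n2 + 1, p) is identically 0; no root", call. = FALSE)
  stats::uniroot(function(p) fm_pvalue(d, t, p) - target,
                 lower = 0, upper = 1, tol = 1e-12, maxiter = 1000L)$root
}

## MUE half-roots r[t] : K(t, r) = 0.5 for t = 1..n2, with the edge
## conventions r[0] := 0 and r[n2 + 1] := 1
mue_roots <- function(d) {
  c(0, vapply(1:d$n2, function(t) k_root(d, t, 0.5), numeric(1)), 1)
}

mue_values <- function(d) {
  r <- mue_roots(d)
  (r[1:(d$n2 + 1L)] + r[2:(d$n2 + 2L)]) / 2
}

estimator_values <- function(d, estimator) {
  estimator <- match.arg(estimator, ESTIMATOR_IDS)
  switch(estimator,
         mle = mle_values(d),
         bc_mle = bc_mle_values(d),
         umvue = umvue_values(d),
         c_umvcue = c_umvcue_values(d),
         mue = mue_values(d),
         umvcue = {
           v <- rep(NA_real_, d$n2 + 1L)
           for (t in t_regions(d)$continuation)
             v[t + 1L] <- umvcue_cont_value(d, t)
           v
         })
}

## ---- user-facing estimation ----------------------------------------------

#' Point estimators of the response probability on the T scale
#'
#' Evaluates one of the five estimators at T-statistic value(s) `t`:
#' * `"mle"` — the observed proportion at termination: `t/n1` (futility),
#'   `(t-(n2-n1))/n1` (efficacy), `t/n2` (stage 2);
#' * `"bc_mle"` — the bias-corrected MLE: the value `q` at which the exact
#'   expectation of the MLE equals the observed MLE (Whitehead's relation),
#'   found by bracketed root-finding on `[0, 1]`;
#' * `"umvue"` — the Rao–Blackwellisation of the stage-1 proportion given
#'   `(M, S)`; equal to the MLE on the stop regions and a ratio of
#'   binomial-coefficient sums (computed in log space) on continuation;
#'   exactly unbiased over the whole design;
#' * `"umvcue"` — the minimum-variance estimator unbiased conditional on
#'   reaching stage 2 (defined only on the continuation region; `NA` and an
#'   error elsewhere);
#' * `"c_umvcue"` — the composite: UMVCUE on continuation, stage-1 MLE on
#'   the stop regions;
#' * `"mue"` — the median unbiased estimate, the average of the two roots
#'   `K(t, p) = 0.5` and `K(t+1, p) = 0.5` (with `p+ := 0` at `t = 0` and
#'   `p- := 1` at `t = n2`).
#'
#' @param d a [two_stage_design()].
#' @param t T-statistic value(s) in `0..n2`.
#' @param estimator one of `"mle"`, `"bc_mle"`, `"umvue"`, `"umvcue"`,
#'   `"c_umvcue"`, `"mue"`.
#' @return Estimates in `[0, 1]`, vectorised over `t`.
#' @examples
#' d <- two_stage_design(19, 4, 14, 54, 16)
#' estimate_p(d, 20, "mle")     # 20/54
#' estimate_p(d, 20, "umvue")
#' @export
estimate_p <- function(d, t, estimator = ESTIMATOR_IDS) {
  d <- as_design(d)
  estimator <- match.arg(estimator)
  check_t(d, t)
  if (estimator == "umvcue" &&
      any(t_region_of(d, t) != "continuation"))
    stop("the UMVCUE is defined only on the continuation region; use 'c_umvcue'",
         call. = FALSE)
  estimator_values(d, estimator)[t + 1L]
}

#' Median unbiased estimate with its two half-roots
#'
#' @inheritParams estimate_p
#' @param t a single T-statistic value in `0..n2`.
#' @return A list with `value`, `p_plus` (root of `K(t, p) = 0.5`) and
#'   `p_minus` (root of `K(t+1, p) = 0.5`).
#' @export
mue_components <- function(d, t) {
  d <- as_design(d)
  stopifnot(length(t) == 1L)
  check_t(d, t)
  p_plus <- if (t == 0) 0 else k_root(d, t, 0.5)
  p_minus <- if (t == d$n2) 1 else k_root(d, t + 1L, 0.5)
  list(value = (p_plus + p_minus) / 2, p_plus = p_plus, p_minus = p_minus)
}

#' Exact confidence bounds under the stage-wise ordering
#'
#' Conservative bounds obtained by inverting the p-value function: the
#' lower bound solves `K(t, p) = alpha/2` and the upper bound solves
#' `K(t+1, p) = 1 - alpha/2`. At the sample-space edges the bounds are 0
#' (`t = 0`) and 1 (`t = n2`) by convention, since `K(0, p) = 1` and
#' `K(n2+1, p) = 0` identically.
#'
#' @inheritParams mue_components
#' @param alpha two-sided error level (the interval has exact coverage at
#'   least `1 - alpha`).
#' @return Named vector `c(lower, upper)`.
#' @export
confidence_bounds <- function(d, t, alpha = 0.05) {
  d <- as_design(d)
  stopifnot(length(t) == 1L, alpha > 0, alpha < 1)
  check_t(d, t)
  lower <- if (t == 0) 0 else k_root(d, t, alpha / 2)
  upper <- if (t == d$n2) 1 else k_root(d, t + 1L, 1 - alpha / 2)
  c(lower = lower, upper = upper)
}
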