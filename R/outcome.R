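#' Regions of the T statistic
#'
#' The terminal outcome of a two-stage trial — the stopping stage `M` and
#' the response count `S` at termination — is mapped injectively onto a
#' single integer statistic `T` in `0..n2` that orders the whole sample
#' space by strength of evidence against the null (the stage-wise,
#' Fairbanks–Madsen ordering):
#' * futility region `t <= l1`: stage-1 futility stop with `S1 = t`;
#' * continuation region `l1+1 <= t <= (n2-n1)+u1-1`: stage-2 outcome with
#'   `S2 = t`;
#' * efficacy region `t >= (n2-n1)+u1`: stage-1 efficacy stop with
#'   `S1 = t - (n2-n1)`.
#'
#' @param d a [two_stage_design()].
#' @return A list of integer vectors `futility`, `continuation`, `efficacy`
#'   partitioning `0..n2`.
#' @export
t_regions <- function(d) {
  d <- as_design(d)
  shift <- d$n2 - d$n1
  list(
    futility = if (d$l1 >= 0L) 0:d$l1 else integer(),
    continuation = seq.int(d$l1 + 1L, shift + d$u1 - 1L),
    efficacy = if (d$u1 <= d$n1) seq.int(shift + d$u1, d$n2) else integer()
  )
}

t_region_of <- function(d, t) {
  shift <- d$n2 - d$n1
  ifelse(t <= d$l1, "futility",
         ifelse(t >= shift + d$u1, "efficacy", "continuation"))
}

## within-continuation summation limits for S1 given T = t
t_limits <- function(d, t) {
  list(lb = max(d$l1 + 1L, t - (d$n2 - d$n1)), ub = min(t, d$u1 - 1L))
}

#' Map a terminal trial outcome to its T statistic
#'
#' `T = S` for a stage-1 futility stop or any stage-2 outcome, and
#' `T = S + (n2 - n1)` for a stage-1 efficacy stop, so that larger `T`
#' always means stronger evidence against the null.
#'
#' @param d a [two_stage_design()].
#' @param stage stopping stage, 1 or 2.
#' @param responses total responses observed at termination (`S1` if
#'   `stage = 1`, `S2` if `stage = 2`).
#' @return Integer `t` in `0..n2`.
#' @examples
#' d <- two_stage_design(19, 4, 14, 54, 16)
#' t_statistic(d, stage = 1, responses = 3)   # futility stop: t = 3
#' t_statistic(d, stage = 1, responses = 14)  # efficacy stop: t = 49
#' t_statistic(d, stage = 2, responses = 20)  # stage 2:       t = 20
#' @export
t_statistic <- function(d, stage, responses) {
  d <- as_design(d)
  s <- responses
  if (length(stage) != 1L || !stage %in% c(1, 2))
    stop("stage must be 1 or 2", call. = FALSE)
  if (length(s) != 1L || is.na(s) || s != round(s))
    stop("responses must be a single integer", call. = FALSE)
  shift <- d$n2 - d$n1
  if (stage == 1) {
    if (s < 0 || s > d$n1 || (s > d$l1 && s < d$u1))
      stop(sprintf("stage-1 stop with S1 = %d is inconsistent with the design", s),
           call. = FALSE)
    if (s <= d$l1) as.integer(s) else as.integer(s + shift)
  } else {
    if (s < d$l1 + 1L || s > d$u1 - 1L + shift)
      stop(sprintf("stage-2 total S2 = %d is inconsistent with the design", s),
           call. = FALSE)
    as.integer(s)
  }
}

#' Inverse of the T mapping
#'
#' @inheritParams t_statistic
#' @param t value of the T statistic, in `0..n2`.
#' @return A list with elements `stage` and `responses`.
#' @export
outcome_from_t <- function(d, t) {
  d <- as_design(d)
  check_t(d, t)
  shift <- d$n2 - d$n1
  switch(t_region_of(d, t),
         futility = list(stage = 1L, responses = as.integer(t)),
         efficacy = list(stage = 1L, responses = as.integer(t - shift)),
         continuation = list(stage = 2L, responses = as.integer(t)))
}

check_t <- function(d, t, allow_next = FALSE) {
  hi <- d$n2 + if (allow_next) 1L else 0L
  if (any(t != round(t)) || any(t < 0) || any(t > hi))
    stop(sprintf("t must be an integer in 0..%d", hi), call. = FALSE)
  invisible(t)
}

#' Exact distribution of the T statistic
#'
#' `P(T = t | p)` over the full sample space `t = 0..n2`:
#' `h(n1, t, p)` on the futility region, `h(n1, t - (n2-n1), p)` on the
#' efficacy region, and on the continuation region
#' \deqn{\sum_{x = LB}^{UB} h(n_1, x, p)\, h(n_2 - n_1, t - x, p),}
#' with `LB = max(l1+1, t-(n2-n1))`, `UB = min(t, u1-1)`. With
#' `conditional = TRUE` the continuation-region mass is renormalised by the
#' probability of reaching stage 2 and only those `t` are returned.
#'
#' @param d a [two_stage_design()].
#' @param p true response probability.
#' @param conditional condition on the trial reaching stage 2?
#' @return A named numeric vector of probabilities (names are `t` values);
#'   sums to 1 in either case.
#' @export
t_pmf <- function(d, p, conditional = FALSE) {
  d <- as_design(d)
  stopifnot(length(p) == 1L, p >= 0, p <= 1)
  shift <- d$n2 - d$n1
  reg <- t_regions(d)
  pmf <- numeric(d$n2 + 1L)
  if (length(reg$futility))
    pmf[reg$futility + 1L] <- binom_pmf(d$n1, reg$futility, p)
  if (length(reg$efficacy))
    pmf[reg$efficacy + 1L] <- binom_pmf(d$n1, reg$efficacy - shift, p)
  for (t in reg$continuation) {
    lim <- t_limits(d, t)
    if (lim$lb <= lim$ub) {
      x <- lim$lb:lim$ub
      pmf[t + 1L] <- sum(binom_pmf(d$n1, x, p) * binom_pmf(shift, t - x, p))
    }
  }
  names(pmf) <- 0:d$n2
  if (conditional) {
    pc <- continuation_prob(d, p)
    if (pc <= 0)
      stop("continuation probability is zero; conditional pmf undefined",
           call. = FALSE)
    pmf <- pmf[reg$continuation + 1L] / pc
  }
  pmf
}

#' Stage-wise-ordering p-value function K(t, p)
#'
#' `K(t, p) = P(T >= t | p)` under the stage-wise (Fairbanks–Madsen)
#' ordering, computed from its closed form rather than by summing the pmf:
#' `H(n1, t, p)` for `t <= l1`; `H(n1, t - (n2-n1), p)` for
#' `t >= (n2-n1)+u1`; and for continuation-region `t`
#' \deqn{H(n_1, u_1, p) + \sum_{x=l_1+1}^{u_1-1} h(n_1, x, p)\,
#'   H(n_2-n_1, t - x, p).}
#' `K` is non-increasing in `t` and non-decreasing in `p`. Evaluated at the
#' observed `t` and `p = p0` it is the trial's p-value. The convention
#' `K(n2 + 1, p) = 0` is honoured (`t = n2 + 1` is accepted).
#'
#' @param d a [two_stage_design()].
#' @param t T-statistic value(s) in `0..n2+1` (vectorised).
#' @param p response probability (vectorised; `t` and `p` are recycled).
#' @return `P(T >= t | p)`.
#' @export
fm_pvalue <- function(d, t, p) {
  d <- as_design(d)
  check_t(d, t, allow_next = TRUE)
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  shift <- d$n2 - d$n1
  cont <- cont_region(d)
  n <- max(length(t), length(p))
  t <- rep_len(t, n); p <- rep_len(p, n)
  vapply(seq_len(n), function(i) {
    ti <- t[i]; pi <- p[i]
    if (ti > d$n2) return(0)
    if (ti <= d$l1) return(binom_sf(d$n1, ti, pi))
    if (ti >= shift + d$u1) return(binom_sf(d$n1, ti - shift, pi))
    binom_sf(d$n1, d$u1, pi) +
      sum(binom_pmf(d$n1, cont, pi) * binom_sf(shift, ti - cont, pi))
  }, numeric(1))
}
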