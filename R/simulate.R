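#' Simulate two-stage trial realisations
#'
#' Monte-Carlo generator used to validate the exact formulas. Each
#' replicate draws the stage-1 count from `Binomial(n1, p)`, applies the
#' stopping rules, and (when the trial continues) adds an independent
#' `Binomial(n2 - n1, p)` stage-2 increment. Both stage draws are made for
#' every replicate regardless of stopping, so replicate `i` consumes a
#' fixed number of random variates: with the same seed, the first `k`
#' replicates of a longer run reproduce a shorter run exactly.
#'
#' @param d a [two_stage_design()].
#' @param p true response probability.
#' @param n_reps number of replicates.
#' @param seed optional integer seed (local to this call).
#' @return A data frame with one row per replicate: `s1`, `stopped_stage1`,
#'   `stop_reason` (`"futility"`, `"efficacy"` or `"continued"`), `s2`
#'   (total responses, `NA` if stopped early), `n_used`, `stage`,
#'   `responses` (count at termination), `t` (the mapped statistic), and
#'   `reject` (the hypothesis decision).
#' @examples
#' d <- two_stage_design(19, 4, 14, 54, 16)
#' sim <- simulate_trials(d, p = 0.4, n_reps = 1000, seed = 1)
#' mean(sim$n_used)   # close to ess(d, 0.4)
#' mean(sim$reject)   # close to trial_power(d, 0.4)
#' @export
simulate_trials <- function(d, p, n_reps, seed = NULL) {
  d <- as_design(d)
  stopifnot(length(p) == 1L, p >= 0, p <= 1, n_reps >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  m <- d$n2 - d$n1
  draws <- matrix(stats::rbinom(2L * n_reps, size = c(d$n1, m), prob = p),
                  nrow = 2L)
  s1 <- draws[1L, ]
  inc2 <- draws[2L, ]
  futility <- s1 <= d$l1
  efficacy <- s1 >= d$u1
  cont <- !futility & !efficacy
  s2 <- ifelse(cont, s1 + inc2, NA_integer_)
  stage <- ifelse(cont, 2L, 1L)
  responses <- ifelse(cont, s2, s1)
  t <- ifelse(cont, s2, ifelse(futility, s1, s1 + m))
  data.frame(
    s1 = s1,
    stopped_stage1 = !cont,
    stop_reason = ifelse(futility, "futility",
                         ifelse(efficacy, "efficacy", "continued")),
    s2 = s2,
    n_used = ifelse(cont, d$n2, d$n1),
    stage = stage,
    responses = responses,
    t = as.integer(t),
    reject = efficacy | (cont & s2 >= d$u2))
}

#' @rdname simulate_trials
#' @param object a [two_stage_design()] (method for [stats::simulate()]).
#' @param nsim number of replicates.
#' @param ... unused.
#' @export
simulate.two_stage_design <- function(object, nsim = 1, seed = NULL, p,
                                      ...) {
  simulate_trials(object, p = p, n_reps = nsim, seed = seed)
}
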