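#' Estimate the response probability from an observed two-stage trial
#'
#' The central analysis entry point: given a design and the observed
#' terminal outcome — either the stopping `stage` and the `responses`
#' observed at termination, or directly the T-statistic value `t` — it
#' evaluates the requested point estimators, the stage-wise-ordering
#' p-value `K(t, p0)` (when `p0` is supplied), and exact confidence bounds.
#'
#' @param d a [two_stage_design()].
#' @param stage stopping stage (1 or 2); give `stage` + `responses`, or `t`.
#' @param responses responses observed at termination.
#' @param t alternatively, the T-statistic value directly.
#' @param estimators character vector of estimator ids (see
#'   [estimate_p()]); `"umvcue"` is dropped with a message when the trial
#'   stopped at stage 1, where it is undefined.
#' @param p0 null response probability for the reported p-value (optional).
#' @param conf.level confidence level for the exact bounds.
#' @return An object of class `twostage_estimate` with components
#'   `design`, `stage`, `responses`, `t`, `estimates` (named numeric),
#'   `mue` (the two half-roots), `ci`, `p_value`.
#' @examples
#' d <- two_stage_design(19, 4, 14, 54, 16)
#' fit <- twostage_estimate(d, stage = 2, responses = 20, p0 = 0.2)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
twostage_estimate <- function(d, stage = NULL, responses = NULL, t = NULL,
                              estimators = c("mle", "bc_mle", "umvue",
                                             "c_umvcue", "umvcue", "mue"),
                              p0 = NULL, conf.level = 0.95) {
  d <- as_design(d)
  if (is.null(t)) {
    if (is.null(stage) || is.null(responses))
      stop("supply either t or both stage and responses", call. = FALSE)
    t <- t_statistic(d, stage, responses)
  } else {
    check_t(d, t)
    o <- outcome_from_t(d, t)
    stage <- o$stage; responses <- o$responses
  }
  estimators <- match.arg(estimators, ESTIMATOR_IDS, several.ok = TRUE)
  if ("umvcue" %in% estimators && t_region_of(d, t) != "continuation") {
    message("trial stopped at stage 1: dropping the UMVCUE (undefined there)")
    estimators <- setdiff(estimators, "umvcue")
  }
  est <- vapply(estimators, function(e) estimate_p(d, t, e), numeric(1))
  out <- list(design = d, stage = stage, responses = responses, t = t,
              estimates = est,
              mue = if ("mue" %in% estimators) mue_components(d, t) else NULL,
              ci = confidence_bounds(d, t, alpha = 1 - conf.level),
              conf.level = conf.level,
              p_value = if (!is.null(p0)) fm_pvalue(d, t, p0) else NULL,
              p0 = p0)
  class(out) <- "twostage_estimate"
  out
}

#' @export
print.twostage_estimate <- function(x, digits = 4, ...) {
  d <- x$design
  cat(sprintf("Two-stage trial outcome: stage %d, %d responses (T = %d, %s region)\n",
              x$stage, x$responses, x$t, t_region_of(d, x$t)))
  tab <- data.frame(estimate = round(x$estimates, digits))
  print(tab)
  if (!is.null(x$p_value))
    cat(sprintf("p-value K(t, p0=%.3g) = %.4g\n", x$p0, x$p_value))
  cat(sprintf("%.0f%% exact CI (stage-wise ordering): [%.*f, %.*f]\n",
              100 * x$conf.level, digits, x$ci[["lower"]],
              digits, x$ci[["upper"]]))
  invisible(x)
}

#' @export
coef.twostage_estimate <- function(object, ...) object$estimates

#' @export
confint.twostage_estimate <- function(object, parm, level = NULL, ...) {
  if (is.null(level) || level == object$conf.level) {
    ci <- object$ci
  } else {
    ci <- confidence_bounds(object$design, object$t, alpha = 1 - level)
  }
  matrix(ci, nrow = 1, dimnames = list("p", c("lower", "upper")))
}

#' @export
summary.twostage_estimate <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$mue))
    cat(sprintf("MUE half-roots: p+ = %.4f (K(t,.)=0.5), p- = %.4f (K(t+1,.)=0.5)\n",
                object$mue$p_plus, object$mue$p_minus))
  invisible(object)
}
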