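#' Construct a two-stage design
#'
#' A single-arm two-stage binomial design is the integer tuple
#' \eqn{\Omega = (n_1, l_1, u_1, n_2, u_2)}: recruit \eqn{n_1} patients at
#' stage 1 and observe \eqn{S_1} responses; stop for futility (accept
#' \eqn{H_0}) if \eqn{S_1 \le l_1}, stop for efficacy (reject \eqn{H_0}) if
#' \eqn{S_1 \ge u_1}; otherwise recruit a further \eqn{n_2 - n_1} patients
#' and reject \eqn{H_0} at stage 2 if the total response count
#' \eqn{S_2 \ge u_2}.
#'
#' Setting `u1 = n1 + 1` disables the stage-1 efficacy stop; such designs
#' stop early for futility only and are conventionally called Simon-type,
#' while designs with `u1 <= n1` (both stops possible) are Shuster-type.
#' `l1 = -1` disables the futility stop. The continuation region
#' `l1+1 .. u1-1` must contain at least one attainable value.
#'
#' @param n1 stage-1 sample size (integer, `1 <= n1 < n2`).
#' @param l1 stage-1 futility bound (integer, `-1 <= l1`).
#' @param u1 stage-1 efficacy bound (integer, `l1 + 2 <= u1 <= n1 + 1`).
#'   Defaults to `n1 + 1` (Simon-type, no efficacy stop).
#' @param n2 total (maximum) sample size (integer, `n2 > n1`).
#' @param u2 stage-2 rejection bound (integer, `0 <= u2 <= n2 + 1`).
#' @return An object of class `two_stage_design`.
#' @examples
#' d <- two_stage_design(n1 = 19, l1 = 4, u1 = 14, n2 = 54, u2 = 16)
#' d
#' type1_error(d, 0.2)
#' trial_power(d, 0.4)
#' ess(d, 0.2)
#' @export
two_stage_design <- function(n1, l1, u1 = n1 + 1, n2, u2) {
  for (v in list(n1, l1, u1, n2, u2)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != round(v))
      stop("design parameters must be single integers", call. = FALSE)
  }
  n1 <- as.integer(n1); l1 <- as.integer(l1); u1 <- as.integer(u1)
  n2 <- as.integer(n2); u2 <- as.integer(u2)
  if (n1 < 1L || n2 <= n1)
    stop("need 1 <= n1 < n2", call. = FALSE)
  if (l1 < -1L || l1 > n1)
    stop("need -1 <= l1 <= n1", call. = FALSE)
  if (u1 > n1 + 1L)
    stop("need u1 <= n1 + 1", call. = FALSE)
  if (l1 + 1L > u1 - 1L || u1 - 1L > n1)
    stop("continuation region l1+1 .. u1-1 must contain at least one value in 0..n1",
         call. = FALSE)
  if (u2 < 0L || u2 > n2 + 1L)
    stop("need 0 <= u2 <= n2 + 1", call. = FALSE)
  structure(list(n1 = n1, l1 = l1, u1 = u1, n2 = n2, u2 = u2),
            class = "two_stage_design")
}

#' @export
print.two_stage_design <- function(x, ...) {
  kind <- if (is_simon(x)) "Simon-type (futility stop only)"
          else "Shuster-type (futility and efficacy stops)"
  cat(sprintf("Two-stage design (n1=%d, l1=%d, u1=%d, n2=%d, u2=%d) -- %s\n",
              x$n1, x$l1, x$u1, x$n2, x$u2, kind))
  cat(sprintf("  stage 1: stop for futility if S1 <= %d%s; continue if %d <= S1 <= %d\n",
              x$l1,
              if (is_simon(x)) "" else sprintf(", for efficacy if S1 >= %d", x$u1),
              x$l1 + 1L, x$u1 - 1L))
  cat(sprintf("  stage 2: reject H0 if S2 >= %d (out of %d)\n", x$u2, x$n2))
  invisible(x)
}

#' Summarise exact operating characteristics of a design
#'
#' @param object a [two_stage_design()].
#' @param p0 null response probability.
#' @param p1 alternative response probability.
#' @param ... unused.
#' @return A list with the exact type I error at `p0`, power at `p1`, and
#'   expected sample sizes at both, printed as a short report.
#' @export
summary.two_stage_design <- function(object, p0 = 0.2, p1 = 0.4, ...) {
  out <- list(design = object, p0 = p0, p1 = p1,
              type1_error = type1_error(object, p0),
              power = trial_power(object, p1),
              ess_p0 = ess(object, p0), ess_p1 = ess(object, p1),
              pet_p0 = 1 - continuation_prob(object, p0))
  class(out) <- "summary.two_stage_design"
  out
}

#' @export
print.summary.two_stage_design <- function(x, ...) {
  print(x$design)
  cat(sprintf("  exact type I error at p0=%.3g : %.5f\n", x$p0, x$type1_error))
  cat(sprintf("  exact power       at p1=%.3g : %.5f\n", x$p1, x$power))
  cat(sprintf("  E[N] at p0: %.2f   E[N] at p1: %.2f   P(stop at stage 1 | p0): %.4f\n",
              x$ess_p0, x$ess_p1, x$pet_p0))
  invisible(x)
}

#' @rdname two_stage_design
#' @param d a `two_stage_design`.
#' @export
is_simon <- function(d) d$u1 == d$n1 + 1L

as_design <- function(d) {
  if (inherits(d, "two_stage_design")) return(d)
  stop("expected a 'two_stage_design' object", call. = FALSE)
}

## stage-1 continuation values l1+1 .. u1-1 (always non-empty by construction)
cont_region <- function(d) seq.int(d$l1 + 1L, d$u1 - 1L)

#' Binomial probability mass with out-of-support zero contract
#'
#' `binom_pmf(n, v, p)` is \eqn{\binom{n}{v} p^v (1-p)^{n-v}} for
#' `0 <= v <= n` and exactly 0 for any other integer `v` (negative or above
#' `n`). This zero contract is what lets one set of formulas cover designs
#' with and without a stage-1 efficacy stop.
#'
#' @param n number of trials (non-negative integer).
#' @param v number of responses (any integer, vectorised).
#' @param p response probability in `[0, 1]`.
#' @return Probability (vectorised over `v`).
#' @export
binom_pmf <- function(n, v, p) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("n must be a single non-negative integer", call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  ifelse(v < 0 | v > n, 0, stats::dbinom(pmax(pmin(v, n), 0), n, p))
}

#' Binomial upper tail P(X >= s)
#'
#' `binom_sf(n, s, p)` is \eqn{\sum_{v=\max(s,0)}^{n} \binom{n}{v} p^v
#' (1-p)^{n-v}}: exactly 1 when `s <= 0` and exactly 0 when `s > n`.
#'
#' @inheritParams binom_pmf
#' @param s tail start (any integer, vectorised).
#' @return Probability (vectorised over `s`).
#' @export
binom_sf <- function(n, s, p) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("n must be a single non-negative integer", call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  ifelse(s <= 0, 1,
         ifelse(s > n, 0,
                stats::pbinom(pmax(s, 1) - 1, n, p, lower.tail = FALSE)))
}

#' Exact rejection probability, type I error and power
#'
#' The exact probability that the design rejects \eqn{H_0} when the true
#' response probability is `p`:
#' \deqn{P(\mathrm{reject} \mid p) = H(n_1, u_1, p) +
#'   \sum_{x=l_1+1}^{u_1-1} h(n_1, x, p)\, H(n_2-n_1, u_2-x, p),}
#' where \eqn{h} and \eqn{H} are [binom_pmf()] and [binom_sf()]. Evaluated at
#' `p0` this is the type I error; at `p1` it is the power. The rejection
#' probability is non-decreasing in `p`, so controlling the error at `p0`
#' controls it on all of `p <= p0`.
#'
#' @param d a [two_stage_design()].
#' @param p true response probability (vectorised).
#' @return Probability of rejecting the null (vectorised over `p`).
#' @export
rejection_prob <- function(d, p) {
  d <- as_design(d)
  cont <- cont_region(d)
  vapply(p, function(pp) {
    binom_sf(d$n1, d$u1, pp) +
      sum(binom_pmf(d$n1, cont, pp) * binom_sf(d$n2 - d$n1, d$u2 - cont, pp))
  }, numeric(1))
}

#' @rdname rejection_prob
#' @param p0 null response probability.
#' @export
type1_error <- function(d, p0) rejection_prob(d, p0)

#' @rdname rejection_prob
#' @param p1 alternative response probability.
#' @export
trial_power <- function(d, p1) rejection_prob(d, p1)

## P(continue to stage 2 | p)
continuation_prob <- function(d, p) {
  cont <- cont_region(d)
  vapply(p, function(pp) sum(binom_pmf(d$n1, cont, pp)), numeric(1))
}

#' Expected sample size
#'
#' \eqn{E[N \mid p] = n_1 + (n_2 - n_1) P(l_1 + 1 \le S_1 \le u_1 - 1 \mid p)},
#' always between `n1` and `n2`.
#'
#' @inheritParams rejection_prob
#' @return Expected number of patients (vectorised over `p`).
#' @export
ess <- function(d, p) {
  d <- as_design(d)
  d$n1 + (d$n2 - d$n1) * continuation_prob(d, p)
}

#' Enumerate feasible two-stage designs
#'
#' Scans all integer tuples `(n1, l1, u1, n2, u2)` inside the given bounds
#' and keeps those whose exact type I error at `p0` is at most `alpha` and
#' whose exact power at `p1` is at least `1 - beta`, restricted to the
#' requested family (`"shuster"`: `u1 <= n1`; `"simon"`: `u1 = n1 + 1`).
#' Rows are ordered lexicographically on `(n2, n1, l1, u1, u2)`. Designs
#' differing only in `u2` are distinct rows: they share all estimation
#' properties but not their error rates.
#'
#' @param p0,p1 null and target response probabilities, `0 < p0 < p1 < 1`.
#' @param alpha maximum type I error.
#' @param beta maximum type II error (power at `p1` is at least `1 - beta`).
#' @param family `"shuster"` or `"simon"`.
#' @param n1_min,n1_max,n2_max search bounds; `n1` ranges over
#'   `n1_min .. min(n1_max, n2 - 1)` and `n2` up to `n2_max`.
#' @return A data frame with columns `n1, l1, u1, n2, u2, alpha, power,
#'   ess_p0` (one row per feasible design), with the constraints attached as
#'   attributes.
#' @examples
#' fd <- feasible_designs(0.2, 0.4, alpha = 0.1, beta = 0.2,
#'                        family = "shuster", n2_max = 20)
#' head(fd)
#' @export
feasible_designs <- function(p0, p1, alpha, beta,
                             family = c("shuster", "simon"),
                             n1_min = 5L, n1_max = NULL, n2_max = 60L) {
  family <- match.arg(family)
  stopifnot(p0 > 0, p0 < p1, p1 < 1, alpha > 0, alpha < 1, beta > 0, beta < 1)
  n1_min <- max(1L, as.integer(n1_min))
  n2_max <- as.integer(n2_max)
  if (is.null(n1_max)) n1_max <- n2_max - 1L
  if (n2_max < n1_min + 1L) stop("n2_max must exceed n1_min", call. = FALSE)

  rows <- vector("list", 256L); nr <- 0L
  for (n2 in seq.int(n1_min + 1L, n2_max)) {
    for (n1 in seq.int(n1_min, min(n1_max, n2 - 1L))) {
      m <- n2 - n1
      u2s <- 0:(n2 + 1L)
      h0 <- stats::dbinom(0:n1, n1, p0)
      h1 <- stats::dbinom(0:n1, n1, p1)
      ## sf2[s + n1 + 1] = P(Bin(m, p) >= s) for s = -n1 .. n2+1
      svals <- seq.int(-n1, n2 + 1L)
      sf0 <- binom_sf(m, svals, p0)
      sf1 <- binom_sf(m, svals, p1)
      ## Hm[x+1, j] = P(Bin(m,p) >= u2s[j] - x), x = 0..n1
      idx <- outer(-(0:n1), u2s, `+`) + n1 + 1L
      C0 <- apply(h0 * matrix(sf0[idx], n1 + 1L), 2L, cumsum)
      C1 <- apply(h1 * matrix(sf1[idx], n1 + 1L), 2L, cumsum)
      C0 <- rbind(0, C0); C1 <- rbind(0, C1)  # row k+2 = cumulative through x = k
      u1s <- if (family == "simon") n1 + 1L else seq.int(1L, n1)
      for (u1 in u1s) {
        su0 <- binom_sf(n1, u1, p0); su1 <- binom_sf(n1, u1, p1)
        l1s <- seq.int(-1L, min(u1 - 2L, n1 - 1L))
        ## alpha(l1, u2) = su0 + C0[u1, ] - C0[l1 + 2, ]
        a <- su0 + matrix(C0[u1 + 1L, ], length(l1s), length(u2s), byrow = TRUE) -
          C0[l1s + 2L, , drop = FALSE]
        pw <- su1 + matrix(C1[u1 + 1L, ], length(l1s), length(u2s), byrow = TRUE) -
          C1[l1s + 2L, , drop = FALSE]
        ok <- which(a <= alpha & pw >= 1 - beta, arr.ind = TRUE)
        if (nrow(ok)) {
          nr <- nr + 1L
          if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
          rows[[nr]] <- data.frame(
            n1 = n1, l1 = l1s[ok[, 1L]], u1 = u1, n2 = n2, u2 = u2s[ok[, 2L]],
            alpha = a[ok], power = pw[ok])
        }
      }
    }
  }
  if (nr == 0L) {
    warning("no feasible design within the given bounds", call. = FALSE)
    out <- data.frame(n1 = integer(), l1 = integer(), u1 = integer(),
                      n2 = integer(), u2 = integer(), alpha = numeric(),
                      power = numeric(), ess_p0 = numeric())
  } else {
    out <- do.call(rbind, rows[seq_len(nr)])
    out <- out[order(out$n2, out$n1, out$l1, out$u1, out$u2), , drop = FALSE]
    rownames(out) <- NULL
    ## ESS at p0 depends only on (n1, l1, u1, n2)
    key <- paste(out$n1, out$l1, out$u1, out$n2)
    uk <- !duplicated(key)
    essv <- vapply(which(uk), function(i)
      ess(two_stage_design(out$n1[i], out$l1[i], out$u1[i], out$n2[i],
                           out$u2[i]), p0), numeric(1))
    out$ess_p0 <- essv[match(key, key[uk])]
  }
  attr(out, "constraints") <- list(p0 = p0, p1 = p1, alpha = alpha,
                                   beta = beta, family = family,
                                   n1_min = n1_min, n1_max = n1_max,
                                   n2_max = n2_max)
  out
}

## row i of a feasible_designs frame as a design object
design_from_row <- function(fd, i) {
  two_stage_design(fd$n1[i], fd$l1[i], fd$u1[i], fd$n2[i], fd$u2[i])
}
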