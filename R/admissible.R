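#' Min-max rescaling of a criterion over the feasible set
#'
#' Maps criterion values onto `[0, 1]` via `(x - min) / (max - min)`, with
#' min and max taken over all feasible pairings. For `kind = "abs_bias"`
#' the minimum is forced to 0: a uniformly unbiased estimator (UMVUE, or
#' UMVCUE in conditional scenarios) is always in the competing set, so zero
#' is attainable. A degenerate criterion (max = min) rescales to all zeros.
#'
#' @param values numeric criterion values over the feasible pairings.
#' @param kind `"ess"`, `"abs_bias"` or `"mse"`.
#' @return Rescaled values in `[0, 1]`.
#' @export
rescale_criterion <- function(values, kind = c("ess", "abs_bias", "mse")) {
  kind <- match.arg(kind)
  if (!length(values)) stop("empty feasible set", call. = FALSE)
  lo <- if (kind == "abs_bias") 0 else min(values)
  hi <- max(values)
  if (hi == lo) return(rep(0, length(values)))
  (values - lo) / (hi - lo)
}

## simplex grid {(w1, w2, 1 - w1 - w2) : wi = k * step >= 0}
weight_grid <- function(step) {
  k <- 1 / step
  if (abs(k - round(k)) > 1e-9)
    stop("grid_step must divide 1 evenly", call. = FALSE)
  k <- as.integer(round(k))
  g <- expand.grid(i = 0:k, j = 0:k)
  g <- g[g$i + g$j <= k, ]
  w <- cbind(w_bias = g$i / k, w_mse = g$j / k, w_ess = (k - g$i - g$j) / k)
  w[order(w[, 1], w[, 2]), , drop = FALSE]
}

## criteria for one estimation class (u2 does not enter): ESS plus
## (abs_bias, mse) per estimator, each estimator's value vector computed once
class_criteria <- function(d, scenario) {
  ess_v <- if (length(scenario$ess_eval) == 2L) {
    averaged_criterion(d, "ess", prior = scenario$ess_eval)
  } else ess(d, scenario$ess_eval)
  crit <- t(vapply(scenario$estimators, function(e) {
    ev <- estimator_values(d, e)
    if (length(scenario$perf_eval) == 2L) {
      a <- scenario$perf_eval[1]; b <- scenario$perf_eval[2]
      c(abs_bias = avg_abs_bias(d, ev, a, b, scenario$conditional),
        mse = avg_mse(d, ev, a, b, scenario$conditional))
    } else {
      p <- scenario$perf_eval
      c(abs_bias = abs(moment_curve(d, ev, p, scenario$conditional, "bias")),
        mse = moment_curve(d, ev, p, scenario$conditional, "mse"))
    }
  }, numeric(2)))
  list(ess = ess_v, crit = crit)
}

avg_mse <- function(d, ev, a, b, conditional) {
  n_nodes <- if (conditional) max(d$n2 + 3L, 81L) else d$n2 + 3L
  r <- gl_rule(n_nodes, a, b)
  sum(r$w * moment_curve(d, ev, r$x, conditional, "mse")) / (b - a)
}

avg_abs_bias <- function(d, ev, a, b, conditional) {
  n_nodes <- if (conditional) max(d$n2 + 3L, 81L) else d$n2 + 3L
  fun <- function(p) moment_curve(d, ev, p, conditional, "bias")
  grid <- seq(a, b, length.out = 401L)
  g <- fun(grid)
  if (max(abs(g)) < 1e-13) return(0)
  cross <- which(g[-1L] * g[-length(g)] < 0)
  cuts <- vapply(cross, function(i)
    stats::uniroot(fun, lower = grid[i], upper = grid[i + 1L],
                   tol = 1e-13)$root, numeric(1))
  br <- c(a, cuts, b)
  total <- 0
  for (k in seq_len(length(br) - 1L)) {
    r <- gl_rule(n_nodes, br[k], br[k + 1L])
    total <- total + abs(sum(r$w * fun(r$x)))
  }
  total / (b - a)
}

#' Search for admissible design-and-estimator pairings
#'
#' Enumerates all feasible designs (correct exact type I error and power
#' within the search bounds), evaluates every (design, estimator) pairing
#' at the scenario's three criteria — expected sample size, absolute bias
#' and MSE — rescales each criterion onto `[0, 1]` over the feasible set,
#' and then, for every weight vector `(w_bias, w_mse, w_ess)` on a simplex
#' grid, finds the pairing(s) minimising the weighted sum of rescaled
#' criteria. The admissible set is the union of minimisers over the grid.
#' Score ties at a weight are broken lexicographically on
#' (`mse*`, `ess*`, `abs_bias*`): at boundary weights a zero component
#' blanks out whole criteria (every unbiased pairing scores 0 when all
#' weight sits on bias), and the tie-break keeps the selection meaningful
#' there. Pairings tied on the full key are all recorded — in particular
#' designs differing only in `u2`, which share all three criteria exactly.
#'
#' @inheritParams feasible_designs
#' @param scenario an [eval_scenario()]; defaults to preset `"1"` for the
#'   Shuster family and preset `"4"` for the Simon family.
#' @param grid_step spacing of the weight grid (must divide 1 evenly);
#'   0.01 gives 5151 weight vectors.
#' @return An object of class `admissible_set`: a list with `pairings`
#'   (data frame: design tuple, `ess`, `estimator`, `abs_bias`, `mse`,
#'   `n_weights`, and the rescaled criteria), `weights` (one row per
#'   (weight vector, minimising pairing)), `feasible` (the feasible-design
#'   table), and the scenario.
#' @examples
#' \donttest{
#' sc <- standard_scenario("1", 0.2, 0.4)
#' adm <- admissible_search(0.2, 0.4, alpha = 0.1, beta = 0.2,
#'                          family = "shuster", scenario = sc, n2_max = 25)
#' adm
#' }
#' @export
admissible_search <- function(p0, p1, alpha, beta,
                              family = c("shuster", "simon"),
                              scenario = NULL, grid_step = 0.01,
                              n1_min = 5L, n1_max = NULL, n2_max = 60L) {
  family <- match.arg(family)
  if (is.null(scenario))
    scenario <- standard_scenario(if (family == "simon") "4" else "1", p0, p1)
  stopifnot(inherits(scenario, "eval_scenario"))
  W <- weight_grid(grid_step)

  fd <- feasible_designs(p0, p1, alpha, beta, family,
                         n1_min = n1_min, n1_max = n1_max, n2_max = n2_max)
  if (!nrow(fd))
    stop("no feasible design satisfies the constraints within the bounds; ",
         "relax alpha/beta or enlarge n2_max", call. = FALSE)

  ## estimation classes: u2 never enters the criteria
  key <- paste(fd$n1, fd$l1, fd$u1, fd$n2)
  uk_idx <- which(!duplicated(key))
  ckey <- key[uk_idx]
  ests <- scenario$estimators
  n_est <- length(ests)

  est_code <- c(mle = 0L, bc_mle = 1L, umvue = 2L, umvcue = 3L,
                c_umvcue = 4L, mue = 5L)
  classes_mat <- as.matrix(fd[uk_idx, c("n1", "l1", "u1", "n2")])
  storage.mode(classes_mat) <- "integer"
  glr <- gl_rule(max(n2_max + 3L, 81L), 0, 1)
  crit_mat <- criteria_classes_cpp(classes_mat, est_code[ests],
                                   scenario$ess_eval, scenario$perf_eval,
                                   scenario$conditional, glr$x, glr$w)

  ## one row per (class, estimator), class-major
  cl <- rep(seq_along(uk_idx), each = n_est)
  est_col <- rep(ests, times = length(uk_idx))
  ab_cols <- 2L * seq_len(n_est)          # columns 2, 4, ...
  ms_cols <- 2L * seq_len(n_est) + 1L     # columns 3, 5, ...
  triples <- cbind(
    abs_bias = as.vector(t(crit_mat[, ab_cols, drop = FALSE])),
    mse = as.vector(t(crit_mat[, ms_cols, drop = FALSE])),
    ess = rep(crit_mat[, 1L], each = n_est))

  M <- cbind(rescale_criterion(triples[, "abs_bias"], "abs_bias"),
             rescale_criterion(triples[, "mse"], "mse"),
             rescale_criterion(triples[, "ess"], "ess"))

  sel <- weight_argmin_cpp(M, W, 0)
  n_weights <- tabulate(unlist(sel), nbins = nrow(M))
  adm_rows <- which(n_weights > 0L)

  ## expand winning (class, estimator) rows to every feasible u2
  rows_of_class <- split(seq_len(nrow(fd)), match(key, ckey))
  pair_list <- lapply(adm_rows, function(r) {
    rows <- rows_of_class[[cl[r]]]
    data.frame(fd[rows, c("n1", "l1", "u1", "n2", "u2", "alpha", "power")],
               ess = triples[r, "ess"], estimator = est_col[r],
               abs_bias = triples[r, "abs_bias"], mse = triples[r, "mse"],
               abs_bias_rescaled = M[r, 1], mse_rescaled = M[r, 2],
               ess_rescaled = M[r, 3], n_weights = n_weights[r],
               row.names = NULL)
  })
  pairings <- do.call(rbind, pair_list)
  pairings <- pairings[order(pairings$ess, pairings$n2, pairings$n1,
                             pairings$l1, pairings$u1, pairings$u2,
                             pairings$estimator), , drop = FALSE]
  rownames(pairings) <- NULL

  wmap <- data.frame(
    w_bias = rep(W[, 1], lengths(sel)),
    w_mse = rep(W[, 2], lengths(sel)),
    w_ess = rep(W[, 3], lengths(sel)),
    n1 = fd$n1[uk_idx][cl[unlist(sel)]],
    l1 = fd$l1[uk_idx][cl[unlist(sel)]],
    u1 = fd$u1[uk_idx][cl[unlist(sel)]],
    n2 = fd$n2[uk_idx][cl[unlist(sel)]],
    estimator = est_col[unlist(sel)])

  structure(list(pairings = pairings, weights = wmap, feasible = fd,
                 scenario = scenario, grid_step = grid_step,
                 constraints = attr(fd, "constraints")),
            class = "admissible_set")
}

#' @export
print.admissible_set <- function(x, digits = 3, ...) {
  cc <- x$constraints
  cat(sprintf(
    "Admissible (design, estimator) pairings: p0=%.3g, p1=%.3g, alpha<=%.3g, power>=%.3g, %s family\n",
    cc$p0, cc$p1, cc$alpha, 1 - cc$beta, cc$family))
  print(x$scenario)
  cat(sprintf("%d feasible designs (%d estimation classes); weight grid step %.3g\n",
              nrow(x$feasible),
              sum(!duplicated(paste(x$feasible$n1, x$feasible$l1,
                                    x$feasible$u1, x$feasible$n2))),
              x$grid_step))
  tab <- x$pairings[, c("n1", "l1", "u1", "n2", "u2", "ess", "estimator",
                        "abs_bias", "mse", "n_weights")]
  tab$ess <- round(tab$ess, 1)
  tab$abs_bias <- signif(tab$abs_bias, digits)
  tab$mse <- signif(tab$mse, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
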