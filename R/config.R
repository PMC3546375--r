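#' Load and validate a run configuration
#'
#' Reads a YAML configuration driving the command-line interface. The
#' recognised keys are: `p0`, `p1`, `alpha`, `beta`, `family` (required);
#' `n1_min`, `n1_max`, `n2_max`, `grid_step`, `scenario` (a preset `"1"`,
#' `"2"`, `"4"` or a mapping with `ess_eval`, `perf_eval`, `conditional`,
#' `estimators`), `design` (mapping with `n1, l1, u1, n2, u2`), `seed`,
#' `out_dir`. Unknown keys are rejected so that misspellings fail loudly.
#'
#' @param path path to the YAML file.
#' @return A validated list of class `run_config` with `constraints`,
#'   `scenario`, `design` (or `NULL`), `grid_step`, `seed`, `out_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("p0", "p1", "alpha", "beta", "family", "n1_min", "n1_max",
             "n2_max", "grid_step", "scenario", "design", "seed", "out_dir")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (k in c("p0", "p1", "alpha", "beta", "family"))
    if (is.null(raw[[k]])) stop("config key missing: ", k, call. = FALSE)
  num <- function(k, lo, hi) {
    v <- raw[[k]]
    if (!is.numeric(v) || length(v) != 1L || v <= lo || v >= hi)
      stop(sprintf("config key '%s' must be a number in (%g, %g)", k, lo, hi),
           call. = FALSE)
    v
  }
  p0 <- num("p0", 0, 1); p1 <- num("p1", 0, 1)
  if (p0 >= p1) stop("config requires p0 < p1", call. = FALSE)
  alpha <- num("alpha", 0, 1); beta <- num("beta", 0, 1)
  family <- match.arg(raw$family, c("shuster", "simon"))
  n1_min <- if (is.null(raw$n1_min)) 5L else as.integer(raw$n1_min)
  n2_max <- if (is.null(raw$n2_max)) 60L else as.integer(raw$n2_max)
  n1_max <- if (is.null(raw$n1_max)) NULL else as.integer(raw$n1_max)
  grid_step <- if (is.null(raw$grid_step)) 0.01 else raw$grid_step

  scenario <- raw$scenario
  if (is.null(scenario)) {
    scenario <- standard_scenario(if (family == "simon") "4" else "1", p0, p1)
  } else if (is.character(scenario) || is.numeric(scenario)) {
    scenario <- standard_scenario(as.character(scenario), p0, p1)
  } else if (is.list(scenario)) {
    args <- scenario
    args$ess_eval <- unlist(args$ess_eval)
    args$perf_eval <- unlist(args$perf_eval)
    if (!is.null(args$estimators)) args$estimators <- unlist(args$estimators)
    scenario <- do.call(eval_scenario, args)
  } else stop("config key 'scenario' is malformed", call. = FALSE)

  design <- raw$design
  if (!is.null(design)) {
    if (!is.list(design) || !all(c("n1", "l1", "n2", "u2") %in% names(design)))
      stop("config key 'design' needs n1, l1, n2, u2 (and optionally u1)",
           call. = FALSE)
    design <- two_stage_design(design$n1, design$l1,
                               if (is.null(design$u1)) design$n1 + 1L
                               else design$u1,
                               design$n2, design$u2)
  }

  structure(list(
    constraints = list(p0 = p0, p1 = p1, alpha = alpha, beta = beta,
                       family = family, n1_min = n1_min, n1_max = n1_max,
                       n2_max = n2_max),
    scenario = scenario, design = design, grid_step = grid_step,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir),
    class = "run_config")
}

#' Write admissible pairings (or any pairing table) as CSV
#'
#' Writes the pairing rows in a fixed column order
#' (`n1, l1, u1, n2, u2, ess, estimator, abs_bias, mse, n_weights`) at full
#' float precision; a companion `*_report.csv` with values rounded to 3
#' significant figures is written alongside when `report = TRUE`.
#'
#' @param pairings data frame of pairings (e.g. the `pairings` element of
#'   an [admissible_search()] result) or an `admissible_set`.
#' @param path output CSV path.
#' @param report also write the 3-significant-figure report variant?
#' @return `path`, invisibly.
#' @export
write_pairings_csv <- function(pairings, path, report = FALSE) {
  if (inherits(pairings, "admissible_set")) pairings <- pairings$pairings
  if (!is.data.frame(pairings) || !nrow(pairings))
    stop("pairings must be a non-empty data frame", call. = FALSE)
  cols <- c("n1", "l1", "u1", "n2", "u2", "ess", "estimator", "abs_bias",
            "mse")
  if ("n_weights" %in% names(pairings)) cols <- c(cols, "n_weights")
  missing_cols <- setdiff(cols, names(pairings))
  if (length(missing_cols))
    stop("pairings table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- pairings[, cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (report) {
    rep_out <- out
    for (k in c("ess", "abs_bias", "mse"))
      rep_out[[k]] <- signif(rep_out[[k]], 3)
    utils::write.csv(rep_out, sub("\\.csv$", "_report.csv", path),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Feasible-design table as CSV
#'
#' Columns `n1, l1, u1, n2, u2, alpha, power, ess_p0` at full precision.
#'
#' @param fd a [feasible_designs()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feasible_csv <- function(fd, path) {
  cols <- c("n1", "l1", "u1", "n2", "u2", "alpha", "power", "ess_p0")
  utils::write.csv(fd[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
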