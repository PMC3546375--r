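test_that("exact bias and MSE agree with the path-enumeration oracle", {
  for (d in tiny_designs()[c(1, 2, 4)]) {
    o <- path_oracle(d, 0.3)
    for (e in c("mle", "umvue", "mue")) {
      ev <- estimate_p(d, 0:d$n2, e)
      est_of_path <- ev[o$t + 1]
      expect_equal(estimator_bias(d, e, 0.3),
                   sum(est_of_path * o$prob) - 0.3, tolerance = 1e-12)
      expect_equal(estimator_mse(d, e, 0.3),
                   sum((est_of_path - 0.3)^2 * o$prob), tolerance = 1e-12)
      ## conditional versions against the stage-2 paths
      wc <- o$prob[o$cont] / sum(o$prob[o$cont])
      expect_equal(estimator_bias(d, e, 0.3, conditional = TRUE),
                   sum(est_of_path[o$cont] * wc) - 0.3, tolerance = 1e-12)
      expect_equal(estimator_mse(d, e, 0.3, conditional = TRUE),
                   sum((est_of_path[o$cont] - 0.3)^2 * wc), tolerance = 1e-12)
    }
  }
})

test_that("unbiasedness claims hold pointwise; MSE dominates squared bias", {
  d <- two_stage_design(11, 2, 5, 31, 10)
  simon <- two_stage_design(13, 3, n2 = 34, u2 = 9)
  for (p in seq(0.05, 0.95, by = 0.1)) {
    expect_lt(abs(estimator_bias(d, "umvue", p)), 1e-10)
    expect_lt(abs(estimator_bias(simon, "umvcue", p, conditional = TRUE)),
              1e-10)
    for (e in c("mle", "bc_mle", "c_umvcue", "mue")) {
      b <- estimator_bias(d, e, p)
      m <- estimator_mse(d, e, p)
      expect_gte(m, b^2 - 1e-14)
    }
  }
  expect_error(estimator_bias(d, "umvcue", 0.3), "c_umvcue")
})

test_that("conditional performance is invariant to the stage-2 bound u2", {
  base <- two_stage_design(10, 2, 11, 20, 8)
  alt <- two_stage_design(10, 2, 11, 20, 14)
  for (e in c("mle", "umvcue", "mue")) {
    expect_equal(estimator_bias(base, e, 0.4, conditional = TRUE),
                 estimator_bias(alt, e, 0.4, conditional = TRUE),
                 tolerance = 1e-13)
    expect_equal(estimator_mse(base, e, 0.4, conditional = TRUE),
                 estimator_mse(alt, e, 0.4, conditional = TRUE),
                 tolerance = 1e-13)
  }
})

test_that("uniform-prior averages: quadrature is self-consistent and exact", {
  d <- two_stage_design(15, 3, 6, 27, 9)
  ## Gauss-Legendre vs a dense Simpson rule (10^4 + 1 points)
  simpson <- function(f, a, b, n = 10000L) {
    x <- seq(a, b, length.out = n + 1L)
    w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
    sum(w * vapply(x, f, numeric(1))) * (b - a) / (3 * n)
  }
  glv <- averaged_criterion(d, "ess", prior = c(0.2, 0.4))
  expect_lt(abs(glv - simpson(function(p) ess(d, p), 0.2, 0.4) / 0.2), 1e-9)
  ev <- estimate_p(d, 0:d$n2, "mle")
  gm <- averaged_criterion(d, "mse", "mle", prior = c(0.2, 0.4))
  expect_lt(abs(gm - simpson(function(p) estimator_mse(d, "mle", p),
                             0.2, 0.4) / 0.2), 1e-9)
  ## pointwise-zero bias integrates to exactly zero
  expect_identical(averaged_criterion(d, "abs_bias", "umvue",
                                      prior = c(0.2, 0.4)), 0)
  expect_equal(averaged_criterion(d, "bias", "umvue", prior = c(0.2, 0.4)),
               0, tolerance = 1e-12)
  ## average |bias| >= |average bias| always
  ab <- averaged_criterion(d, "abs_bias", "bc_mle", prior = c(0.2, 0.4))
  sb <- averaged_criterion(d, "bias", "bc_mle", prior = c(0.2, 0.4))
  expect_gte(ab, abs(sb) - 1e-12)
})

test_that("scenario presets assemble the advertised profiles", {
  sc1 <- standard_scenario("1", 0.2, 0.4)
  expect_false(sc1$conditional)
  expect_true("c_umvcue" %in% sc1$estimators)
  sc2 <- standard_scenario("2", 0.2, 0.4)
  expect_identical(sc2$perf_eval, c(0.2, 0.4))
  sc4 <- standard_scenario("4", 0.2, 0.4)
  expect_true(sc4$conditional)
  expect_true("umvcue" %in% sc4$estimators)
  expect_error(eval_scenario(0.2, 0.4, conditional = FALSE,
                             estimators = c("mle", "umvcue")), "conditional")

  d <- two_stage_design(11, 2, 5, 31, 10)
  pr <- performance_profile(d, "bc_mle", sc1)
  expect_equal(pr$ess, ess(d, 0.2), tolerance = 1e-13)
  expect_equal(pr$abs_bias, abs(estimator_bias(d, "bc_mle", 0.4)),
               tolerance = 1e-13)
  expect_equal(pr$mse, estimator_mse(d, "bc_mle", 0.4), tolerance = 1e-13)
  expect_error(performance_profile(d, "umvcue", sc1), "conditional")
})

test_that("Monte-Carlo estimates agree with the exact formulas", {
  d <- two_stage_design(19, 4, 14, 54, 16)
  n <- 40000L
  sim <- simulate_trials(d, 0.4, n, seed = 424242)
  ## ESS within 4 standard errors
  se_n <- stats::sd(sim$n_used) / sqrt(n)
  expect_lt(abs(mean(sim$n_used) - ess(d, 0.4)), 4 * se_n)
  ## rejection rate within 4 standard errors
  pw <- trial_power(d, 0.4)
  expect_lt(abs(mean(sim$reject) - pw), 4 * sqrt(pw * (1 - pw) / n))
  ## mean and MSE of the UMVUE within 4 standard errors
  ev <- estimate_p(d, 0:d$n2, "umvue")
  est <- ev[sim$t + 1]
  expect_lt(abs(mean(est) - (estimator_bias(d, "umvue", 0.4) + 0.4)),
            4 * stats::sd(est) / sqrt(n))
  sq <- (est - 0.4)^2
  expect_lt(abs(mean(sq) - estimator_mse(d, "umvue", 0.4)),
            4 * stats::sd(sq) / sqrt(n))
})
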