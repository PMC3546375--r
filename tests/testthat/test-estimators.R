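worked <- two_stage_design(19, 4, 14, 54, 16)
p_grid <- seq(0.05, 0.95, by = 0.05)

test_that("the MLE is the observed proportion at termination", {
  expect_equal(estimate_p(worked, 4, "mle"), 4 / 19)
  expect_equal(estimate_p(worked, 49, "mle"), 14 / 19)
  expect_equal(estimate_p(worked, 20, "mle"), 20 / 54)
})

test_that("UMVUE: stop-region identity, exact unbiasedness, Rao-Blackwell", {
  ## equals the MLE on both stop regions
  expect_equal(estimate_p(worked, 0:4, "umvue"), (0:4) / 19)
  expect_equal(estimate_p(worked, 49:54, "umvue"), (14:19) / 19)
  ## exact unbiasedness over the whole sample space, every p on a grid
  ev <- estimate_p(worked, 0:54, "umvue")
  for (p in p_grid)
    expect_lt(abs(sum(ev * t_pmf(worked, p)) - p), 1e-10)
  ## continuation values equal E[S1/n1 | T = t] from the path oracle
  for (d in tiny_designs()[c(1, 3, 4)]) {
    for (t in t_regions(d)$continuation) {
      orc <- oracle_cond_exp(d, 0.45, t, function(s1, s2) s1 / d$n1)
      if (!is.nan(orc))
        expect_equal(estimate_p(d, t, "umvue"), orc, tolerance = 1e-12)
    }
  }
})

test_that("UMVCUE: conditional unbiasedness, stage-2 Rao-Blackwell, domain", {
  simon <- two_stage_design(13, 3, n2 = 34, u2 = 9)
  cont <- t_regions(simon)$continuation
  ev <- estimate_p(simon, cont, "umvcue")
  for (p in p_grid)
    expect_lt(abs(sum(ev * t_pmf(simon, p, conditional = TRUE)) - p), 1e-10)
  expect_error(estimate_p(simon, 0, "umvcue"), "continuation")
  m <- simon$n2 - simon$n1
  for (d in tiny_designs()[c(2, 4, 6)]) {  # includes the n2 - n1 = 1 case
    md <- d$n2 - d$n1
    for (t in t_regions(d)$continuation) {
      orc <- oracle_cond_exp(d, 0.45, t, function(s1, s2) (s2 - s1) / md)
      if (!is.nan(orc))
        expect_equal(estimate_p(d, t, "umvcue"), orc, tolerance = 1e-12)
    }
  }
})

test_that("the composite c-UMVCUE delegates by region", {
  expect_equal(estimate_p(worked, 2, "c_umvcue"), 2 / 19)
  expect_equal(estimate_p(worked, 50, "c_umvcue"), 15 / 19)
  expect_equal(estimate_p(worked, 22, "c_umvcue"),
               estimate_p(worked, 22, "umvcue"))
})

test_that("BC-MLE solves Whitehead's relation and degenerates correctly", {
  ## design with no stopping: the MLE is unbiased, so no correction
  flat <- two_stage_design(6, -1, 7, 12, 5)
  expect_equal(estimate_p(flat, 0:12, "bc_mle"),
               estimate_p(flat, 0:12, "mle"), tolerance = 1e-9)
  ## at the returned q*, the exact expectation of the MLE over the T pmf
  ## reproduces the observed MLE (direct dual-route check)
  mv <- estimate_p(worked, 0:54, "mle")
  for (t in c(2, 5, 20, 35, 49, 52)) {
    qstar <- estimate_p(worked, t, "bc_mle")
    expect_lt(abs(sum(mv * t_pmf(worked, qstar)) - mv[t + 1]), 1e-8)
  }
  expect_true(all(estimate_p(worked, 0:54, "bc_mle") >= 0))
  expect_true(all(estimate_p(worked, 0:54, "bc_mle") <= 1))
})

test_that("MUE averages the two half-roots with the edge conventions", {
  cmp <- mue_components(worked, 20)
  expect_lt(abs(fm_pvalue(worked, 20, cmp$p_plus) - 0.5), 1e-9)
  expect_lt(abs(fm_pvalue(worked, 21, cmp$p_minus) - 0.5), 1e-9)
  expect_equal(cmp$value, (cmp$p_plus + cmp$p_minus) / 2)
  expect_equal(estimate_p(worked, 20, "mue"), cmp$value, tolerance = 1e-10)
  c0 <- mue_components(worked, 0)
  expect_identical(c0$p_plus, 0)          # K(0, .) = 1 never crosses 0.5
  cn <- mue_components(worked, worked$n2)
  expect_identical(cn$p_minus, 1)         # K(n2 + 1, .) = 0 never crosses
  ## K is strictly increasing in p between its 0 and 1 plateaus, so the
  ## half-roots are unique and increase with t
  r <- vapply(1:worked$n2, function(t) mue_components(worked, t)$p_plus,
              numeric(1))
  expect_true(all(diff(r) >= -1e-12))
})

test_that("MUE and UMVUE are monotone in t; all estimators stay in [0, 1]", {
  for (d in list(worked, two_stage_design(13, 3, n2 = 34, u2 = 9))) {
    ts <- 0:d$n2
    expect_true(all(diff(estimate_p(d, ts, "mue")) >= -1e-12))
    expect_true(all(diff(estimate_p(d, ts, "umvue")) >= -1e-12))
    for (e in c("mle", "bc_mle", "umvue", "c_umvcue", "mue")) {
      v <- estimate_p(d, ts, e)
      expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
    }
  }
})

test_that("confidence bounds invert K and achieve exact coverage", {
  d <- two_stage_design(11, 2, 5, 31, 10)
  expect_identical(confidence_bounds(d, 0, 0.1)[["lower"]], 0)
  expect_identical(confidence_bounds(d, d$n2, 0.1)[["upper"]], 1)
  cb <- confidence_bounds(d, 12, 0.1)
  expect_lt(abs(fm_pvalue(d, 12, cb[["lower"]]) - 0.05), 1e-9)
  expect_lt(abs(fm_pvalue(d, 13, cb[["upper"]]) - 0.95), 1e-9)
  expect_lt(cb[["lower"]], cb[["upper"]])
  ## exact coverage: sum the T pmf over outcomes whose interval covers p
  bounds <- t(vapply(0:d$n2, function(t) confidence_bounds(d, t, 0.1),
                     numeric(2)))
  for (p in seq(0.1, 0.9, by = 0.2)) {
    pm <- t_pmf(d, p)
    cover <- sum(pm[bounds[, 1] <= p & p <= bounds[, 2]])
    expect_gte(cover, 0.9 - 1e-10)
  }
})

test_that("the estimation fit object carries estimates, p-value and CI", {
  fit <- twostage_estimate(worked, stage = 2, responses = 20, p0 = 0.2)
  expect_s3_class(fit, "twostage_estimate")
  expect_equal(fit$t, 20L)
  expect_equal(unname(coef(fit)["mle"]), 20 / 54)
  expect_equal(fit$p_value, fm_pvalue(worked, 20, 0.2))
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), unname(confidence_bounds(worked, 20, 0.05)))
  ## stage-1 stop drops the UMVCUE with a message
  expect_message(fit1 <- twostage_estimate(worked, stage = 1, responses = 2),
                 "UMVCUE")
  expect_false("umvcue" %in% names(coef(fit1)))
  ## t and (stage, responses) entry points agree
  fit2 <- twostage_estimate(worked, t = 20)
  expect_equal(coef(fit2), coef(fit))
})
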