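test_that("binomial primitives honour the out-of-support contracts", {
  # closed form evaluated from first principles (no dbinom)
  expect_equal(binom_pmf(11, 3, 0.2),
               (11 * 10 * 9 / 6) * 0.2^3 * 0.8^8, tolerance = 1e-14)
  expect_identical(binom_pmf(11, -1, 0.2), 0)
  expect_identical(binom_pmf(11, 12, 0.2), 0)
  expect_equal(binom_pmf(1, 0, 0.5), 0.5)
  expect_equal(binom_sf(7, 0, 0.3), 1)
  expect_identical(binom_sf(7, 8, 0.3), 0)
  expect_equal(binom_sf(2, 1, 0.5), 0.75)
  # vectorised over the count argument
  expect_equal(binom_sf(5, -2:7, 0.4)[1:2], c(1, 1))
  expect_error(binom_pmf(-1, 0, 0.5), "non-negative")
  expect_error(binom_pmf(5, 2, 1.2), "\\[0, 1\\]")
})

test_that("design constructor enforces the stopping-rule invariants", {
  d <- two_stage_design(19, 4, 14, 54, 16)
  expect_s3_class(d, "two_stage_design")
  expect_false(is_simon(d))
  expect_true(is_simon(two_stage_design(13, 3, n2 = 34, u2 = 9)))
  expect_error(two_stage_design(5, 2, 3, 10, 4), "continuation")
  expect_error(two_stage_design(5, -2, 3, 10, 4), "l1")
  expect_error(two_stage_design(5, 1, 7, 10, 4), "u1")
  expect_error(two_stage_design(5, 1, 3, 5, 4), "n1 < n2")
  expect_error(two_stage_design(5, 1, 3, 10, 12), "u2")
  # l1 = -1 (no futility stop) is a valid design
  expect_silent(two_stage_design(5, -1, 3, 10, 4))
})

test_that("exact operating characteristics match the path-enumeration oracle", {
  for (d in tiny_designs()) {
    for (p in c(0.1, 0.35, 0.5, 0.8)) {
      expect_equal(rejection_prob(d, p), oracle_reject(d, p),
                   tolerance = 1e-12)
      expect_equal(ess(d, p), oracle_ess(d, p), tolerance = 1e-12)
    }
  }
})

test_that("rejection probability is monotone in p and ESS stays in [n1, n2]", {
  designs <- list(two_stage_design(19, 4, 14, 54, 16),
                  two_stage_design(11, 2, 5, 31, 10),
                  two_stage_design(13, 3, n2 = 34, u2 = 9))
  ps <- seq(0.02, 0.98, by = 0.04)
  for (d in designs) {
    r <- rejection_prob(d, ps)
    expect_true(all(r >= 0 & r <= 1))
    expect_true(all(diff(r) >= -1e-12))
    e <- ess(d, ps)
    expect_true(all(e >= d$n1 - 1e-9 & e <= d$n2 + 1e-9))
  }
  # degenerate corners
  d <- two_stage_design(5, 1, 6, 10, 11)   # rejection impossible
  expect_equal(rejection_prob(d, 0.5), 0)
  d <- two_stage_design(5, -1, 6, 10, 0)   # always reaches stage 2, u2 = 0
  expect_equal(trial_power(d, 0.3), 1)
  d <- two_stage_design(5, 1, 4, 10, 6)
  expect_equal(ess(d, 0), d$n1)            # certain futility stop at p = 0
})

test_that("feasible enumeration agrees with a brute-force tuple scan", {
  p0 <- 0.15; p1 <- 0.55; alpha <- 0.25; beta <- 0.25
  fd <- feasible_designs(p0, p1, alpha, beta, family = "shuster",
                         n1_min = 1, n2_max = 6)
  ## independent scan over all integer tuples, operating characteristics
  ## from the path oracle
  brute <- list()
  for (n2 in 2:6) for (n1 in 1:(n2 - 1)) for (l1 in -1:(n1 - 1))
    for (u1 in (l1 + 2):(n1 + 1)) for (u2 in 0:(n2 + 1)) {
      if (u1 > n1) next  # shuster family: stage-1 efficacy stop possible
      if (u1 - 1 > n1) next
      d <- two_stage_design(n1, l1, u1, n2, u2)
      if (oracle_reject(d, p0) <= alpha && oracle_reject(d, p1) >= 1 - beta)
        brute[[length(brute) + 1L]] <- c(n1, l1, u1, n2, u2)
    }
  brute <- do.call(rbind, brute)
  got <- as.matrix(fd[, c("n1", "l1", "u1", "n2", "u2")])
  dimnames(got) <- NULL
  expect_equal(nrow(got), nrow(brute))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
  expect_setequal(key(got), key(brute))
  ## deterministic lexicographic order on (n2, n1, l1, u1, u2)
  ord <- order(fd$n2, fd$n1, fd$l1, fd$u1, fd$u2)
  expect_identical(ord, seq_len(nrow(fd)))
  ## impossible constraints yield an empty table with a warning
  expect_warning(
    empty <- feasible_designs(0.2, 0.4, 1e-9, 0.2, "shuster", n2_max = 10),
    "no feasible")
  expect_identical(nrow(empty), 0L)
})

test_that("reported alpha, power and ESS columns are exact", {
  fd <- feasible_designs(0.2, 0.4, 0.1, 0.2, family = "shuster",
                         n1_min = 10, n1_max = 12, n2_max = 31)
  i <- which(fd$n1 == 11 & fd$l1 == 2 & fd$u1 == 5 & fd$n2 == 31 &
               fd$u2 == 10)
  expect_length(i, 1L)
  d <- two_stage_design(11, 2, 5, 31, 10)
  expect_equal(fd$alpha[i], type1_error(d, 0.2), tolerance = 1e-14)
  expect_equal(fd$power[i], trial_power(d, 0.4), tolerance = 1e-14)
  expect_equal(fd$ess_p0[i], ess(d, 0.2), tolerance = 1e-14)
})
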