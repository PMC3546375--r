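# Independent brute-force oracle: enumerate all 2^n2 patient-level outcome
# paths of a small trial, weight each by its Bernoulli probability, and read
# every quantity (rejection, sample size, T statistic, conditional laws)
# straight off the paths. No binomial formulas are used, so this is a fully
# independent check of the closed-form machinery. Only viable for n2 <= ~12.
path_oracle <- function(d, p) {
  n1 <- d$n1; n2 <- d$n2; m <- n2 - n1
  paths <- as.matrix(expand.grid(rep(list(0:1), n2)))
  prob <- apply(paths, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  s1 <- rowSums(paths[, seq_len(n1), drop = FALSE])
  fut <- s1 <= d$l1
  eff <- s1 >= d$u1
  cont <- !fut & !eff
  s2 <- rowSums(paths)
  tt <- ifelse(fut, s1, ifelse(eff, s1 + m, s2))
  data.frame(prob = prob, s1 = s1, s2 = s2, cont = cont, t = tt,
             reject = eff | (cont & s2 >= d$u2),
             n_used = ifelse(cont, n2, n1))
}

oracle_tpmf <- function(d, p) {
  o <- path_oracle(d, p)
  vapply(0:d$n2, function(t) sum(o$prob[o$t == t]), numeric(1))
}

oracle_reject <- function(d, p) {
  o <- path_oracle(d, p)
  sum(o$prob[o$reject])
}

oracle_ess <- function(d, p) {
  o <- path_oracle(d, p)
  sum(o$prob * o$n_used)
}

# E[g(S1, S2) | T = t, reached stage 2] from the path weights
oracle_cond_exp <- function(d, p, t, g) {
  o <- path_oracle(d, p)
  sub <- o[o$cont & o$t == t, ]
  sum(sub$prob * g(sub$s1, sub$s2)) / sum(sub$prob)
}

# small designs used across oracle tests (n2 <= 8 keeps 2^n2 enumerable)
tiny_designs <- function() {
  list(
    two_stage_design(n1 = 2, l1 = 0, u1 = 2, n2 = 4, u2 = 3),
    two_stage_design(n1 = 3, l1 = 0, u1 = 3, n2 = 7, u2 = 4),
    two_stage_design(n1 = 4, l1 = 1, u1 = 4, n2 = 8, u2 = 5),
    two_stage_design(n1 = 3, l1 = 1, n2 = 8, u2 = 5),   # Simon-type
    two_stage_design(n1 = 3, l1 = -1, u1 = 3, n2 = 6, u2 = 4),  # no futility stop
    two_stage_design(n1 = 4, l1 = 1, u1 = 3, n2 = 5, u2 = 4)    # n2 - n1 = 1
  )
}

# printed-precision comparison: agree within one unit in the last printed
# digit (digits = number of significant figures printed), or 0.5% relative
# (rounding ambiguity at 3 significant figures plus solver slop)
expect_printed <- function(computed, printed, digits = 3) {
  tol <- max(10^(floor(log10(abs(printed))) - (digits - 1)),
             0.005 * abs(printed))
  expect_lt(abs(computed - printed), tol + 1e-15)
}
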