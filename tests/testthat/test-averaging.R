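test_that("QEA law: generic machinery equals the conditioned Poisson form", {
  for (s in c(0L, 2L, 21L, 60L)) {
    a <- qea_distribution(params21, s, method = "product_form")
    b <- qea_distribution(params21, s, method = "closed_form")
    expect_lt(distribution_distance(a, b, "total_variation"), 1e-11)
  }
  expect_equal(qea_distribution(params21, 0L)$prob, 1)
  ## s = 2: ratio of the two states from direct arithmetic
  d <- dimer_equilibrium_closed_form(params21[["k1"]], params21[["k2"]])
  q2 <- qea_distribution(params21, 2L, method = "closed_form")
  ratio <- (d[2] / 1) / (d[1]^2 / 2)     # pi(1)/pi(0)
  expect_equal(q2$prob[2] / q2$prob[1], ratio, tolerance = 1e-12)
})

test_that("constrained law: two independent code paths agree everywhere", {
  for (s in c(1L, 7L, 40L, 120L)) {
    a <- constrained_distribution(params21, s, method = "theorem2")
    b <- constrained_distribution(params21, s, method = "closed_form")
    expect_equal(a$prob, b$prob, tolerance = 1e-12)
  }
  expect_equal(constrained_distribution(params21, 1L)$prob, 1)  # single state
})

test_that("constrained law converges to the QEA law as the projected rate vanishes", {
  tvs <- vapply(c(100, 10, 1, 0.1), function(k3) {
    pp <- c(k1 = 1, k2 = 100, k3 = k3, k4 = 30)
    distribution_distance(constrained_distribution(pp, 80L, "closed_form"),
                          qea_distribution(pp, 80L, "closed_form"),
                          "total_variation")
  }, numeric(1))
  expect_true(all(diff(tvs) < 0))
  expect_lt(tvs[4], 1e-3)
})

test_that("effective rates of the reduced slow model", {
  expect_equal(effective_rates(params21, 0L)$lambda4, 0)
  er <- effective_rates(params21, 300L, mode = "qea")
  expect_equal(er$lambda3, params21[["k3"]])
  expect_equal(er$lambda4, params21[["k4"]] * er$E_X1)
  erc <- effective_rates(params21, 300L, mode = "constrained")
  expect_false(isTRUE(all.equal(er$lambda4, erc$lambda4)))
  expect_equal(unname(er$jumps), c(2L, -1L))

  ## linear propensity under a (conditioned) Poisson fast law: the
  ## effective rate is kappa4 times the conditional mean, recovered by
  ## direct summation over the class
  q <- qea_distribution(params21, 50L, method = "closed_form")
  m <- expectation(q, function(X) 50 - 2 * X[, 1])
  expect_equal(effective_rates(params21, 50L, "qea")$lambda4,
               params21[["k4"]] * m, tolerance = 1e-12)
})

test_that("fast-reaction proportion: limiting controls", {
  base <- c(k1 = 1, k2 = 10)
  cls <- state_class(c("S1", "S2"), box = c(30L, 15L))
  ## slow rates near zero: all flux is fast
  fx_hi <- crn_fixture("full_system15",
                       params = c(base, k3 = 1e-9, k4 = 1e-9))
  d_hi <- solve_stationary(build_generator(fx_hi$net, fx_hi$kin, cls))
  expect_equal(fast_reaction_proportion(d_hi, fx_hi$net, fx_hi$kin, fx_hi$fast),
               100, tolerance = 1e-4)
  ## fast rates near zero: none of it is
  fx_lo <- crn_fixture("full_system15",
                       params = c(k1 = 1e-10, k2 = 1e-10, k3 = 5, k4 = 2))
  d_lo <- solve_stationary(build_generator(fx_lo$net, fx_lo$kin, cls))
  expect_lt(fast_reaction_proportion(d_lo, fx_lo$net, fx_lo$kin, fx_lo$fast),
            0.01)
  expect_error(fast_reaction_proportion(d_lo, fx_lo$net, fx_lo$kin, "nope"),
               "unknown reaction labels")
})

test_that("comparison pipeline on a small, well-contained configuration", {
  ## moderate rates so the full law fits a small box
  pp <- c(k1 = 1, k2 = 10, k3 = 20, k4 = 5)
  cmp <- compare_averaging(pp, s = 20L, box = c(60L, 40L))
  expect_lt(cmp$boundary_mass, 1e-8)
  expect_true(is.finite(cmp$rel_l2_qea) && is.finite(cmp$rel_l2_constrained))
  expect_equal(sum(cmp$full_conditional$prob), 1, tolerance = 1e-12)
  expect_equal(sum(cmp$qea$prob), 1, tolerance = 1e-12)
  expect_equal(sum(cmp$constrained$prob), 1, tolerance = 1e-12)
  ## identical inputs give zero error
  expect_equal(distribution_distance(cmp$qea, cmp$qea), 0)
  ## the constrained reduction should beat the QEA here
  expect_lt(cmp$rel_l2_constrained, cmp$rel_l2_qea)
})

test_that("conditioning on a slice extracts and renormalizes", {
  states <- as.matrix(expand.grid(S1 = 0:4, S2 = 0:2))[, 1:2]
  colnames(states) <- c("S1", "S2")
  prob <- rep(1 / nrow(states), nrow(states))
  d <- crnstationary:::state_distribution(states, prob)
  cond <- condition_on_slice(d, w = c(1L, 2L), v = 4L)
  ## slice states: (4,0), (2,1), (0,2) -> uniform over 3 x2 values
  expect_equal(cond$prob, rep(1 / 3, 3))
})

test_that("reduced slow model simulates with cached effective rates", {
  out <- reduced_slow_ssa(c(k1 = 1, k2 = 10, k3 = 20, k4 = 5),
                          s0 = 20L, t_end = 5, seed = 9)
  expect_equal(sum(out$occupancy$prob), 1, tolerance = 1e-12)
  expect_true(all(out$occupancy$s >= 0))
  expect_gt(out$n_jumps, 10)
})
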