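test_that("generator assembly: structure, row sums, truncation", {
  bd <- birth_death(lambda = 3, mu = 1)
  cls <- state_class("S", box = 10L)
  ch <- build_generator(bd, mass_action_kinetics(), cls)
  A <- as.matrix(ch$A)
  expect_equal(dim(A), c(11L, 11L))
  ## tridiagonal: no entry beyond the first off-diagonals
  expect_true(all(A[abs(row(A) - col(A)) > 1] == 0))
  expect_equal(as.numeric(Matrix::rowSums(ch$A)), rep(0, 11), tolerance = 1e-12)
  ## birth out of the top state is dropped by truncation
  expect_equal(A[11, 11], -10)

  ## 3-state class chain of the dimer pair on s = 4
  net <- reversible_dimer(2, 3)
  cls4 <- state_class(c("S1", "S2"), box = c(6L, 6L),
                      invariants = list("S1+2*S2=4"))
  ch4 <- build_generator(net, mass_action_kinetics(), cls4)
  expect_equal(nrow(ch4$states), 3L)
  expect_equal(as.numeric(Matrix::rowSums(ch4$A)), rep(0, 3), tolerance = 1e-12)
  ## states in order (0,2), (2,1), (4,0)
  expect_equal(as.matrix(ch4$A)[2, ], c(2 * 2 * 1, -(2 * 2 + 3 * 1), 3 * 1))
})

test_that("stationary solve matches closed forms and hand solves", {
  bd <- birth_death(lambda = 3, mu = 1)
  d <- solve_stationary(build_generator(bd, mass_action_kinetics(),
                                        state_class("S", box = 40L)))
  pois <- stats::dpois(0:40, 3)
  expect_equal(d$prob, pois / sum(pois), tolerance = 1e-10)
  expect_lt(d$meta$residual, 1e-10)

  ## hand linear solve of the 3-state chain
  net <- reversible_dimer(2, 3)
  cls4 <- state_class(c("S1", "S2"), box = c(6L, 6L),
                      invariants = list("S1+2*S2=4"))
  ch4 <- build_generator(net, mass_action_kinetics(), cls4)
  d4 <- solve_stationary(ch4)
  M <- t(as.matrix(ch4$A))
  M[3, ] <- 1
  hand <- solve(M, c(0, 0, 1))
  expect_equal(d4$prob, hand, tolerance = 1e-12)

  ## full four-reaction model on a small box: mode location sanity
  fx <- crn_fixture("full_system15", params = c(k1 = 1, k2 = 10, k3 = 20, k4 = 5))
  cls <- state_class(c("S1", "S2"), box = c(50L, 35L))
  dfull <- solve_stationary(build_generator(fx$net, fx$kin, cls))
  expect_lt(dfull$boundary_mass, 1e-8)
  expect_equal(sum(dfull$prob), 1, tolerance = 1e-12)
})

test_that("solution is invariant under permutation of the enumeration", {
  net <- reversible_dimer(2, 3)
  fx <- crn_fixture("full_system15", params = c(k1 = 1, k2 = 10, k3 = 20, k4 = 5))
  cls <- state_class(c("S1", "S2"), box = c(15L, 10L))
  ch <- build_generator(fx$net, fx$kin, cls)
  d <- solve_stationary(ch)
  set.seed(1)
  p <- sample(nrow(ch$states))
  chp <- ch
  chp$A <- ch$A[p, p]
  chp$states <- ch$states[p, , drop = FALSE]
  dp <- solve_stationary(chp)
  expect_equal(dp$prob[order(p)], d$prob, tolerance = 1e-10)
})

test_that("reducible truncations are detected", {
  ## the bare dimer pair conserves s: a full box mixes many closed classes
  net <- reversible_dimer(1, 1)
  cls <- state_class(c("S1", "S2"), box = c(6L, 6L))
  ch <- build_generator(net, mass_action_kinetics(), cls)
  expect_error(solve_stationary(ch), "closed")
})

test_that("stationarity residual separates stationary from non-stationary laws", {
  bd <- birth_death(lambda = 3, mu = 1)
  cls <- state_class("S", box = 40L)
  ch <- build_generator(bd, mass_action_kinetics(), cls)
  d <- solve_stationary(ch)
  sr <- stationarity_residual(d, bd, mass_action_kinetics())
  expect_lt(sr$max_scaled, 1e-10)
  ## negative control: the uniform law is far from stationary
  uni <- d
  uni$prob <- rep(1 / length(d$prob), length(d$prob))
  sru <- stationarity_residual(uni, bd, mass_action_kinetics())
  expect_gt(sru$max_abs, 0.01)
})

test_that("distribution distances behave as metrics on shared supports", {
  p <- c(1, 0); q <- c(0, 1)
  expect_equal(distribution_distance(p, p), 0)
  expect_equal(distribution_distance(p, q, "total_variation"), 1)
  expect_equal(distribution_distance(c(0.5, 0.5), c(1, 0), "relative_l2"),
               sqrt(0.5) / 1)
  expect_error(distribution_distance(c(1), c(0.5, 0.5)), "mismatch")
  bd <- birth_death()
  cls <- state_class("S", box = 10L)
  d1 <- solve_stationary(build_generator(bd, mass_action_kinetics(), cls))
  d2 <- d1
  d2$states <- d1$states + 1L
  expect_error(distribution_distance(d1, d2), "support")
})
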