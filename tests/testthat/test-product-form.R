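test_that("class enumeration is exact and lexicographic", {
  cls <- state_class(c("S1", "S2"), box = c(10L, 10L),
                     invariants = list("S1+2*S2=4"))
  expect_equal(unname(enumerate_class(cls)),
               matrix(c(0L, 2L, 2L, 1L, 4L, 0L), ncol = 2, byrow = TRUE))

  cls2 <- state_class(c("S1", "S2"), box = c(2L, 2L),
                      residues = list("S1+S2%2=0"))
  X2 <- enumerate_class(cls2)
  expect_equal(nrow(X2), 5L)
  expect_true(all((rowSums(X2) %% 2) == 0))

  cls3 <- state_class(c("S1", "S2"), box = c(1000L, 500L),
                      invariants = list("S1+2*S2=300"))
  expect_equal(nrow(enumerate_class(cls3)), 151L)

  empty <- state_class(c("S1", "S2"), box = c(2L, 2L),
                       invariants = list("S1+2*S2=40"))
  expect_equal(nrow(enumerate_class(empty)), 0L)
  m <- product_form_measure(c(1, 1), identity_thetas(c("S1", "S2")),
                            reversible_dimer())
  expect_error(normalize_measure(m, empty), "empty")
})

test_that("log-measures: direct arithmetic, special cases, zero denominators", {
  th <- list(theta_fn(fun = function(z) z, alpha = 1L))
  expect_equal(log_measure_thm1(c = 2, thetas = th, x = 3), log(8 / 6))
  expect_equal(log_measure_thm1(c = 2, thetas = th, x = 0), 0)

  ## all alpha = 1: the strided measure equals the classical one
  net <- bd3_network()
  kin <- identity_thetas(net$species)
  cvec <- c(2, 3, 1.25)
  m <- product_form_measure(cvec, kin, net)
  for (x in list(c(0, 0, 0), c(3, 1, 2), c(5, 5, 5))) {
    expect_equal(as.numeric(m$log_weight(matrix(x, 1))),
                 log_measure_thm1(cvec, rep(list(theta_fn(fun = function(z) z)), 3), x))
    expect_equal(log_measure_thm2(cvec, kin, net, alpha_partition(net), x),
                 log_measure_thm1(cvec, rep(list(theta_fn(fun = function(z) z)), 3), x))
  }

  ## scaled species below alpha contribute only the numerator
  fx <- crn_fixture("constrained_system18")
  eqc <- dimer_equilibrium_closed_form(1, 100)
  m18 <- product_form_measure(eqc, fx$kin, fx$net, ap = fx$ap)
  expect_equal(as.numeric(m18$log_weight(matrix(c(1, 0), 1))), log(eqc[1]))

  ## a theta that vanishes somewhere above alpha knocks states out of support
  holey <- theta_kinetics(list(S1 = theta_fn(table = c(0, 0, 1, 2, 0, 3, 1, 1, 1),
                                             alpha = 2L),
                               S2 = theta_fn(fun = function(z) z, alpha = 1L)),
                          mode = "alpha_theta_product")
  mh <- product_form_measure(c(1, 1), holey, fx$net, ap = fx$ap)
  expect_equal(as.numeric(mh$log_weight(matrix(c(4, 0), 1))), -Inf)
  cls <- state_class(c("S1", "S2"), box = c(8L, 4L),
                     invariants = list("S1+2*S2=8"))
  dh <- normalize_measure(mh, cls)
  expect_equal(dh$prob[dh$states[, 1] == 4], 0)
})

test_that("the measure with identity thetas is the matched product-Poisson", {
  net <- bd3_network()
  eq <- solve_complex_balanced(net)
  m <- product_form_measure(eq$c, identity_thetas(net$species), net)
  cls <- state_class(net$species, box = c(25L, 32L, 20L))
  d <- normalize_measure(m, cls)
  pois <- stats::dpois(d$states[, 1], eq$c[1]) *
    stats::dpois(d$states[, 2], eq$c[2]) * stats::dpois(d$states[, 3], eq$c[3])
  expect_equal(d$prob, pois / sum(pois), tolerance = 1e-12)
  expect_lt(d$boundary_mass, 1e-12)
  expect_false(d$truncation_limited)
})

test_that("normalization, moments and the truncation flag", {
  one <- state_class("S", box = 5L, invariants = list(list(w = 1L, v = 3L)))
  m1 <- product_form_measure(2, identity_thetas("S"), birth_death(2, 1))
  d1 <- normalize_measure(m1, one)
  expect_equal(d1$prob, 1)

  big <- state_class("S", box = 80L)
  d <- normalize_measure(product_form_measure(5, identity_thetas("S"),
                                              birth_death(5, 1)), big)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(expectation(d, 1L), 5, tolerance = 1e-10)   # Poisson mean
  expect_equal(expectation(d, function(X) rep(1, nrow(X))), 1)
  mg <- marginal_distribution(d, "S")
  expect_equal(mg$prob, d$prob)

  cramped <- normalize_measure(product_form_measure(5, identity_thetas("S"),
                                                    birth_death(5, 1)),
                               state_class("S", box = 6L))
  expect_true(cramped$truncation_limited)
})

test_that("product-form distributions are stationary for the exact chain", {
  ## the headline equivalence on the constrained subsystem, several classes
  fx <- crn_fixture("constrained_system18")
  eq <- solve_complex_balanced(fx$net, constraint = "S1+2*S2=1")
  meas <- product_form_measure(eq$c, fx$kin, fx$net, ap = fx$ap)
  for (s in c(11L, 40L)) {
    cls <- state_class(c("S1", "S2"), box = c(s, s %/% 2L),
                       invariants = list(sprintf("S1+2*S2=%d", s)))
    pfd <- normalize_measure(meas, cls)
    exd <- solve_stationary(build_generator(fx$net, fx$kin, cls, ap = fx$ap))
    expect_lt(distribution_distance(pfd, exd, "total_variation"), 1e-8)
    sr <- stationarity_residual(pfd, fx$net, fx$kin, ap = fx$ap)
    expect_lt(sr$max_abs, 1e-10)
  }
})
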