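test_that("the fixture catalog is structurally consistent", {
  expect_setequal(fixture_names(),
                  c("full_system15", "qea_system17", "constrained_system18",
                    "ex1_network9", "dimer_system22", "example3_tabulated",
                    "example4_system25"))
  for (nm in fixture_names()) {
    fx <- crn_fixture(nm, zmax = 60L)
    expect_s3_class(fx$net, "crn_network")
    expect_s3_class(fx$kin, "crn_kinetics")
    if (fx$kin$mode != "mass_action") {
      va <- validate_assumption1(fx$kin, fx$net, fx$ap, zmax = 50L)
      expect_true(va$valid, info = nm)
    }
  }
  expect_error(crn_fixture("dimer_genetic23"), "unknown fixture")

  st18 <- crn_structure(crn_fixture("constrained_system18")$net)
  expect_equal(st18$deficiency, 0L)
  expect_true(st18$weakly_reversible)
  expect_equal(crn_structure(crn_fixture("full_system15")$net)$deficiency, 1L)
  expect_equal(crn_fixture("example3_tabulated", zmax = 60L)$ap$alpha, 2L)
  expect_equal(crn_fixture("example4_system25", zmax = 60L)$ap$alpha, c(1L, 1L))
})

test_that("the catalyzed dimerization fixture has a product-form stationary law", {
  fx <- crn_fixture("dimer_system22")
  eq <- solve_complex_balanced(fx$net, constraint = "P+2*D=1")
  meas <- product_form_measure(eq$c, fx$kin, fx$net, ap = fx$ap)
  cls <- state_class(c("P", "D"), box = c(30L, 15L),
                     invariants = list("P+2*D=30"))
  pfd <- normalize_measure(meas, cls)
  exd <- solve_stationary(build_generator(fx$net, fx$kin, cls, ap = fx$ap))
  expect_lt(distribution_distance(pfd, exd, "total_variation"), 1e-10)
})

test_that("the tabulated-theta motif has the strided invariant law on its parity class", {
  fx <- crn_fixture("example3_tabulated", zmax = 80L)
  eq <- solve_complex_balanced(fx$net)
  expect_equal(as.numeric(eq$c), sqrt(fx$params[["kb"]] / fx$params[["kd"]]),
               tolerance = 1e-10)
  meas <- product_form_measure(eq$c, fx$kin, fx$net, ap = fx$ap)
  cls <- state_class("S", box = 70L, residues = list(list(u = 1L, m = 2L, a = 0L)))
  pfd <- normalize_measure(meas, cls)
  expect_false(pfd$truncation_limited)
  sr <- stationarity_residual(pfd, fx$net, fx$kin, ap = fx$ap)
  expect_lt(sr$max_scaled, 1e-12)
})

test_that("random thetas have the exact admissibility pattern, reproducibly", {
  for (a in 1:3) {
    th <- random_theta(alpha = a, zmax = 30, seed = 42)
    vals <- theta_eval(th, 0:30)
    expect_true(all(vals[seq_len(a)] == 0))
    expect_true(all(vals[(a + 1):31] > 0))
    expect_true(all(vals[(a + 1):31] >= 1e-2 & vals[(a + 1):31] <= 1e2))
    th2 <- random_theta(alpha = a, zmax = 30, seed = 42)
    expect_identical(theta_eval(th2, 0:30), vals)
  }
})

test_that("random networks are weakly reversible with deficiency zero", {
  for (seed in 1:10) {
    d <- (seed %% 3L) + 1L
    net <- random_complex_balanced_network(d, seed = seed)
    st <- crn_structure(net)
    expect_equal(st$deficiency, 0L)
    expect_true(st$weakly_reversible)
  }
})

test_that("end-to-end: the strided product-form measure is stationary for random models", {
  ## randomized theorem check: random deficiency-zero cycle + admissible
  ## random thetas => the measure built from the complex-balanced
  ## equilibrium satisfies the pointwise balance on interior states
  n_checked <- 0L
  for (seed in 1:50) {
    d <- (seed %% 3L) + 1L
    net <- random_complex_balanced_network(d, seed = 1000L + seed)
    kin <- random_theta_kinetics(net, zmax = 60L, seed = seed)
    eq <- tryCatch(solve_complex_balanced(net), error = function(e) NULL)
    if (is.null(eq)) next     # rare: hard Newton instance, not the theorem
    m <- product_form_measure(eq$c, kin, net)
    box <- rep(if (d == 3L) 14L else 24L, d)
    X <- enumerate_class(state_class(net$species, box))
    lw <- m$log_weight(X)
    fin <- is.finite(lw)
    w <- exp(lw - max(lw[fin]))
    dist <- crnstationary:::state_distribution(X, w / sum(w))
    sr <- stationarity_residual(dist, net, kin)
    expect_lt(sr$max_rel, 1e-10)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 45L)
})

test_that("perturbing one theta value breaks stationarity (non-vacuous residuals)", {
  fx <- crn_fixture("constrained_system18")
  eq <- solve_complex_balanced(fx$net, constraint = "S1+2*S2=1")
  tab <- theta_eval(fx$kin$thetas$S1, 0:60)
  tab[11] <- tab[11] * 1.1                     # theta1(10) off by 10%
  kin_bad <- theta_kinetics(list(S1 = theta_fn(table = tab, alpha = 2L),
                                 S2 = theta_fn(fun = function(z) z)),
                            mode = "alpha_theta_product")
  cls <- state_class(c("S1", "S2"), box = c(20L, 10L),
                     invariants = list("S1+2*S2=20"))
  pfd <- normalize_measure(product_form_measure(eq$c, fx$kin, fx$net, ap = fx$ap), cls)
  sr <- stationarity_residual(pfd, fx$net, kin_bad, ap = fx$ap)
  expect_gt(sr$max_rel, 1e-4)
})
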