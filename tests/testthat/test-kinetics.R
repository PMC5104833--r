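test_that("stochastic mass action uses falling factorials", {
  net <- reversible_dimer(kf = 1, kr = 1)
  expect_equal(mass_action_intensity(net, 1L, c(5, 0)), 20)      # 5*4
  expect_equal(mass_action_intensity(net, 1L, c(1, 0)), 0)       # below source
  expect_equal(mass_action_intensity(net, 2L, c(0, 3)), 3)
  fx <- crn_fixture("full_system15")
  x <- c(7, 2)
  lam <- intensities(fx$kin, fx$net, x)
  expect_equal(as.numeric(lam),
               c(params21[["k1"]] * 7 * 6, params21[["k2"]] * 2,
                 params21[["k3"]], params21[["k4"]] * 7))
})

test_that("theta-product intensities follow the alpha-strided form", {
  fx <- crn_fixture("constrained_system18")
  ## theta1(5) = 5*4 + 1500 = 1520
  expect_equal(theta_intensity(fx$kin, fx$net, fx$ap, 1L, c(5, 0)), 1520)
  expect_equal(theta_intensity(fx$kin, fx$net, fx$ap, 1L, c(1, 4)), 0)
  expect_equal(theta_intensity(fx$kin, fx$net, fx$ap, 2L, c(1, 4)),
               params21[["k2"]] * 4)

  ## the four-factor rate of the three-species illustration
  fx9 <- crn_fixture("ex1_network9")
  th1 <- function(z) ifelse(z >= 0, z * (z - 1) + (z >= 2), 0)
  x <- c(6, 3, 2)
  expect_equal(theta_intensity(fx9$kin, fx9$net, fx9$ap, 3L, x),
               th1(6) * th1(4) * 3 * 2)
  expect_equal(theta_intensity(fx9$kin, fx9$net, fx9$ap, 4L, x), 2 / 3)
  ## source 4S1 + 2S2 needs x1 >= 4 on the alpha-2 lattice
  expect_equal(theta_intensity(fx9$kin, fx9$net, fx9$ap, 3L, c(3, 3, 2)), 0)
})

test_that("theta modes collapse onto each other and onto mass action", {
  net <- crn_fixture("full_system15")$net
  kin_theta <- identity_thetas(net$species)
  X <- as.matrix(expand.grid(0:6, 0:4))
  expect_equal(intensities(kin_theta, net, X),
               intensities(mass_action_kinetics(), net, X))
  ## alpha_theta_product with all alpha = 1 equals theta_product
  ths <- list(S1 = theta_fn(expr = "x*x + x", alpha = 1L),
              S2 = theta_fn(expr = "x", alpha = 1L))
  k1 <- theta_kinetics(ths, mode = "theta_product")
  k2 <- theta_kinetics(ths, mode = "alpha_theta_product")
  expect_equal(intensities(k1, net, X), intensities(k2, net, X))
})

test_that("no kinetics mode produces transitions off the lattice", {
  fixtures <- c("full_system15", "constrained_system18", "ex1_network9")
  for (fn in fixtures) {
    fx <- crn_fixture(fn)
    X <- as.matrix(expand.grid(rep(list(0:5), fx$net$d)))
    lam <- intensities(fx$kin, fx$net, X, ap = fx$ap)
    for (k in seq_len(fx$net$K)) {
      below <- rowSums(sweep(X, 2L, fx$net$nu[k, ], `<`)) > 0
      expect_true(all(lam[below, k] == 0), info = paste(fn, "reaction", k))
    }
  }
})

test_that("admissibility validation reports each violation", {
  fx <- crn_fixture("constrained_system18")
  expect_true(validate_assumption1(fx$kin, fx$net, fx$ap, zmax = 200)$valid)

  ## theta(z) = z under alpha = 2 violates the zero condition at z = 1
  bad <- theta_kinetics(list(S1 = theta_fn(expr = "x", alpha = 2L),
                             S2 = theta_fn(expr = "x", alpha = 1L)),
                        mode = "alpha_theta_product")
  rep1 <- validate_assumption1(bad, fx$net, fx$ap, zmax = 50)
  expect_false(rep1$valid)
  expect_true(any(grepl("must be 0", rep1$violations)))

  ## divisibility failure: source count 3 against alpha = 2
  tri <- crn_network("S", list(
    list(reactants = c(S = 3), products = integer(0), rate_constant = 1),
    list(reactants = integer(0), products = c(S = 3), rate_constant = 1)))
  fake_ap <- structure(list(alpha = 2L, slow_set = integer(0),
                            scaled_set = 1L, species = "S"),
                       class = "crn_alpha")
  kin3 <- theta_kinetics(list(S = theta_fn(expr = "x*(x-1)*ind(x>1)", alpha = 2L)),
                         mode = "alpha_theta_product")
  rep2 <- validate_assumption1(kin3, tri, fake_ap, zmax = 20)
  expect_false(rep2$valid)
  expect_true(any(grepl("not divisible", rep2$violations)))
  expect_error(intensities(kin3, tri, c(5L), ap = fake_ap), "not divisible")
})

test_that("theta rules: tables refuse to extrapolate, expressions are sandboxed", {
  th <- theta_fn(table = c(0, 1, 4, 9), alpha = 1L)
  expect_equal(theta_eval(th, c(-2, 0, 3)), c(0, 0, 9))
  expect_error(theta_eval(th, 4), "extrapolate")
  expect_error(theta_fn(expr = "system('ls')"), "not allowed")
  expect_error(theta_fn(expr = "x + y"), "not allowed")
  th2 <- theta_fn(expr = "ind(x > 1) * (10 + x + 6*sin(pi*x/5))", alpha = 2L)
  expect_equal(theta_eval(th2, 0:2), c(0, 0, 12 + 6 * sin(2 * pi / 5)))
})
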