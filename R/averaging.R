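#' Quasi-equilibrium (QEA) fast-subsystem distribution
#'
#' Stationary distribution of the dimerization count under the QEA
#' reduction of the two-species dimerization module: the fast subsystem
#' `2 S1 <-> S2` with its own mass-action rate constants `(k1, k2)`,
#' conditioned on the conserved quantity `s = x1 + 2 x2`. Being
#' mass-action, weakly reversible and deficiency zero, the fast subsystem
#' has a conditioned product-Poisson stationary law with parameter the
#' complex-balanced equilibrium `(d1, d2)` normalized by `d1 + 2 d2 = 1`:
#' \deqn{\pi_{QEA}(x_2) \propto \frac{d_1^{s-2x_2}}{(s-2x_2)!}
#'   \frac{d_2^{x_2}}{x_2!}.}
#'
#' @param params named vector with `k1..k4` (only `k1`, `k2` enter the
#'   fast subsystem).
#' @param s conserved quantity (nonnegative integer).
#' @param method `"product_form"` runs the generic product-form machinery
#'   on the fixture network; `"closed_form"` evaluates the conditioned
#'   Poisson formula directly. The two agree to floating precision and are
#'   kept as independent code paths.
#' @return `state_distribution` over `x2 = 0..floor(s/2)` (single
#'   coordinate `S2`).
#' @export
qea_distribution <- function(params, s,
                             method = c("product_form", "closed_form")) {
  method <- match.arg(method)
  params <- check_dimer_params(params)
  s <- as.integer(s)
  x2 <- 0:(s %/% 2)
  d <- dimer_equilibrium_closed_form(params[["k1"]], params[["k2"]])
  if (method == "closed_form") {
    lw <- (s - 2 * x2) * log(d[1]) - lfactorial(s - 2 * x2) +
      x2 * log(d[2]) - lfactorial(x2)
    return(x2_distribution(x2, lw, s))
  }
  fx <- crn_fixture("qea_system17", params = params)
  eq <- solve_complex_balanced(fx$net, constraint = "S1+2*S2=1")
  meas <- product_form_measure(eq$c, fx$kin, fx$net)
  cls <- state_class(c("S1", "S2"), box = c(s, s %/% 2),
                     invariants = list(sprintf("S1+2*S2=%d", s)))
  dist <- normalize_measure(meas, cls)
  marginal_to_x2(dist, s)
}

#' Constrained-averaging fast-subsystem distribution
#'
#' Stationary distribution of the dimer count for the constrained
#' reduction of the same module: the chain `2 S1 <-> S2` in which the slow
#' production reaction is projected into the dimerization direction, so
#' the forward intensity is \eqn{k_1 x_1(x_1-1) + k_3 1\{x_1>1\}} — a
#' theta-product rate with \eqn{\alpha_1 = 2},
#' \eqn{\theta_1(z) = z(z-1) + (k_3/k_1) 1\{z>1\}} — and the reverse
#' intensity is \eqn{k_2 x_2}. The alpha-strided product-form theorem
#' gives the stationary law in closed form with parameter the
#' complex-balanced equilibrium of the associated mass-action system
#' `(k1, k2)` under `c1 + 2 c2 = 1`:
#' \deqn{\pi_{Con}(x_2) \propto \frac{c_1^{s-2x_2}}
#'   {\prod_{j=0}^{\lfloor (s-2x_2)/2\rfloor - 1}
#'    ((s-2x_2-2j)(s-2x_2-2j-1) + k_3/k_1)} \frac{c_2^{x_2}}{x_2!}}
#' (the indicator in \eqn{\theta_1} is identically one over the product
#' range and drops out).
#'
#' @inheritParams qea_distribution
#' @param method `"theorem2"` goes through the generic machinery
#'   (equilibrium solve, alpha-strided measure, class marginal);
#'   `"closed_form"` evaluates the displayed formula directly.
#' @return `state_distribution` over `x2 = 0..floor(s/2)`.
#' @export
constrained_distribution <- function(params, s,
                                     method = c("theorem2", "closed_form")) {
  method <- match.arg(method)
  params <- check_dimer_params(params)
  s <- as.integer(s)
  if (method == "closed_form") {
    k1 <- params[["k1"]]; k2 <- params[["k2"]]; k3 <- params[["k3"]]
    cc <- dimer_equilibrium_closed_form(k1, k2)
    x2 <- 0:(s %/% 2)
    lw <- vapply(x2, function(x2v) {
      m <- s - 2L * x2v
      nj <- m %/% 2L
      den <- if (nj > 0) {
        j <- 0:(nj - 1L)
        sum(log((m - 2 * j) * (m - 2 * j - 1) + k3 / k1))
      } else 0
      m * log(cc[1]) - den + x2v * log(cc[2]) - lfactorial(x2v)
    }, numeric(1))
    return(x2_distribution(x2, lw, s))
  }
  fx <- crn_fixture("constrained_system18", params = params)
  eq <- solve_complex_balanced(fx$net, constraint = "S1+2*S2=1")
  meas <- product_form_measure(eq$c, fx$kin, fx$net, ap = fx$ap)
  cls <- state_class(c("S1", "S2"), box = c(s, s %/% 2),
                     invariants = list(sprintf("S1+2*S2=%d", s)))
  dist <- normalize_measure(meas, cls)
  marginal_to_x2(dist, s)
}

## distributions over the dimer count share one constructor so supports
## always align for distance computations
x2_distribution <- function(x2, lw, s) {
  prob <- exp(lw - logsumexp(lw))
  prob <- prob / sum(prob)
  state_distribution(matrix(as.integer(x2), ncol = 1L,
                            dimnames = list(NULL, "S2")),
                     prob, log_weights = lw, meta = list(s = s))
}

marginal_to_x2 <- function(dist, s) {
  mg <- marginal_distribution(dist, "S2")
  full_x2 <- 0:(s %/% 2)
  prob <- numeric(length(full_x2))
  prob[match(mg$value, full_x2)] <- mg$prob
  state_distribution(matrix(full_x2, ncol = 1L, dimnames = list(NULL, "S2")),
                     prob, meta = list(s = s))
}

check_dimer_params <- function(params) {
  params <- unlist(params)
  need <- c("k1", "k2", "k3", "k4")
  if (!all(need %in% names(params)))
    stop("params must name ", paste(need, collapse = ", "))
  if (any(params[need] <= 0)) stop("rate parameters must be positive")
  params[need]
}

#' Closed-form equilibrium of the dimerization pair under c1 + 2 c2 = 1
#'
#' For `2 S1 <-> S2` with forward constant `kf` and reverse constant `kr`,
#' complex balance reads \eqn{k_f c_1^2 = k_r c_2}; with the normalization
#' \eqn{c_1 + 2 c_2 = 1} the positive root is
#' \deqn{c_1 = \frac{\sqrt{k_r(k_r + 8 k_f)} - k_r}{4 k_f},\qquad
#'   c_2 = (1 - c_1)/2.}
#' Used as the independent oracle for the equilibrium solver.
#'
#' @param kf,kr positive rate constants.
#' @return numeric vector `c(c1, c2)`.
#' @export
dimer_equilibrium_closed_form <- function(kf, kr) {
  c1 <- (sqrt(kr * (kr + 8 * kf)) - kr) / (4 * kf)
  c(c1, (1 - c1) / 2)
}

#' Effective rates of the reduced slow model
#'
#' In the averaged slow model for `s = x1 + 2 x2`, the production reaction
#' keeps its constant rate \eqn{\bar\lambda_3(s) = \kappa_3}, while the
#' degradation rate is the slow propensity averaged under the fast
#' stationary law: \eqn{\bar\lambda_4(s) = \kappa_4\, E[X_1]} with
#' \eqn{X_1 = s - 2 X_2}. The generic pattern — expectation of any slow
#' propensity under a fast stationary distribution — is available as
#' [expectation()].
#'
#' @param params named `k1..k4`.
#' @param s slow variable value.
#' @param mode `"qea"` or `"constrained"` fast law.
#' @return list with `lambda3`, `lambda4`, `E_X1`, and the jump sizes of
#'   the two slow channels in `s` (+2 for production, -1 for degradation,
#'   as forced by `s = x1 + 2 x2`).
#' @export
effective_rates <- function(params, s, mode = c("qea", "constrained")) {
  mode <- match.arg(mode)
  params <- check_dimer_params(params)
  dist <- switch(mode,
                 qea = qea_distribution(params, s, method = "closed_form"),
                 constrained = constrained_distribution(params, s, method = "closed_form"))
  e_x1 <- expectation(dist, function(X) s - 2 * X[, 1L])
  list(lambda3 = params[["k3"]], lambda4 = params[["k4"]] * e_x1,
       E_X1 = e_x1, jumps = c(lambda3 = +2L, lambda4 = -1L), mode = mode)
}

#' Expected share of reaction flux carried by designated fast reactions
#'
#' Under a stationary distribution, the long-run proportion of reaction
#' occurrences due to a designated fast subset equals the ratio of
#' expected propensities,
#' \eqn{100\, E[\sum_{k \in fast} \lambda_k(X)] / E[\sum_k \lambda_k(X)]}.
#' Fast reactions are designated explicitly (by label or index), never
#' auto-detected from timescales.
#'
#' @param dist a `state_distribution` (full-model stationary law).
#' @param net a [crn_network()].
#' @param kin a `crn_kinetics`.
#' @param fast reaction labels or indices of the fast subset.
#' @param ap optional [alpha_partition()].
#' @return percentage in `[0, 100]`.
#' @export
fast_reaction_proportion <- function(dist, net, kin, fast, ap = NULL) {
  stopifnot(inherits(dist, "state_distribution"))
  if (is.character(fast)) {
    idx <- match(fast, net$labels)
    if (anyNA(idx)) stop("unknown reaction labels: ",
                         paste(fast[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(fast)
  lam <- intensities(kin, net, dist$states, ap = ap)
  e_fast <- sum(rowSums(lam[, idx, drop = FALSE]) * dist$prob)
  e_tot <- sum(rowSums(lam) * dist$prob)
  100 * e_fast / e_tot
}

#' Compare QEA and constrained reductions against the full model
#'
#' The headline pipeline of the dimerization example: solve the full
#' four-reaction model's stationary distribution on a truncated box,
#' condition on the slice `x1 + 2 x2 = s` (take the slice probabilities
#' and renormalize), compute the QEA and constrained fast laws at the same
#' `s`, and report both relative l2 errors with the full-model conditional
#' as the reference.
#'
#' @param params named `k1..k4`.
#' @param s slice value.
#' @param box length-2 truncation bounds for the full solve.
#' @param full_dist optionally, a precomputed full-model stationary
#'   `state_distribution` on `box` (reused across calls; the solve
#'   dominates the cost).
#' @return list with `full_conditional`, `qea`, `constrained`
#'   (`state_distribution`s over `x2`), `rel_l2_qea`, `rel_l2_constrained`,
#'   `boundary_mass`, and solver metadata.
#' @export
compare_averaging <- function(params, s, box = c(500L, 350L),
                              full_dist = NULL) {
  params <- check_dimer_params(params)
  fx <- crn_fixture("full_system15", params = params)
  if (is.null(full_dist)) {
    cls <- state_class(c("S1", "S2"), box = box)
    chain <- build_generator(fx$net, fx$kin, cls)
    full_dist <- solve_stationary(chain)
  }
  cond <- condition_on_slice(full_dist, w = c(1L, 2L), v = s)
  qea <- qea_distribution(params, s, method = "closed_form")
  con <- constrained_distribution(params, s, method = "closed_form")
  list(full_conditional = cond, qea = qea, constrained = con,
       rel_l2_qea = distribution_distance(qea, cond),
       rel_l2_constrained = distribution_distance(con, cond),
       boundary_mass = full_dist$boundary_mass,
       meta = list(s = s, box = box, params = params,
                   solver = full_dist$meta))
}

#' Condition a two-species distribution on a linear slice
#'
#' Extracts the probabilities of all states with `w . x = v` and
#' renormalizes, returning the marginal over the last coordinate.
#'
#' @param dist a `state_distribution` over (x1, x2).
#' @param w integer weights of the conserved functional.
#' @param v slice value.
#' @return `state_distribution` over `x2 = 0..floor(v/w[2])`.
#' @export
condition_on_slice <- function(dist, w, v) {
  stopifnot(inherits(dist, "state_distribution"), ncol(dist$states) == 2L)
  sel <- as.numeric(dist$states %*% w) == v
  if (!any(sel)) stop("no state on the slice")
  ps <- dist$prob[sel]
  xs <- dist$states[sel, 2L]
  full_x2 <- 0:(v %/% w[2L])
  prob <- numeric(length(full_x2))
  prob[match(xs, full_x2)] <- ps
  prob <- prob / sum(prob)
  state_distribution(matrix(full_x2, ncol = 1L,
                            dimnames = list(NULL, colnames(dist$states)[2L])),
                     prob, meta = list(slice_w = w, slice_v = v))
}

#' Minimal slow-scale simulation of the reduced model
#'
#' Demonstration loop for the averaged slow model of `s = x1 + 2 x2`:
#' a birth-death walk on `s` with jumps +2 (rate `k3`) and -1 (rate
#' `k4 E[X1 | s]` under the selected fast law), simulated by the direct
#' method with the effective rates computed (and cached) per visited `s`.
#'
#' @param params named `k1..k4`.
#' @param s0 initial slow value.
#' @param t_end horizon.
#' @param seed integer seed.
#' @param mode fast law used for the averaging.
#' @return list with `occupancy` (data.frame `s`, `prob`), `n_jumps`.
#' @export
reduced_slow_ssa <- function(params, s0, t_end, seed,
                             mode = c("constrained", "qea")) {
  mode <- match.arg(mode)
  params <- check_dimer_params(params)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  cache <- new.env(parent = emptyenv())
  rate4 <- function(s) {
    key <- as.character(s)
    if (is.null(cache[[key]]))
      cache[[key]] <- effective_rates(params, s, mode)$lambda4
    cache[[key]]
  }
  s <- as.integer(s0)
  t_now <- 0
  occ <- new.env(parent = emptyenv())
  n_jumps <- 0L
  repeat {
    l3 <- params[["k3"]]
    l4 <- if (s > 0) rate4(s) else 0
    l0 <- l3 + l4
    tau <- stats::rexp(1L) / l0
    dwell <- min(tau, t_end - t_now)
    key <- as.character(s)
    occ[[key]] <- (occ[[key]] %||% 0) + dwell
    if (t_now + tau >= t_end) break
    t_now <- t_now + tau
    s <- if (stats::runif(1L) * l0 < l3) s + 2L else s - 1L
    n_jumps <- n_jumps + 1L
    if (n_jumps > 1e6) stop("reduced_slow_ssa: jump budget exceeded")
  }
  ks <- as.integer(ls(occ))
  wt <- vapply(as.character(sort(ks)), function(k) occ[[k]], numeric(1))
  list(occupancy = data.frame(s = sort(ks), prob = wt / sum(wt)),
       n_jumps = n_jumps, mode = mode, seed = seed)
}
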