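#' Product-form invariant measure
#'
#' The unnormalized product-form invariant measure of a complex-balanced
#' system with theta-product kinetics,
#' \deqn{\tilde\pi(x) = \prod_{i=1}^d \frac{c_i^{x_i}}
#'   {\prod_{j=0}^{\lfloor x_i/\alpha_i\rfloor - 1} \theta_i(x_i - j\alpha_i)},}
#' where `c` is a complex-balanced equilibrium of the associated
#' deterministic mass-action system. With all \eqn{\alpha_i = 1} this is
#' the classical theta-product measure, and with \eqn{\theta_i(z) = z} it
#' collapses to a product of Poisson weights \eqn{c_i^{x_i}/x_i!}.
#'
#' All arithmetic is in log space; states at which a denominator theta
#' factor vanishes are outside the support (log-weight `-Inf`) and receive
#' probability zero.
#'
#' @param c positive equilibrium vector (length d).
#' @param kin a `crn_kinetics` (theta modes or mass action, mass action
#'   meaning the identity thetas).
#' @param net the [crn_network()] the kinetics refer to.
#' @param ap optional [alpha_partition()].
#' @return object of class `pf_measure` with `$log_weight(X)` evaluating
#'   log of the measure on a state matrix.
#' @export
product_form_measure <- function(c, kin, net, ap = NULL) {
  stopifnot(inherits(net, "crn_network"), length(c) == net$d, all(c > 0))
  rt <- resolve_thetas(kin, net, ap)
  lc <- log(c)
  d <- net$d
  gcache <- new.env(parent = emptyenv())
  ## g_i(x) = sum_{j=0}^{floor(x/alpha)-1} log theta_i(x - j alpha),
  ## tabulated by the strided recursion g(x) = g(x - alpha) + log theta(x).
  gtab <- function(i, xmax) {
    key <- paste0(i, ":", xmax)
    if (!is.null(gcache[[key]])) return(gcache[[key]])
    a <- rt$alpha[i]
    lth <- suppressWarnings(log(theta_eval(rt$thetas[[i]], 0:xmax)))
    g <- numeric(xmax + 1L)
    if (xmax >= a) for (x in a:xmax) g[x + 1L] <- g[x - a + 1L] + lth[x + 1L]
    gcache[[key]] <- g
    g
  }
  log_weight <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    lw <- numeric(nrow(X))
    for (i in seq_len(d)) {
      g <- gtab(i, max(X[, i], rt$alpha[i]))
      lw <- lw + X[, i] * lc[i] - g[X[, i] + 1L]
    }
    ## a zero theta factor makes g = -Inf: such states are outside the
    ## support and get weight zero, not infinite weight
    lw[is.nan(lw) | lw == Inf] <- -Inf
    unname(lw)
  }
  structure(list(c = c, alpha = rt$alpha, thetas = rt$thetas,
                 log_weight = log_weight, species = net$species),
            class = "pf_measure")
}

#' Classical product-form log-measure (all alpha = 1)
#'
#' Direct evaluation of
#' \eqn{\log\tilde\pi(x) = \sum_i [x_i \log c_i -
#' \sum_{j=0}^{x_i-1}\log\theta_i(x_i-j)]} at a single state.
#'
#' @param c positive vector.
#' @param thetas list of [theta_fn()] with alpha 1, one per coordinate.
#' @param x state.
#' @return log of the unnormalized weight (`-Inf` outside the support).
#' @export
log_measure_thm1 <- function(c, thetas, x) {
  stopifnot(length(c) == length(x), length(thetas) == length(x))
  lw <- 0
  for (i in seq_along(x)) {
    if (thetas[[i]]$alpha != 1L) stop("log_measure_thm1 requires alpha = 1")
    lw <- lw + x[i] * log(c[i])
    if (x[i] > 0) {
      f <- theta_eval(thetas[[i]], x[i] - 0:(x[i] - 1L))
      if (any(f <= 0)) return(-Inf)
      lw <- lw - sum(log(f))
    }
  }
  lw
}

#' Alpha-strided product-form log-measure
#'
#' Single-state evaluation of the alpha-strided measure; the batch
#' equivalent is `product_form_measure(...)$log_weight`.
#'
#' @param c positive vector.
#' @param kin a `crn_kinetics`.
#' @param net the [crn_network()].
#' @param ap an [alpha_partition()].
#' @param x state.
#' @return log weight (`-Inf` outside support).
#' @export
log_measure_thm2 <- function(c, kin, net, ap, x) {
  m <- product_form_measure(c, kin, net, ap)
  m$log_weight(matrix(stop_if_not_state(x, net$d), 1L))
}

#' Normalize a product-form measure on a state class
#'
#' Enumerates the class, evaluates log-weights, and normalizes by
#' log-sum-exp. Summability over the infinite lattice is not proven here;
#' it is certified empirically: if the boundary shell of the box (states
#' with any coordinate at its upper bound) carries a relative mass of
#' 1e-12 or more, the result is flagged `truncation_limited`.
#'
#' @param measure a [product_form_measure()].
#' @param cls a [state_class()].
#' @return a `state_distribution`: list with `states`, `prob`,
#'   `log_weights`, `log_gamma` (log normalization), `boundary_mass`,
#'   `truncation_limited`, `class`.
#' @export
normalize_measure <- function(measure, cls) {
  stopifnot(inherits(measure, "pf_measure"), inherits(cls, "state_class"))
  X <- enumerate_class(cls)
  if (nrow(X) == 0L) stop("state class is empty")
  lw <- measure$log_weight(X)
  lg <- logsumexp(lw)
  if (!is.finite(lg)) stop("no state of the class lies in the measure's support")
  prob <- exp(lw - lg)
  prob <- prob / sum(prob)
  state_distribution(X, prob, log_weights = lw, log_gamma = lg,
                     class_ = cls,
                     boundary_mass = boundary_shell_mass(X, prob, cls))
}

## Common container for distributions over an enumerated state set.
state_distribution <- function(states, prob, log_weights = NULL,
                               log_gamma = NA_real_, class_ = NULL,
                               boundary_mass = NA_real_, meta = list()) {
  prob <- unname(as.numeric(prob))
  structure(list(states = states, prob = prob, log_weights = log_weights,
                 log_gamma = log_gamma, class = class_,
                 boundary_mass = boundary_mass,
                 truncation_limited = is.finite(boundary_mass) && boundary_mass >= 1e-12,
                 meta = meta),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("Distribution over", nrow(x$states), "states in",
      ncol(x$states), "coordinates\n")
  if (is.finite(x$boundary_mass))
    cat("  boundary mass:", format(x$boundary_mass),
        if (isTRUE(x$truncation_limited)) " (truncation-limited!)" else "", "\n")
  top <- order(x$prob, decreasing = TRUE)[seq_len(min(3L, length(x$prob)))]
  for (t in top)
    cat("  P(", paste(x$states[t, ], collapse = ","), ") = ",
        signif(x$prob[t], 6), "\n", sep = "")
  invisible(x)
}

#' Expectations and marginals over an enumerated distribution
#'
#' `expectation()` computes \eqn{E[f(X)]} by exact summation;
#' `marginal_distribution()` aggregates the probability of one coordinate.
#'
#' @param dist a `state_distribution`.
#' @param f either a coordinate index, a numeric coefficient vector (a
#'   linear functional of the state), or a function taking the state matrix
#'   and returning one value per state.
#' @return a single number (`expectation`) or a data.frame with columns
#'   `value`, `prob` (`marginal_distribution`).
#' @export
expectation <- function(dist, f) {
  stopifnot(inherits(dist, "state_distribution"))
  vals <- functional_values(dist$states, f)
  sum(vals * dist$prob)
}

#' @rdname expectation
#' @param coordinate coordinate index or species name.
#' @export
marginal_distribution <- function(dist, coordinate) {
  stopifnot(inherits(dist, "state_distribution"))
  if (is.character(coordinate))
    coordinate <- match(coordinate, colnames(dist$states))
  v <- dist$states[, coordinate]
  agg <- rowsum(dist$prob, v)
  data.frame(value = as.integer(rownames(agg)), prob = as.numeric(agg))
}

functional_values <- function(X, f) {
  if (is.function(f)) return(f(X))
  if (is.character(f)) {
    i <- match(f, colnames(X))
    if (anyNA(i)) stop("unknown coordinate: ", paste(f[is.na(i)], collapse = ", "))
    f <- i
  }
  f <- as.numeric(f)
  if (length(f) == 1L) return(X[, f])
  as.numeric(X %*% f)
}

## Coordinates for which the box bound actually truncates the class: a
## coordinate whose maximum under the linear invariants already fits in
## the box cannot lose mass to truncation (e.g. the extreme states of a
## conserved slice are genuine lattice boundary, not a cut).
truncating_coords <- function(cls) {
  vapply(seq_len(cls$d), function(i) {
    for (iv in cls$invariants) {
      if (all(iv$w >= 0) && iv$w[i] > 0 && iv$v >= 0 &&
          iv$v %/% iv$w[i] <= cls$box[i])
        return(FALSE)
    }
    TRUE
  }, logical(1))
}

boundary_shell_mass <- function(states, prob, cls) {
  tc <- truncating_coords(cls)
  if (!any(tc)) return(0)
  shell <- rowSums(t(t(states[, tc, drop = FALSE]) == cls$box[tc])) > 0
  sum(prob[shell])
}
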