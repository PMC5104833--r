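#' Per-species theta function
#'
#' A theta function is the univariate building block of theta-product
#' kinetics: reaction intensities factor as products of
#' \eqn{\theta_i} evaluated along an \eqn{\alpha_i}-strided lattice of the
#' species count. The admissibility condition ("Assumption 1") is that
#' \eqn{\theta_i(z) = 0} exactly for \eqn{z \le \alpha_i - 1} and
#' \eqn{\theta_i(z) > 0} for \eqn{z \ge \alpha_i}; see
#' [validate_assumption1()].
#'
#' Exactly one of `expr`, `table`, `fun` must be given:
#' \describe{
#'   \item{`expr`}{arithmetic expression in the variable `x`, e.g.
#'     `"x*(x-1) + 1500*ind(x > 1)"`. Supported: `+ - * / ^`, comparisons
#'     inside `ind()` (indicator, returns 0/1), `sin`, `cos`, `sqrt`,
#'     `exp`, `log`, `abs`, `floor`, and the constant `pi`.}
#'   \item{`table`}{numeric vector of values `theta(0), theta(1), ...`.
#'     Evaluation beyond the last entry is an error, never an
#'     extrapolation (silent extrapolation would corrupt product-form
#'     denominators).}
#'   \item{`fun`}{a vectorized R function of the integer count.}
#' }
#' Negative arguments always evaluate to zero: an intensity whose source
#' would drive the state off the nonnegative lattice vanishes.
#'
#' @param expr,table,fun the rule (see above).
#' @param alpha positive integer stride \eqn{\alpha_i}.
#' @return object of class `theta_fn`.
#' @export
theta_fn <- function(expr = NULL, table = NULL, fun = NULL, alpha = 1L) {
  given <- c(!is.null(expr), !is.null(table), !is.null(fun))
  if (sum(given) != 1L) stop("give exactly one of expr, table, fun")
  alpha <- as.integer(alpha)
  if (alpha < 1L) stop("alpha must be a positive integer")
  type <- c("expr", "table", "fun")[given]
  if (type == "table") {
    table <- as.numeric(table)
    if (any(table < 0)) stop("theta table values must be nonnegative")
  }
  if (type == "expr") {
    parsed <- tryCatch(parse(text = expr)[[1L]],
                       error = function(e) stop("cannot parse theta expression: ", expr))
    check_theta_expr(parsed)
  } else parsed <- NULL
  structure(list(type = type, expr = expr, parsed = parsed,
                 table = table, fun = fun, alpha = alpha),
            class = "theta_fn")
}

## Whitelist of callables allowed inside a theta expression.
theta_expr_env <- function(x) {
  list2env(list(
    x = x, pi = base::pi,
    ind = function(cond) as.numeric(cond),
    sin = base::sin, cos = base::cos, sqrt = base::sqrt, exp = base::exp,
    log = base::log, abs = base::abs, floor = base::floor,
    `+` = `+`, `-` = `-`, `*` = `*`, `/` = `/`, `^` = `^`,
    `(` = `(`, `>` = `>`, `>=` = `>=`, `<` = `<`, `<=` = `<=`,
    `==` = `==`, `!=` = `!=`, `&` = `&`, `|` = `|`, `!` = `!`,
    pmax = base::pmax, pmin = base::pmin
  ), parent = emptyenv())
}

check_theta_expr <- function(e) {
  ok_names <- c("x", "pi", "ind", "sin", "cos", "sqrt", "exp", "log", "abs",
                "floor", "+", "-", "*", "/", "^", "(", ">", ">=", "<", "<=",
                "==", "!=", "&", "|", "!", "pmax", "pmin")
  walk <- function(e) {
    if (is.name(e)) {
      if (!as.character(e) %in% ok_names)
        stop("symbol '", as.character(e), "' not allowed in theta expression")
    } else if (is.call(e)) {
      lapply(as.list(e), walk)
    } else if (!is.numeric(e) && !is.logical(e)) {
      stop("unsupported element in theta expression")
    }
    invisible(NULL)
  }
  walk(e)
}

#' Evaluate a theta function on integer counts
#'
#' @param th a [theta_fn()].
#' @param z integer vector of counts; negative entries evaluate to 0.
#' @return numeric vector of the same length.
#' @export
theta_eval <- function(th, z) {
  stopifnot(inherits(th, "theta_fn"))
  z <- round(z)
  out <- numeric(length(z))
  pos <- z >= 0
  if (!any(pos)) return(out)
  zp <- z[pos]
  val <- switch(th$type,
    table = {
      if (max(zp) + 1L > length(th$table))
        stop("theta table queried at z = ", max(zp),
             " beyond its last entry (z = ", length(th$table) - 1L,
             "); tables do not extrapolate")
      th$table[zp + 1L]
    },
    expr = eval(th$parsed, theta_expr_env(zp)),
    fun = th$fun(zp))
  if (length(val) == 1L) val <- rep(val, length(zp))
  out[pos] <- val
  out
}

#' @export
print.theta_fn <- function(x, ...) {
  rule <- switch(x$type,
                 expr = x$expr,
                 table = paste0("table[0..", length(x$table) - 1L, "]"),
                 fun = "<R function>")
  cat("theta_fn: alpha =", x$alpha, " rule:", rule, "\n")
  invisible(x)
}

#' Kinetics specification for a reaction network
#'
#' Three intensity families are supported. `mass_action_kinetics()` is the
#' stochastic mass-action rule
#' \eqn{\lambda_k(x) = \kappa_k \prod_i x_i!/(x_i-\nu_{ki})!}.
#' `theta_kinetics()` with `mode = "theta_product"` is the classical
#' generalization in which every falling-factorial factor \eqn{(x_i - j)}
#' is replaced by \eqn{\theta_i(x_i - j)}; with
#' `mode = "alpha_theta_product"` the factors are evaluated on the
#' alpha-strided lattice,
#' \eqn{\lambda_k(x) = \kappa_k \prod_i \prod_{j=0}^{\nu_{ki}/\alpha_i - 1}
#' \theta_i(x_i - j\alpha_i)}, which requires every source stoichiometry to
#' be divisible by \eqn{\alpha_i}. Empty products equal one.
#'
#' @param thetas named list of [theta_fn()], one per species that ever
#'   appears in a source complex (names are species names). Species absent
#'   from the list default to the identity theta \eqn{\theta(z) = z} with
#'   \eqn{\alpha = 1}.
#' @param mode `"theta_product"` or `"alpha_theta_product"`.
#' @return object of class `crn_kinetics`.
#' @export
theta_kinetics <- function(thetas, mode = c("alpha_theta_product", "theta_product")) {
  mode <- match.arg(mode)
  if (is.null(names(thetas)) || any(!nzchar(names(thetas))))
    stop("thetas must be a named list (names = species)")
  if (!all(vapply(thetas, inherits, logical(1), "theta_fn")))
    stop("every entry of thetas must be a theta_fn")
  if (mode == "theta_product" &&
      any(vapply(thetas, function(t) t$alpha, integer(1)) != 1L))
    stop("theta_product mode requires alpha = 1 for every theta")
  structure(list(mode = mode, thetas = thetas), class = "crn_kinetics")
}

#' @rdname theta_kinetics
#' @export
mass_action_kinetics <- function() {
  structure(list(mode = "mass_action", thetas = NULL), class = "crn_kinetics")
}

#' @export
print.crn_kinetics <- function(x, ...) {
  cat("Kinetics mode:", x$mode, "\n")
  if (!is.null(x$thetas))
    for (nm in names(x$thetas))
      cat("  theta[", nm, "]: alpha=", x$thetas[[nm]]$alpha, "\n", sep = "")
  invisible(x)
}

## Resolve per-species theta list and alpha vector for a kinetics spec
## against a network. Mass action corresponds to theta(z)=z, alpha=1.
resolve_thetas <- function(kin, net, ap = NULL) {
  d <- net$d
  if (kin$mode == "mass_action") {
    alpha <- rep(1L, d)
  } else if (kin$mode == "theta_product") {
    alpha <- rep(1L, d)
  } else {
    if (is.null(ap)) ap <- alpha_partition(net)
    alpha <- ap$alpha
  }
  thetas <- vector("list", d)
  for (i in seq_len(d)) {
    nm <- net$species[i]
    th <- if (!is.null(kin$thetas)) kin$thetas[[nm]] else NULL
    if (is.null(th)) {
      th <- theta_fn(fun = function(z) z, alpha = alpha[i])
    } else if (kin$mode == "alpha_theta_product" && th$alpha != alpha[i]) {
      stop("theta for species ", nm, " declares alpha = ", th$alpha,
           " but the network's alpha-partition gives ", alpha[i])
    }
    thetas[[i]] <- th
  }
  list(thetas = thetas, alpha = alpha)
}

#' Reaction intensities on a batch of states
#'
#' Evaluates all K reaction intensities on each row of a state matrix.
#' This is the vectorized workhorse behind the generator builder and the
#' simulation routines.
#'
#' @param kin a `crn_kinetics` object.
#' @param net a [crn_network()].
#' @param X integer matrix of states, one state per row (n x d). A single
#'   state may be given as a vector.
#' @param ap optional [alpha_partition()] (computed from `net` when needed).
#' @return n x K matrix of nonnegative intensities.
#' @export
intensities <- function(kin, net, X, ap = NULL) {
  stopifnot(inherits(kin, "crn_kinetics"), inherits(net, "crn_network"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$d) stop("states must have ", net$d, " columns")
  n <- nrow(X)
  lam <- matrix(rep(net$kappa, each = n), n, net$K)
  if (kin$mode == "mass_action") {
    for (k in seq_len(net$K)) {
      for (i in which(net$nu[k, ] > 0L)) {
        for (j in seq_len(net$nu[k, i]) - 1L) lam[, k] <- lam[, k] * (X[, i] - j)
      }
    }
    lam[lam < 0] <- 0   # states below the source complex contribute zero
    return(lam)
  }
  rt <- resolve_thetas(kin, net, ap)
  for (k in seq_len(net$K)) {
    for (i in which(net$nu[k, ] > 0L)) {
      a <- rt$alpha[i]
      if (net$nu[k, i] %% a != 0L)
        stop("source stoichiometry nu[", k, ",", i, "] = ", net$nu[k, i],
             " is not divisible by alpha_", i, " = ", a,
             " (Assumption 1 violated)")
      for (j in seq_len(net$nu[k, i] %/% a) - 1L)
        lam[, k] <- lam[, k] * theta_eval(rt$thetas[[i]], X[, i] - j * a)
    }
  }
  lam
}

#' Single intensity evaluations
#'
#' `mass_action_intensity()` and `theta_intensity()` evaluate one
#' reaction's rate at one state; they are thin wrappers over
#' [intensities()].
#'
#' @param net a [crn_network()].
#' @param k reaction index.
#' @param x state (nonnegative integer vector).
#' @param kin a `crn_kinetics`.
#' @param ap optional [alpha_partition()].
#' @return a single nonnegative number.
#' @export
mass_action_intensity <- function(net, k, x) {
  x <- stop_if_not_state(x, net$d)
  intensities(mass_action_kinetics(), net, matrix(x, 1L))[1L, k]
}

#' @rdname mass_action_intensity
#' @export
theta_intensity <- function(kin, net, ap, k, x) {
  x <- stop_if_not_state(x, net$d)
  intensities(kin, net, matrix(x, 1L), ap = ap)[1L, k]
}

#' Validate the admissibility assumption for theta-product kinetics
#'
#' Checks, on the finite working range `0..zmax`, the two conditions under
#' which the alpha-strided product-form stationary measure applies:
#' (i) every source stoichiometry is divisible by the species' alpha, and
#' (ii) \eqn{\theta_i(z) = 0} if and only if \eqn{z \le \alpha_i - 1}.
#' Theta rules can be black-box expressions, so positivity is certified on
#' the working range only; `zmax` should cover the truncation box used
#' downstream.
#'
#' @param kin a `crn_kinetics` (theta modes; mass action is reported valid
#'   with the identity thetas).
#' @param net a [crn_network()].
#' @param ap an [alpha_partition()]; defaults to `alpha_partition(net)`.
#' @param zmax upper end of the verified range (must be >= max alpha).
#' @return list with `valid` (logical) and `violations` (character vector
#'   describing each failure; empty when valid).
#' @export
validate_assumption1 <- function(kin, net, ap = NULL, zmax = 100L) {
  stopifnot(inherits(kin, "crn_kinetics"), inherits(net, "crn_network"))
  if (is.null(ap)) ap <- alpha_partition(net)
  zmax <- as.integer(zmax)
  if (zmax < max(ap$alpha)) stop("zmax must be at least max(alpha)")
  rt <- resolve_thetas(kin, net, ap)
  viol <- character(0)
  for (i in seq_len(net$d)) {
    a <- ap$alpha[i]
    bad <- which(net$nu[, i] %% a != 0L)
    for (k in bad)
      viol <- c(viol, sprintf(
        "reaction %s: source count %d of species %s not divisible by alpha=%d",
        net$labels[k], net$nu[k, i], net$species[i], a))
    th <- rt$thetas[[i]]
    vals <- theta_eval(th, 0:zmax)
    zero_range <- seq_len(a) - 1L
    nz <- zero_range[vals[zero_range + 1L] != 0]
    for (z in nz)
      viol <- c(viol, sprintf("theta[%s](%d) = %g but must be 0 for z <= alpha-1 = %d",
                              net$species[i], z, vals[z + 1L], a - 1L))
    pos_range <- a:zmax
    np <- pos_range[vals[pos_range + 1L] <= 0]
    for (z in np)
      viol <- c(viol, sprintf("theta[%s](%d) = %g but must be > 0 for z >= alpha = %d",
                              net$species[i], z, vals[z + 1L], a))
  }
  list(valid = length(viol) == 0L, violations = viol, zmax = zmax)
}
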