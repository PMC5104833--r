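#' Constructive factorization of a theta function
#'
#' Builds the auxiliary function \eqn{\varphi} that factors an admissible
#' theta function through a window of length alpha:
#' \deqn{\theta(z) = \varphi(z)\,\varphi(z-1)\cdots\varphi(z-\alpha+1),
#'   \quad z \ge \alpha.}
#' The construction sets \eqn{\varphi(0) = 0}, \eqn{\varphi(z) = C} for
#' \eqn{1 \le z \le \alpha - 1}, and for \eqn{z \ge \alpha} recursively
#' \deqn{\varphi(z) = \theta(z) / (\varphi(z-1)\cdots\varphi(z-\alpha+1)).}
#' With `C = 1` this is the reduction used to prove the alpha-strided
#' product-form theorem from the classical one. The free constant `C`
#' matters only for the alpha-mismatch construction (a reaction consuming a
#' scaled species with multiplicity not a multiple of alpha), where any
#' `C > 0` yields a valid, typically wildly oscillating, rate function.
#'
#' For `alpha = 1` the window is a single factor and \eqn{\varphi = \theta}.
#'
#' @param theta a [theta_fn()] satisfying the admissibility condition (the
#'   recursion divides by earlier phi values, which are positive exactly
#'   when theta is admissible).
#' @param zmax tabulate phi on `0..zmax`.
#' @param C positive free constant (default 1).
#' @return object of class `phi_fn` with fields `values` (`phi(0..zmax)`),
#'   `alpha`, `C`.
#' @export
phi_from_theta <- function(theta, zmax, C = 1) {
  stopifnot(inherits(theta, "theta_fn"))
  zmax <- as.integer(zmax)
  a <- theta$alpha
  if (zmax < a) stop("zmax must be at least alpha")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be positive")
  th <- theta_eval(theta, 0:zmax)
  phi <- numeric(zmax + 1L)        # phi[z + 1] = phi(z)
  phi[1L] <- 0
  if (a >= 2L) phi[seq(2L, a)] <- C
  if (a == 1L) {
    phi <- th
  } else {
    for (z in a:zmax) {
      window <- phi[(z - 1L):(z - a + 1L) + 1L]
      if (any(window == 0))
        stop("phi recursion hit a zero divisor at z = ", z,
             "; theta violates the admissibility condition")
      phi[z + 1L] <- th[z + 1L] / prod(window)
    }
  }
  structure(list(values = phi, alpha = a, C = C, zmax = zmax),
            class = "phi_fn")
}

#' @export
print.phi_fn <- function(x, ...) {
  cat("phi_fn: alpha =", x$alpha, " C =", x$C,
      " tabulated on 0..", x$zmax, "\n", sep = "")
  invisible(x)
}

#' Evaluate a tabulated phi function
#' @param phi a `phi_fn`.
#' @param z integer vector (0..zmax; negatives evaluate to 0).
#' @return numeric vector.
#' @export
phi_eval <- function(phi, z) {
  z <- round(z)
  out <- numeric(length(z))
  ok <- z >= 0
  if (any(z[ok] > phi$zmax))
    stop("phi queried beyond its tabulated range 0..", phi$zmax)
  out[ok] <- phi$values[z[ok] + 1L]
  out
}

#' Rebuild theta from phi by windowed products
#'
#' The involution target of the construction: multiplying phi over a length
#' alpha window must reproduce theta at every `z >= alpha`.
#'
#' @param phi a `phi_fn`.
#' @param z integer vector with `z >= alpha`.
#' @return numeric vector `theta(z)`.
#' @export
theta_from_phi <- function(phi, z) {
  vapply(round(z), function(zz) {
    prod(phi_eval(phi, zz - (0:(phi$alpha - 1L))))
  }, numeric(1))
}

#' Check the telescoping factorization identity
#'
#' Verifies, for all `z <= zmax`, that the full product of phi down to 1
#' telescopes to the alpha-strided product of theta:
#' \deqn{\prod_{j=0}^{z-1} \varphi(z-j)
#'   = \prod_{j=0}^{\lfloor z/\alpha\rfloor - 1} \theta(z - j\alpha).}
#' This identity is what transports the classical product-form measure to
#' the alpha-strided one. Both sides are accumulated in log space.
#'
#' @param theta a [theta_fn()].
#' @param phi the matching `phi_fn` (from [phi_from_theta()]).
#' @param zmax check `z = 0..zmax`.
#' @return the maximum absolute relative discrepancy over the range.
#' @export
factorization_check <- function(theta, phi, zmax = phi$zmax) {
  zmax <- as.integer(zmax)
  if (zmax > phi$zmax) stop("zmax exceeds the phi tabulation")
  a <- theta$alpha
  worst <- 0
  lphi <- c(0, cumsum(log(phi$values[seq(2L, zmax + 1L)])))  # sum log phi(1..z)
  for (z in 0:zmax) {
    lhs <- lphi[z + 1L]
    m <- z %/% a
    rhs <- if (m == 0L) 0 else sum(log(theta_eval(theta, z - (0:(m - 1L)) * a)))
    denom <- max(abs(rhs), 1e-12)
    worst <- max(worst, abs(lhs - rhs) / denom, abs(expm1(lhs - rhs)))
  }
  worst
}
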