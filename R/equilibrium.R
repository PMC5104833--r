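#' Deterministic mass-action right-hand side
#'
#' \eqn{\dot x = \sum_k r_k(x) (\nu_k' - \nu_k)} with
#' \eqn{r_k(x) = \kappa_k \prod_i x_i^{\nu_{ki}}}.
#'
#' @param net a [crn_network()].
#' @param x positive concentration vector (length d).
#' @return length-d numeric vector.
#' @export
deterministic_rhs <- function(net, x) {
  stopifnot(inherits(net, "crn_network"), length(x) == net$d)
  r <- mass_action_rates(net, x)
  as.numeric(crossprod(net$nu_prime - net$nu, r))
}

## r_k(x) = kappa_k prod_i x_i^{nu_ki}; x > 0 componentwise expected.
mass_action_rates <- function(net, x) {
  lx <- log(x)
  as.numeric(net$kappa * exp(net$nu %*% lx))
}

#' Complex-balance residuals
#'
#' For each distinct complex \eqn{\eta}, the inflow/outflow mismatch
#' \eqn{\sum_{k: \nu_k = \eta} r_k(c) - \sum_{k: \nu_k' = \eta} r_k(c)}
#' under deterministic mass action. A positive vector `c` is a
#' complex-balanced equilibrium exactly when all residuals vanish; complex
#' balance implies that `c` is a fixed point of [deterministic_rhs()].
#'
#' @param net a [crn_network()].
#' @param c positive concentration vector.
#' @param structure optional precomputed [crn_structure()].
#' @return numeric vector of residuals, one per distinct complex (named by
#'   a compact rendering of the complex).
#' @export
complex_balance_residual <- function(net, c, structure = NULL) {
  stopifnot(inherits(net, "crn_network"), length(c) == net$d, all(c > 0))
  st <- structure %||% crn_structure(net)
  r <- mass_action_rates(net, c)
  res <- numeric(st$n)
  out_idx <- sort(unique(st$source_index))
  in_idx <- sort(unique(st$product_index))
  res[out_idx] <- res[out_idx] + as.numeric(rowsum(r, st$source_index))
  res[in_idx] <- res[in_idx] - as.numeric(rowsum(r, st$product_index))
  names(res) <- apply(st$complexes, 1L, function(row) {
    nz <- which(row > 0)
    if (!length(nz)) return("0")
    paste(ifelse(row[nz] > 1, paste0(row[nz], net$species[nz]), net$species[nz]),
          collapse = "+")
  })
  res
}

#' Solve for a complex-balanced equilibrium
#'
#' Finds a positive concentration vector with vanishing complex-balance
#' residuals, optionally restricted to an affine constraint
#' \eqn{w \cdot c = b} (the natural normalization when the equilibrium set
#' is a ray along a conservation relation). The solve runs in
#' log-concentration coordinates \eqn{c = e^u} — positivity is then free —
#' using damped Gauss–Newton on the stacked residual (complex-balance
#' residuals plus constraint), starting from \eqn{c = 1}.
#'
#' For weakly reversible deficiency-zero networks a complex-balanced
#' equilibrium exists for every choice of rate constants and is unique per
#' positive compatibility class; for other networks the solve is attempted
#' and failure reported. The stopping rule is scale-free: max-norm residual
#' below `tol * (1 + max complex throughput)`.
#'
#' @param net a [crn_network()].
#' @param constraint optional: either a string like `"S1+2*S2=1"` or a list
#'   `list(w = <numeric length d>, b = <value>)`.
#' @param tol relative tolerance of the stopping rule.
#' @param max_iter iteration cap.
#' @return object of class `crn_equilibrium`: list with `c`, `residuals`,
#'   `rhs_norm`, `constraint`, `converged`, `iterations`, `tol_used`.
#'   Non-convergence raises an error carrying the best iterate in
#'   `attr(, "best")`; a non-weakly-reversible network attaches a warning.
#' @export
solve_complex_balanced <- function(net, constraint = NULL, tol = 1e-10,
                                   max_iter = 200L) {
  stopifnot(inherits(net, "crn_network"))
  st <- crn_structure(net)
  if (!st$weakly_reversible)
    warning("network is not weakly reversible; a complex-balanced ",
            "equilibrium may not exist")
  cons <- NULL
  if (!is.null(constraint)) {
    if (is.character(constraint)) {
      pf <- parse_linear_functional(constraint, net$species)
      if (!is.na(pf$modulus)) stop("equilibrium constraints must be affine, not residue")
      cons <- list(w = as.numeric(pf$w), b = as.numeric(pf$value))
    } else {
      cons <- list(w = as.numeric(constraint$w), b = as.numeric(constraint$b))
    }
    if (length(cons$w) != net$d) stop("constraint vector has wrong length")
  }

  ## Relative per-complex balance: (out - in) / (out + in). The absolute
  ## residuals vanish along the degenerate boundary direction c -> 0 (all
  ## rates die together), which traps a naive least-squares iteration;
  ## the relative form tends to +-1 there and repels it, while the true
  ## equilibrium is its exact zero. Both sums are positive for c > 0.
  ## Positive equilibria of a complex-balanced system form the manifold
  ## ln c in ln c* + span(conservation laws); an unconstrained Newton
  ## iteration slides freely along it (possibly to extreme scales), so
  ## unconstrained solves are anchored at w . ln c = 0 per conservation
  ## law, the canonical representative reached from c = 1.
  anchors <- if (is.null(cons) && nrow(st$conservation_laws) > 0)
    st$conservation_laws else matrix(numeric(0), 0L, net$d)
  n_extra <- (!is.null(cons)) + nrow(anchors)
  resid_fun <- function(u) {
    c_ <- exp(u)
    r <- mass_action_rates(net, c_)
    out_ <- numeric(st$n); in_ <- numeric(st$n)
    oi <- sort(unique(st$source_index)); ii <- sort(unique(st$product_index))
    out_[oi] <- as.numeric(rowsum(r, st$source_index))
    in_[ii] <- as.numeric(rowsum(r, st$product_index))
    res <- (out_ - in_) / (out_ + in_)
    res[out_ + in_ == 0] <- 0      # isolated complex (cannot occur for c > 0)
    if (!is.null(cons))
      res <- c(res, (sum(cons$w * c_) - cons$b) / (abs(cons$b) + 1))
    if (nrow(anchors) > 0)
      res <- c(res, as.numeric(anchors %*% u) / rowSums(abs(anchors)))
    res
  }
  jac_num <- function(u, r0) {
    ## forward-difference Jacobian; d is tiny so this is cheap and avoids
    ## hand-differentiating the rescaled residual
    h <- 1e-7
    vapply(seq_len(net$d), function(j) {
      uj <- u; uj[j] <- uj[j] + h
      (resid_fun(uj) - r0) / h
    }, numeric(st$n + n_extra))
  }

  throughput <- function(c_) {
    r <- mass_action_rates(net, c_)
    max(as.numeric(rowsum(r, st$source_index)))
  }
  abs_ok <- function(c_) {
    tol_eff <- tol * (1 + throughput(c_))
    res_abs <- complex_balance_residual(net, c_, structure = st)
    if (!is.null(cons))
      ok_cons <- abs(sum(cons$w * c_) - cons$b) <= tol * (abs(cons$b) + 1)
    else ok_cons <- TRUE
    max(abs(res_abs)) <= tol_eff && ok_cons
  }

  u <- numeric(net$d)
  res <- resid_fun(u)
  best <- list(u = u, norm = max(abs(res)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## convergence is judged on the relative residuals only: the absolute
    ## criterion is trivially satisfied near the degenerate boundary
    if (max(abs(res)) <= 1e-12) { converged <- TRUE; break }
    J <- jac_num(u, res)
    step <- tryCatch(qr.solve(J, -res, tol = 1e-13),
                     error = function(e) {
                       H <- crossprod(J)
                       ridge <- 1e-8 * max(diag(H), 1)
                       as.numeric(solve(H + ridge * diag(net$d),
                                        -crossprod(J, res)))
                     })
    ## trust-region-ish cap plus damped line search on the residual norm
    step <- step * min(1, 5 / max(abs(step)))
    lambda <- 1
    f0 <- sum(res^2)
    repeat {
      u_new <- u + lambda * step
      res_new <- resid_fun(u_new)
      if (sum(res_new^2) < f0 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    u <- u_new
    res <- res_new
    if (max(abs(res)) < best$norm) best <- list(u = u, norm = max(abs(res)))
  }
  c_ <- exp(u)
  tol_eff <- tol * (1 + throughput(c_))
  if (!converged && !abs_ok(c_)) {
    err <- simpleError(paste0(
      "complex-balance solve did not converge: best max residual ",
      format(best$norm), " (tolerance ", format(tol_eff), ")"))
    attr(err, "best") <- list(c = exp(best$u), residual = best$norm)
    stop(err)
  }
  cb <- complex_balance_residual(net, c_, structure = st)
  structure(list(c = stats::setNames(c_, net$species), residuals = cb,
                 rhs_norm = max(abs(deterministic_rhs(net, c_))),
                 constraint = cons, converged = TRUE, iterations = it,
                 tol_used = tol_eff),
            class = "crn_equilibrium")
}

#' @export
print.crn_equilibrium <- function(x, ...) {
  cat("Complex-balanced equilibrium:\n")
  print(signif(x$c, 8))
  cat("  max |complex-balance residual| =", format(max(abs(x$residuals))), "\n")
  cat("  |deterministic RHS|_inf        =", format(x$rhs_norm), "\n")
  if (!is.null(x$constraint))
    cat("  constraint w.c = b satisfied to ",
        format(abs(sum(x$constraint$w * x$c) - x$constraint$b)), "\n")
  invisible(x)
}
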