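#' Build the truncated CTMC generator on a state class
#'
#' Assembles the sparse generator matrix `A` of the chain restricted to the
#' enumerated states of a class: `A[x, x + nu' - nu] = lambda_k(x)` for
#' every reaction whose target stays in the set, diagonal entries equal to
#' minus the row sums. Transitions leaving the set are dropped
#' (reflecting-by-dropping truncation); the induced error is monitored
#' downstream through boundary mass, not corrected.
#'
#' @param net a [crn_network()].
#' @param kin a `crn_kinetics`.
#' @param cls a [state_class()].
#' @param ap optional [alpha_partition()].
#' @return object of class `truncated_chain`: list with `states` (n x d),
#'   `A` (n x n `dgCMatrix`), `keys`, `cls`, `net`, `kin`.
#' @export
build_generator <- function(net, kin, cls, ap = NULL) {
  stopifnot(inherits(net, "crn_network"), inherits(cls, "state_class"))
  X <- enumerate_class(cls)
  n <- nrow(X)
  if (n == 0L) stop("state class is empty")
  keys <- class_state_keys(X, cls$box)
  lam <- intensities(kin, net, X, ap = ap)
  zeta <- net$nu_prime - net$nu
  ii <- vector("list", net$K); jj <- ii; vv <- ii
  for (k in seq_len(net$K)) {
    Y <- sweep(X, 2L, zeta[k, ], `+`)
    inside <- rowSums(Y < 0) == 0 & rowSums(t(t(Y) > cls$box)) == 0
    tgt <- rep(NA_integer_, n)
    tgt[inside] <- match(encode_states(Y[inside, , drop = FALSE], cls$box), keys)
    ok <- !is.na(tgt) & lam[, k] > 0
    ii[[k]] <- which(ok); jj[[k]] <- tgt[ok]; vv[[k]] <- lam[ok, k]
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, n))
  Matrix::diag(A) <- Matrix::diag(A) - Matrix::rowSums(A)
  structure(list(states = X, A = A, keys = keys, cls = cls, net = net,
                 kin = kin, ap = ap),
            class = "truncated_chain")
}

#' @export
print.truncated_chain <- function(x, ...) {
  cat("Truncated CTMC generator:", nrow(x$states), "states,",
      length(x$A@x), "stored entries\n")
  invisible(x)
}

#' Stationary distribution of a truncated chain
#'
#' Solves `pi A = 0`, `sum(pi) = 1` by sparse LU on the adjoint: one
#' balance equation is replaced by the unit equation `pi[anchor] = 1` (a
#' sparse row — a dense normalization row would destroy the factor's
#' sparsity), the system is solved directly, and the solution renormalized.
#' The anchor defaults to an approximate mode found by a few uniformized
#' power steps, which keeps the unnormalized solve well scaled.
#'
#' A uniqueness check (every state reaches the anchor, which implies a
#' single closed communicating class) runs by default on chains up to
#' `check_limit` states; beyond that the residual check below is the
#' safeguard. The returned residual is `max |pi A| / max |diag(A)|` and
#' must not exceed `tol`.
#'
#' @param chain a [build_generator()] result.
#' @param anchor state index, or `"auto"`.
#' @param tol residual tolerance (relative to the largest exit rate).
#' @param check_limit run the explicit closed-class check when `n <=
#'   check_limit`.
#' @return a `state_distribution` with `meta$residual`, `meta$anchor`,
#'   `meta$method`.
#' @export
solve_stationary <- function(chain, anchor = "auto", tol = 1e-10,
                             check_limit = 20000L) {
  stopifnot(inherits(chain, "truncated_chain"))
  A <- chain$A
  n <- nrow(A)
  if (identical(anchor, "auto")) anchor <- guess_anchor(A)
  anchor <- as.integer(anchor)
  if (n <= check_limit && !all_states_reach(A, anchor))
    stop("multiple closed communicating classes detected (not every state ",
         "reaches the anchor); restrict the state class, e.g. by fixing a ",
         "conserved quantity or a residue class")
  M <- Matrix::t(A)
  T3 <- as(as(M, "TsparseMatrix"), "generalMatrix")
  solve_with_anchor <- function(anchor) {
    keep <- T3@i != (anchor - 1L)
    M2 <- Matrix::sparseMatrix(i = c(T3@i[keep] + 1L, anchor),
                               j = c(T3@j[keep] + 1L, anchor),
                               x = c(T3@x[keep], 1), dims = c(n, n))
    b <- numeric(n); b[anchor] <- 1
    pi_raw <- tryCatch(as.numeric(Matrix::solve(M2, b)),
                       error = function(e) rep(NA_real_, n))
    pi_raw
  }
  dmax <- max(abs(Matrix::diag(A)))
  neg <- 0
  prob <- NULL
  resid <- Inf
  ## a poor anchor (e.g. deep in a tail) can make the unnormalized direct
  ## solve ill-scaled; retry from the argmax of the previous attempt and
  ## a couple of deterministic fallbacks before giving up
  tried <- integer(0)
  candidates <- c(anchor, NA_integer_, 1L, max(1L, n %/% 2L))
  ci <- 1L
  while (ci <= length(candidates)) {
    anchor <- candidates[ci]
    ci <- ci + 1L
    if (is.na(anchor) || anchor %in% tried) next
    tried <- c(tried, anchor)
    pi_raw <- solve_with_anchor(anchor)
    if (!anyNA(pi_raw)) {
      neg <- min(pi_raw)
      pi_raw[pi_raw < 0] <- 0
      if (sum(pi_raw) > 0) {
        prob_try <- pi_raw / sum(pi_raw)
        resid_try <- max(abs(as.numeric(prob_try %*% A))) / dmax
        if (resid_try < resid) { prob <- prob_try; resid <- resid_try }
        if (resid <= tol) break
        candidates[2L] <- which.max(prob_try)  # re-anchor at the apparent mode
        if (ci > 2L) candidates <- c(candidates, which.max(prob_try))
      }
    }
  }
  anchor <- tried[length(tried)]
  if (is.null(prob) || resid > tol)
    stop("stationary solve residual ", format(resid), " exceeds tolerance ",
         format(tol), "; the chain may have multiple closed classes ",
         "within the truncated set")
  state_distribution(chain$states, prob,
                     boundary_mass = boundary_shell_mass(chain$states, prob,
                                                         chain$cls),
                     class_ = chain$cls,
                     meta = list(residual = resid, anchor = anchor,
                                 min_raw = neg, method = "sparse-LU"))
}

## Approximate the mode of the stationary distribution with a few
## uniformized power steps; cheap, deterministic, and good enough to keep
## the unnormalized direct solve away from overflow.
guess_anchor <- function(A, steps = 50L) {
  n <- nrow(A)
  lam_u <- max(abs(Matrix::diag(A))) * 1.05
  v <- rep(1 / n, n)
  for (s in seq_len(steps)) {
    v <- v + as.numeric(v %*% A) / lam_u
    v[v < 0] <- 0
    sv <- sum(v)
    if (sv <= 0) return(1L)
    v <- v / sv
  }
  which.max(v)
}

## TRUE iff every state has a path to `anchor` inside the truncated set
## (boolean frontier propagation on the adjacency pattern).
all_states_reach <- function(A, anchor) {
  n <- nrow(A)
  Adj <- A
  Matrix::diag(Adj) <- 0
  Adj <- Adj != 0
  reached <- logical(n)
  reached[anchor] <- TRUE
  repeat {
    grow <- as.logical(Adj %*% reached) & !reached
    if (!any(grow)) break
    reached <- reached | grow
  }
  all(reached)
}

#' Pointwise stationarity residual of a distribution
#'
#' Evaluates, at every interior state x, the master-equation balance
#' \deqn{\sum_k \lambda_k(x - \zeta_k)\,\pi(x - \zeta_k)
#'   - \sum_k \lambda_k(x)\,\pi(x), \qquad \zeta_k = \nu_k' - \nu_k,}
#' which must vanish for a stationary distribution. Interior states are
#' those whose full in/out neighborhoods lie inside the enumerated set
#' (transitions with zero intensity do not disqualify); boundary states of
#' a truncated box are excluded because the truncated solve distorts their
#' balance by construction.
#'
#' @param dist a `state_distribution` (its `states` define the set).
#' @param net a [crn_network()].
#' @param kin a `crn_kinetics`.
#' @param ap optional [alpha_partition()].
#' @param box box used for state keys; defaults to the class stored in
#'   `dist` or per-coordinate maxima.
#' @return list with `max_abs` (largest absolute residual), `max_scaled`
#'   (the same normalized by the largest exit rate, the convention used
#'   for generator residuals), `max_rel` (residual relative to the
#'   state's own probability flux), and `n_interior`.
#' @export
stationarity_residual <- function(dist, net, kin, ap = NULL, box = NULL) {
  stopifnot(inherits(dist, "state_distribution"))
  X <- dist$states
  n <- nrow(X)
  prob <- dist$prob
  if (is.null(box)) box <- dist$class$box %||% apply(X, 2L, max)
  keys <- encode_states(X, box)
  lam <- intensities(kin, net, X, ap = ap)
  zeta <- net$nu_prime - net$nu
  outflow <- rowSums(lam)
  net_flux <- -outflow * prob
  flux_scale <- outflow * prob
  interior <- rep(TRUE, n)
  for (k in seq_len(net$K)) {
    ## outgoing edge must stay in the set unless the rate vanishes
    Y <- sweep(X, 2L, zeta[k, ], `+`)
    y_in_box <- rowSums(Y < 0) == 0 & rowSums(t(t(Y) > box)) == 0
    tgt <- rep(NA_integer_, n)
    tgt[y_in_box] <- match(encode_states(Y[y_in_box, , drop = FALSE], box), keys)
    interior <- interior & (!is.na(tgt) | lam[, k] == 0)
    ## incoming edge from x - zeta_k
    W <- sweep(X, 2L, zeta[k, ], `-`)
    w_nonneg <- rowSums(W < 0) == 0
    w_in_box <- w_nonneg & rowSums(t(t(W) > box)) == 0
    src <- rep(NA_integer_, n)
    src[w_in_box] <- match(encode_states(W[w_in_box, , drop = FALSE], box), keys)
    lam_src <- numeric(n)
    has_src <- !is.na(src)
    if (any(has_src)) {
      lam_src[has_src] <- lam[src[has_src], k]
      net_flux[has_src] <- net_flux[has_src] + lam_src[has_src] * prob[src[has_src]]
      flux_scale[has_src] <- flux_scale[has_src] +
        lam_src[has_src] * prob[src[has_src]]
    }
    ## a nonnegative in-state missing from the set breaks the balance
    interior <- interior & (!w_nonneg | has_src)
  }
  use <- interior & prob > 0
  if (!any(use)) stop("no interior state with positive probability")
  r <- abs(net_flux[use])
  list(max_abs = max(r),
       ## scaled as generator residuals are: relative to the largest exit rate
       max_scaled = max(r) / max(outflow),
       max_rel = max(r / pmax(flux_scale[use], 1e-300)),
       n_interior = sum(use))
}

#' Distance between two distributions on a common support
#'
#' `relative_l2` is \eqn{\lVert p-q\rVert_2 / \lVert q\rVert_2} with `q`
#' the reference; `total_variation` is \eqn{\tfrac12\sum_x |p(x)-q(x)|}.
#'
#' @param p,q `state_distribution`s on identical state sets, or plain
#'   probability vectors of equal length.
#' @param mode `"relative_l2"` or `"total_variation"`.
#' @return a nonnegative number.
#' @export
distribution_distance <- function(p, q, mode = c("relative_l2", "total_variation")) {
  mode <- match.arg(mode)
  if (inherits(p, "state_distribution") || inherits(q, "state_distribution")) {
    stopifnot(inherits(p, "state_distribution"), inherits(q, "state_distribution"))
    if (!identical(dim(p$states), dim(q$states)) ||
        any(p$states != q$states))
      stop("distributions live on different enumerated supports")
    pv <- p$prob; qv <- q$prob
  } else {
    if (length(p) != length(q)) stop("support mismatch")
    pv <- as.numeric(p); qv <- as.numeric(q)
  }
  switch(mode,
         relative_l2 = sqrt(sum((pv - qv)^2)) / sqrt(sum(qv^2)),
         total_variation = 0.5 * sum(abs(pv - qv)))
}
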