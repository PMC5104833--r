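#' Stochastic simulation (Gillespie direct method)
#'
#' Simulates an exact-jump trajectory of the CTMC and returns the
#' time-weighted occupancy measure of the visited states, optionally split
#' into equal-length batches (batch means give Monte-Carlo standard errors
#' for occupancy fractions). The direct method draws an exponential
#' holding time at the total rate and picks the reaction proportionally to
#' its intensity; random numbers are consumed in fixed order, so a seed
#' reproduces the trajectory exactly.
#'
#' @param net a [crn_network()].
#' @param kin a `crn_kinetics`.
#' @param x0 initial state.
#' @param t_end simulation horizon.
#' @param seed integer seed (the RNG state is restored on exit).
#' @param ap optional [alpha_partition()].
#' @param n_batches number of equal time batches for occupancy.
#' @param record_trajectory keep the full jump sequence (memory-heavy).
#' @param max_jumps abort guard.
#' @return object of class `ssa_result`: `occupancy` (a
#'   `state_distribution` over visited states), `batch_occupancy` (matrix
#'   states x batches of occupancy fractions), `n_jumps`, `t_end`, `seed`,
#'   and optionally `trajectory` (times, states).
#' @export
ssa_simulate <- function(net, kin, x0, t_end, seed, ap = NULL,
                         n_batches = 1L, record_trajectory = FALSE,
                         max_jumps = 1e7) {
  stopifnot(inherits(net, "crn_network"), t_end > 0)
  x <- stop_if_not_state(x0, net$d)
  rate_fun <- build_rate_fun(net, kin, ap)
  zeta <- net$nu_prime - net$nu
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  batch_len <- t_end / n_batches
  occ <- new.env(parent = emptyenv(), hash = TRUE)
  add_time <- function(state, t0, t1) {
    ## split the dwell interval across batch boundaries
    key <- paste(state, collapse = ",")
    slot <- occ[[key]]
    if (is.null(slot)) slot <- numeric(n_batches)
    b0 <- min(floor(t0 / batch_len), n_batches - 1)
    b1 <- min(floor(t1 / batch_len), n_batches - 1)
    if (b0 == b1) {
      slot[b0 + 1] <- slot[b0 + 1] + (t1 - t0)
    } else {
      for (b in b0:b1) {
        lo <- max(t0, b * batch_len)
        hi <- min(t1, (b + 1) * batch_len)
        if (hi > lo) slot[b + 1] <- slot[b + 1] + hi - lo
      }
    }
    occ[[key]] <- slot
  }

  t_now <- 0
  n_jumps <- 0L
  traj_t <- if (record_trajectory) numeric(1024L) else NULL
  traj_x <- if (record_trajectory) matrix(0L, 1024L, net$d) else NULL
  if (record_trajectory) { traj_t[1L] <- 0; traj_x[1L, ] <- x }
  blk <- 4096L
  u_exp <- stats::rexp(blk); u_pick <- stats::runif(blk); ui <- 0L
  repeat {
    lam <- rate_fun(x)
    lam0 <- sum(lam)
    if (!is.finite(lam0)) stop("propensity overflow at state (",
                               paste(x, collapse = ","), ")")
    if (lam0 <= 0) { add_time(x, t_now, t_end); break }   # absorbed
    ui <- ui + 1L
    if (ui > blk) { u_exp <- stats::rexp(blk); u_pick <- stats::runif(blk); ui <- 1L }
    tau <- u_exp[ui] / lam0
    if (t_now + tau >= t_end) { add_time(x, t_now, t_end); break }
    add_time(x, t_now, t_now + tau)
    t_now <- t_now + tau
    k <- findInterval(u_pick[ui] * lam0, cumsum(lam)) + 1L
    if (k > net$K) k <- net$K
    x <- x + zeta[k, ]
    n_jumps <- n_jumps + 1L
    if (n_jumps >= max_jumps) stop("max_jumps reached at t = ", t_now)
    if (record_trajectory) {
      if (n_jumps + 1L > length(traj_t)) {
        traj_t <- c(traj_t, numeric(length(traj_t)))
        traj_x <- rbind(traj_x, matrix(0L, nrow(traj_x), net$d))
      }
      traj_t[n_jumps + 1L] <- t_now
      traj_x[n_jumps + 1L, ] <- x
    }
  }

  keys <- ls(occ)
  S <- do.call(rbind, lapply(strsplit(keys, ",", fixed = TRUE), as.integer))
  B <- do.call(rbind, lapply(keys, function(k) occ[[k]]))
  o <- do.call(order, as.data.frame(S))
  S <- S[o, , drop = FALSE]; B <- B[o, , drop = FALSE]
  colnames(S) <- net$species
  total <- rowSums(B)
  occupancy <- state_distribution(S, total / sum(total),
                                  meta = list(seed = seed, t_end = t_end,
                                              n_jumps = n_jumps,
                                              method = "ssa-direct"))
  out <- list(occupancy = occupancy,
              batch_occupancy = sweep(B, 2L, colSums(B), `/`),
              n_jumps = n_jumps, t_end = t_end, seed = seed)
  if (record_trajectory)
    out$trajectory <- list(time = traj_t[seq_len(n_jumps + 1L)],
                           states = traj_x[seq_len(n_jumps + 1L), , drop = FALSE])
  class(out) <- "ssa_result"
  out
}

#' @export
print.ssa_result <- function(x, ...) {
  cat("SSA run:", x$n_jumps, "jumps to t =", x$t_end,
      "(seed", x$seed, ");", nrow(x$occupancy$states), "states visited\n")
  invisible(x)
}

## Low-overhead per-state rate evaluator used in the jump loop: the
## reaction structure is unpacked once so each call is a handful of scalar
## operations per reaction.
build_rate_fun <- function(net, kin, ap = NULL) {
  K <- net$K
  if (kin$mode == "mass_action") {
    nu <- net$nu; kap <- net$kappa
    return(function(x) {
      lam <- kap
      for (k in seq_len(K)) {
        for (i in which(nu[k, ] > 0L)) {
          v <- nu[k, i]
          xi <- x[i]
          if (xi < v) { lam[k] <- 0; break }
          lam[k] <- lam[k] * prod(xi - 0:(v - 1L))
        }
      }
      lam
    })
  }
  rt <- resolve_thetas(kin, net, ap)
  nu <- net$nu; kap <- net$kappa; alpha <- rt$alpha; thetas <- rt$thetas
  function(x) {
    lam <- kap
    for (k in seq_len(K)) {
      for (i in which(nu[k, ] > 0L)) {
        a <- alpha[i]
        for (j in seq_len(nu[k, i] %/% a) - 1L) {
          f <- theta_eval(thetas[[i]], x[i] - j * a)
          if (f == 0) { lam[k] <- 0; break }
          lam[k] <- lam[k] * f
        }
        if (lam[k] == 0) break
      }
    }
    lam
  }
}
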