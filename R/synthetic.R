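#' Random admissible theta function
#'
#' Draws a tabulated theta with the exact admissibility pattern: zero on
#' `0..alpha-1`, strictly positive (log-uniform on `[1e-2, 1e2]`) from
#' `alpha` on. Used for property-based testing of the factorization
#' machinery and the product-form theorem on randomized kinetics.
#'
#' @param alpha positive integer stride.
#' @param zmax last tabulated count.
#' @param seed integer seed (RNG state restored on exit).
#' @return a [theta_fn()].
#' @export
random_theta <- function(alpha, zmax, seed) {
  alpha <- as.integer(alpha)
  zmax <- as.integer(zmax)
  stopifnot(alpha >= 1L, zmax >= alpha)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  tab <- c(rep(0, alpha), 10^stats::runif(zmax - alpha + 1L, -2, 2))
  theta_fn(table = tab, alpha = alpha)
}

#' Random weakly reversible deficiency-zero network
#'
#' Generates a single directed cycle through `m <= d + 1` distinct random
#' complexes (entries 0..4, kept small so brute-force oracles stay
#' feasible), which is strongly connected by construction, and accepts it
#' only if the structural report certifies deficiency zero (the cycle's
#' reaction vectors must have rank `m - 1`). Such networks admit a
#' complex-balanced equilibrium for every choice of rate constants, which
#' makes them the natural randomized test bed for the product-form
#' theorem.
#'
#' @param d number of species.
#' @param seed integer seed.
#' @param max_retries rejection-sampling cap.
#' @param alpha_pool candidate per-species strides used to bias source
#'   counts toward nontrivial alpha-partitions.
#' @return a [crn_network()] with `deficiency == 0` and
#'   `weakly_reversible == TRUE`.
#' @export
random_complex_balanced_network <- function(d, seed, max_retries = 200L,
                                            alpha_pool = c(1L, 2L, 3L)) {
  d <- as.integer(d)
  stopifnot(d >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  for (try in seq_len(max_retries)) {
    m <- sample(2:(d + 1L), 1L)
    stride <- sample(alpha_pool, d, replace = TRUE)
    cx <- matrix(0L, m, d)
    for (r in seq_len(m))
      cx[r, ] <- stride * sample(0:1, d, replace = TRUE) *
        sample(1:2, d, replace = TRUE)
    if (anyDuplicated(apply(cx, 1L, paste, collapse = ","))) next
    reactions <- lapply(seq_len(m), function(r) {
      nxt <- if (r == m) 1L else r + 1L
      list(reactants = stats::setNames(cx[r, ], paste0("X", seq_len(d)))[cx[r, ] > 0],
           products = stats::setNames(cx[nxt, ], paste0("X", seq_len(d)))[cx[nxt, ] > 0],
           rate_constant = 10^stats::runif(1L, -0.5, 0.5))
    })
    net <- tryCatch(crn_network(paste0("X", seq_len(d)), reactions),
                    error = function(e) NULL)
    if (is.null(net)) next
    st <- crn_structure(net)
    if (st$deficiency == 0L && st$weakly_reversible) return(net)
  }
  stop("failed to generate a deficiency-zero cycle in ", max_retries, " tries")
}

#' Random theta kinetics matched to a network's alpha-partition
#'
#' Convenience wrapper: draws one [random_theta()] per species with the
#' stride dictated by the network's alpha-partition.
#'
#' @param net a [crn_network()].
#' @param zmax table range.
#' @param seed integer seed (per-species seeds are derived from it).
#' @return a `crn_kinetics` in alpha-strided mode.
#' @export
random_theta_kinetics <- function(net, zmax, seed) {
  ap <- alpha_partition(net)
  thetas <- lapply(seq_len(net$d), function(i)
    random_theta(ap$alpha[i], zmax, seed = as.integer(seed) * 131L + i))
  names(thetas) <- net$species
  theta_kinetics(thetas, mode = "alpha_theta_product")
}
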