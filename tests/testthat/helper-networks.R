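# Shared fixtures built in code.

params21 <- c(k1 = 1, k2 = 100, k3 = 1500, k4 = 30)
params28 <- c(k1 = 1, k2 = 100, k3 = 10, k4 = 1)

reversible_dimer <- function(kf = 1, kr = 1) {
  crn_network(c("S1", "S2"), list(
    list(reactants = c(S1 = 2), products = c(S2 = 1), rate_constant = kf),
    list(reactants = c(S2 = 1), products = c(S1 = 2), rate_constant = kr)))
}

birth_death <- function(lambda = 5, mu = 1) {
  crn_network("S", list(
    list(reactants = integer(0), products = c(S = 1), rate_constant = lambda),
    list(reactants = c(S = 1), products = integer(0), rate_constant = mu)))
}

## three independent birth-death pairs: weakly reversible, deficiency 0,
## product-Poisson stationary law with means (b/d) per species
bd3_network <- function(b = c(2, 9, 5), d = c(1, 3, 4)) {
  crn_network(c("A", "B", "C"), list(
    list(reactants = integer(0), products = c(A = 1), rate_constant = b[1]),
    list(reactants = c(A = 1), products = integer(0), rate_constant = d[1]),
    list(reactants = integer(0), products = c(B = 1), rate_constant = b[2]),
    list(reactants = c(B = 1), products = integer(0), rate_constant = d[2]),
    list(reactants = integer(0), products = c(C = 1), rate_constant = b[3]),
    list(reactants = c(C = 1), products = integer(0), rate_constant = d[3])))
}

identity_thetas <- function(species) {
  ths <- lapply(species, function(s) theta_fn(fun = function(z) z, alpha = 1L))
  names(ths) <- species
  theta_kinetics(ths, mode = "theta_product")
}

## random reaction soup (no structural guarantees) for structural
## property tests
random_network <- function(d, K, seed) {
  set.seed(seed)
  repeat {
    reactions <- vector("list", K)
    ok <- TRUE
    for (k in seq_len(K)) {
      src <- sample(0:3, d, replace = TRUE)
      prd <- sample(0:3, d, replace = TRUE)
      if (all(src == prd)) { ok <- FALSE; break }
      sp <- paste0("X", seq_len(d))
      reactions[[k]] <- list(
        reactants = stats::setNames(src, sp)[src > 0],
        products = stats::setNames(prd, sp)[prd > 0],
        rate_constant = stats::runif(1, 0.1, 10))
    }
    if (ok) return(crn_network(paste0("X", seq_len(d)), reactions))
  }
}

## Independent brute-force structural oracle: connectivity by boolean
## matrix powers, rank by base::qr.
brute_structure <- function(net) {
  keys <- apply(rbind(net$nu, net$nu_prime), 1L, paste, collapse = "/")
  u <- unique(keys)
  n <- length(u)
  src <- match(keys[seq_len(net$K)], u)
  prd <- match(keys[net$K + seq_len(net$K)], u)
  A <- matrix(FALSE, n, n)
  A[cbind(src, prd)] <- TRUE
  reach <- diag(TRUE, n) | A
  for (i in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  und <- A | t(A)
  comp <- integer(n); cid <- 0L
  for (v in seq_len(n)) if (comp[v] == 0L) {
    cid <- cid + 1L
    members <- v
    repeat {
      grown <- sort(unique(c(members, which(apply(und[members, , drop = FALSE], 2L, any)))))
      if (length(grown) == length(members)) break
      members <- grown
    }
    comp[members] <- cid
  }
  ell <- length(unique(comp))
  wr <- all(vapply(split(seq_len(n), comp), function(m)
    all(reach[m, m] & t(reach[m, m])), logical(1)))
  s <- qr(net$nu_prime - net$nu)$rank
  list(n = n, ell = ell, s = s, deficiency = n - ell - s,
       weakly_reversible = wr)
}
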