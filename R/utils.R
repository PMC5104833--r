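# Internal numeric and combinatorial helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#'
#' @param lw numeric vector of log-weights; `-Inf` entries are allowed.
#' @return `log(sum(exp(lw)))` computed without overflow.
#' @keywords internal
logsumexp <- function(lw) {
  lw <- lw[!is.na(lw)]
  if (length(lw) == 0L) return(-Inf)
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lw - m)))
}

## gcd with the convention gcd over the empty set / all-zero set = 0;
## callers map 0 to 1 where the alpha convention requires it.
gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  abs(a)
}

gcd_vec <- function(v) {
  v <- as.integer(abs(v))
  Reduce(gcd2, v, accumulate = FALSE, 0L)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

## Exact integer left-null-space basis of an integer matrix (rows of the
## result w satisfy w %*% M = 0). Fraction-free Gaussian elimination keeps
## all arithmetic in integers (stored as doubles; entries stay small for the
## stoichiometries handled here), so the result is exact. Returned vectors
## are primitive: cleared of common factors, first nonzero entry positive.
integer_left_nullspace <- function(M) {
  M <- t(M)                       # nullspace of t(M) on the right
  m <- nrow(M); n <- ncol(M)
  A <- rbind(M, diag(n))          # track column operations below M
  A <- apply(A, 2L, as.numeric)
  if (n == 1L) A <- matrix(A, ncol = 1L)
  pr <- 0L
  for (r in seq_len(m)) {
    if (pr >= n) break
    piv <- which(abs(A[r, (pr + 1L):n]) > 1e-9)
    if (length(piv) == 0L) next
    piv <- piv[1L] + pr
    pr <- pr + 1L
    if (piv != pr) A[, c(pr, piv)] <- A[, c(piv, pr)]
    p <- A[r, pr]
    for (j in seq_len(n)) {
      if (j == pr) next
      if (abs(A[r, j]) > 1e-9) {
        A[, j] <- A[, j] * p - A[, pr] * A[r, j]
        g <- gcd_vec(round(A[, j]))
        if (g > 1) A[, j] <- A[, j] / g
      }
    }
  }
  if (pr >= n) return(matrix(numeric(0), nrow = 0L, ncol = m))
  null_cols <- A[(m + 1L):(m + n), (pr + 1L):n, drop = FALSE]
  basis <- t(null_cols)
  t(apply(basis, 1L, primitive_integer_vector))
}

## Clear denominators / common factors; sign fixed so the first nonzero
## entry is positive (deterministic output, see crn_structure()).
primitive_integer_vector <- function(v) {
  v <- round(v)
  g <- gcd_vec(v)
  if (g > 0) v <- v / g
  nz <- which(v != 0)
  if (length(nz) && v[nz[1L]] < 0) v <- -v
  v
}

## Rank of an integer/real matrix via QR with a scale-aware tolerance.
matrix_rank <- function(M, tol = 1e-9) {
  if (length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  s <- svd(M, nu = 0L, nv = 0L)$d
  sum(s > tol * max(s[1L], 1))
}

## Parse a linear-functional string such as "S1+2*S2=300" or "S1+S2%2=0"
## into integer coefficients over the network's species. Only integer
## coefficients are accepted: state classes are lattice objects.
parse_linear_functional <- function(txt, species) {
  txt <- gsub("[[:space:]]", "", txt)
  modulus <- NA_integer_
  if (grepl("%", txt, fixed = TRUE)) {
    parts <- strsplit(txt, "%", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed residue constraint: ", txt)
    txt <- parts[1L]
    rhs_part <- strsplit(parts[2L], "=", fixed = TRUE)[[1L]]
    if (length(rhs_part) != 2L) stop("malformed residue constraint: ", txt)
    modulus <- as.integer(rhs_part[1L])
    value <- as.integer(rhs_part[2L])
    lhs <- txt
  } else {
    parts <- strsplit(txt, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed constraint (need '='): ", txt)
    lhs <- parts[1L]
    value <- as.numeric(parts[2L])
    if (!is_wholenumber(value)) stop("constraint value must be an integer: ", txt)
    value <- as.integer(value)
  }
  w <- integer(length(species))
  names(w) <- species
  terms <- strsplit(gsub("-", "+-", lhs), "+", fixed = TRUE)[[1L]]
  terms <- terms[nzchar(terms)]
  for (tm in terms) {
    coef <- 1L
    sp <- tm
    if (grepl("*", tm, fixed = TRUE)) {
      bits <- strsplit(tm, "*", fixed = TRUE)[[1L]]
      if (length(bits) != 2L) stop("malformed term '", tm, "' in ", txt)
      cnum <- suppressWarnings(as.numeric(bits[1L]))
      if (is.na(cnum) || !is_wholenumber(cnum))
        stop("non-integer coefficient in term '", tm, "'")
      coef <- as.integer(round(cnum))
      sp <- bits[2L]
    } else if (grepl("^-", tm)) {
      coef <- -1L
      sp <- sub("^-", "", tm)
    }
    if (is.na(coef)) stop("non-integer coefficient in term '", tm, "'")
    if (!sp %in% species) stop("unknown species '", sp, "' in constraint ", txt)
    w[sp] <- w[sp] + coef
  }
  list(w = unname(w), value = value, modulus = modulus, species = species)
}

## Deterministic integer key for states inside a box, used for O(1)-ish
## membership lookup via match().
encode_states <- function(X, box) {
  stride <- cumprod(c(1, box[-length(box)] + 1))
  as.numeric(X %*% stride)
}

stop_if_not_state <- function(x, d) {
  if (length(x) != d || any(x < 0) || any(!is_wholenumber(x)))
    stop("state must be a length-", d, " vector of nonnegative integers")
  invisible(as.integer(round(x)))
}
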