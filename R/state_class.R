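#' State classes: truncated boxes with linear and residue constraints
#'
#' A state class describes the finite set of lattice states on which a
#' stationary measure is enumerated and normalized: a per-coordinate box
#' `0..box[i]`, intersected with any number of linear invariants
#' \eqn{w \cdot x = v} (conserved quantities such as `S1 + 2*S2 = 300`) and
#' residue constraints \eqn{u \cdot x \equiv a \pmod m} (e.g. parity
#' classes). Irreducibility of the chain on the class is the caller's
#' responsibility; classes are how compatibility classes are specified.
#'
#' @param species character vector naming the coordinates (defines d).
#' @param box integer vector of per-coordinate upper bounds (lower bounds
#'   are 0).
#' @param invariants list of linear invariants; each either a string
#'   (`"S1+2*S2=300"`) or a list `list(w = <int vector>, v = <int>)`.
#' @param residues list of residue constraints; each either a string
#'   (`"S1+S2%2=0"`) or a list `list(u = <int vector>, m = <int>, a = <int>)`.
#' @return object of class `state_class`.
#' @export
state_class <- function(species, box, invariants = list(), residues = list()) {
  species <- as.character(species)
  d <- length(species)
  box <- as.integer(box)
  if (length(box) != d || any(box < 0)) stop("box must give one nonnegative bound per coordinate")
  norm_inv <- lapply(invariants, function(iv) {
    if (is.character(iv)) {
      pf <- parse_linear_functional(iv, species)
      if (!is.na(pf$modulus)) stop("use residues= for modular constraints: ", iv)
      list(w = as.integer(pf$w), v = pf$value)
    } else list(w = as.integer(iv$w), v = as.integer(iv$v))
  })
  norm_res <- lapply(residues, function(rv) {
    if (is.character(rv)) {
      pf <- parse_linear_functional(rv, species)
      if (is.na(pf$modulus)) stop("residue constraint needs a modulus: ", rv)
      list(u = as.integer(pf$w), m = pf$modulus, a = pf$value)
    } else list(u = as.integer(rv$u), m = as.integer(rv$m), a = as.integer(rv$a))
  })
  structure(list(species = species, d = d, box = box,
                 invariants = norm_inv, residues = norm_res),
            class = "state_class")
}

#' @export
print.state_class <- function(x, ...) {
  cat("State class over (", paste(x$species, collapse = ", "), "), box [0,",
      paste(x$box, collapse = "] x [0,"), "]\n", sep = "")
  for (iv in x$invariants)
    cat("  invariant: (", paste(iv$w, collapse = ","), ") . x = ", iv$v, "\n", sep = "")
  for (rv in x$residues)
    cat("  residue:   (", paste(rv$u, collapse = ","), ") . x = ", rv$a,
        " (mod ", rv$m, ")\n", sep = "")
  invisible(x)
}

#' Enumerate all states of a class in lexicographic order
#'
#' States are ordered lexicographically with the first coordinate most
#' significant; the order is deterministic and shared by every consumer
#' (generator rows, distribution vectors, TSV output).
#'
#' @param cls a [state_class()].
#' @return integer matrix, one state per row (possibly 0 rows).
#' @export
enumerate_class <- function(cls) {
  stopifnot(inherits(cls, "state_class"))
  d <- cls$d
  ## last coordinate varies fastest => lexicographic with x1 most significant
  grids <- lapply(rev(cls$box), function(b) 0:b)
  X <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  X <- X[, rev(seq_len(d)), drop = FALSE]
  keep <- rep(TRUE, nrow(X))
  for (iv in cls$invariants) keep <- keep & (as.numeric(X %*% iv$w) == iv$v)
  for (rv in cls$residues) keep <- keep & ((as.numeric(X %*% rv$u) %% rv$m) == rv$a)
  X <- X[keep, , drop = FALSE]
  o <- do.call(order, as.data.frame(X))
  X <- X[o, , drop = FALSE]
  dimnames(X) <- list(NULL, cls$species)
  storage.mode(X) <- "integer"
  X
}

## Membership keys for a set of enumerated states (match() against these).
class_state_keys <- function(X, box) encode_states(X, box)
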