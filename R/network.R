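#' Construct a chemical reaction network
#'
#' A chemical reaction network is the triple of species, complexes and
#' reactions. Each reaction converts a source complex \eqn{\nu_k} into a
#' product complex \eqn{\nu_k'} at rate constant \eqn{\kappa_k > 0}; source
#' and product must differ.
#'
#' @param species character vector of unique species names (length `d`).
#' @param reactions list of reactions. Each reaction is a list with entries
#'   `reactants` and `products` (named integer vectors, `c(S1 = 2)`; the
#'   empty complex is `integer(0)` or an empty named vector), a positive
#'   `rate_constant`, and an optional `label`.
#' @return An object of class `crn_network` with fields `species`, `nu`
#'   (the K x d source stoichiometry matrix), `nu_prime` (K x d products),
#'   `kappa`, and `labels`.
#' @examples
#' rev_dimer <- crn_network(
#'   c("S1", "S2"),
#'   list(list(reactants = c(S1 = 2), products = c(S2 = 1), rate_constant = 1),
#'        list(reactants = c(S2 = 1), products = c(S1 = 2), rate_constant = 1)))
#' @export
crn_network <- function(species, reactions) {
  species <- as.character(species)
  if (length(species) < 1L) stop("need at least one species")
  if (anyDuplicated(species)) stop("duplicate species names: ",
                                   paste(unique(species[duplicated(species)]), collapse = ", "))
  if (length(reactions) < 1L) stop("need at least one reaction")
  d <- length(species)
  K <- length(reactions)
  nu <- matrix(0L, K, d, dimnames = list(NULL, species))
  nu_prime <- nu
  kappa <- numeric(K)
  labels <- character(K)
  as_complex_row <- function(v, what, k) {
    row <- integer(d)
    if (length(v) == 0L) return(row)
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop("reaction ", k, ": ", what, " must be a named vector")
    if (any(!names(v) %in% species))
      stop("reaction ", k, ": unknown species in ", what, ": ",
           paste(setdiff(names(v), species), collapse = ", "))
    if (any(v < 0) || any(!is_wholenumber(v)))
      stop("reaction ", k, ": stoichiometries must be nonnegative integers")
    row[match(names(v), species)] <- as.integer(round(v))
    row
  }
  for (k in seq_len(K)) {
    rx <- reactions[[k]]
    nu[k, ] <- as_complex_row(rx$reactants %||% integer(0), "reactants", k)
    nu_prime[k, ] <- as_complex_row(rx$products %||% integer(0), "products", k)
    kk <- rx$rate_constant
    if (is.null(kk) || !is.numeric(kk) || length(kk) != 1L || !is.finite(kk) || kk <= 0)
      stop("reaction ", k, ": rate_constant must be a single positive number")
    kappa[k] <- kk
    labels[k] <- as.character(rx$label %||% paste0("r", k))
    if (all(nu[k, ] == nu_prime[k, ]))
      stop("reaction ", k, " (", labels[k],
           "): source and product complexes are identical (nu_k = nu_k')")
  }
  structure(list(species = species, nu = nu, nu_prime = nu_prime,
                 kappa = kappa, labels = labels, d = d, K = K),
            class = "crn_network")
}

#' @export
print.crn_network <- function(x, ...) {
  cat("Chemical reaction network:", x$d, "species,", x$K, "reactions\n")
  fmt <- function(row) {
    nz <- which(row > 0)
    if (!length(nz)) return("0")
    paste(ifelse(row[nz] > 1, paste0(row[nz], x$species[nz]), x$species[nz]),
          collapse = " + ")
  }
  for (k in seq_len(x$K)) {
    cat(sprintf("  %-8s %s -> %s   (kappa = %g)\n", x$labels[k],
                fmt(x$nu[k, ]), fmt(x$nu_prime[k, ]), x$kappa[k]))
  }
  invisible(x)
}

## Distinct complexes of the network, as a matrix with one complex per row,
## deduplicated by exact integer value, in order of first appearance
## (sources scanned before products, reaction by reaction).
network_complexes <- function(net) {
  all_cx <- rbind(net$nu, net$nu_prime)
  keys <- apply(all_cx, 1L, paste, collapse = ",")
  ux <- !duplicated(keys)
  cx <- all_cx[ux, , drop = FALSE]
  rownames(cx) <- NULL
  src_idx <- match(keys[seq_len(net$K)], keys[ux])
  prod_idx <- match(keys[net$K + seq_len(net$K)], keys[ux])
  list(complexes = cx, source_index = src_idx, product_index = prod_idx)
}

#' Structural report: complexes, linkage classes, deficiency, conservation laws
#'
#' Computes the chemical reaction network theory invariants that gate the
#' product-form theorems: the `n` distinct complexes, the `l` linkage
#' classes (connected components of the undirected complex graph), weak
#' reversibility (every component of the directed complex graph strongly
#' connected), the rank `s` of the span of the reaction vectors
#' \eqn{\nu_k' - \nu_k}, the deficiency \eqn{\delta = n - l - s}, and an
#' integer basis of conservation laws (left null space of the stoichiometric
#' matrix, computed exactly).
#'
#' The complex graph is the directed multigraph on distinct complexes with
#' an edge per reaction, collapsed to a simple digraph for connectivity.
#'
#' @param net a [crn_network()].
#' @return An object of class `crn_structure`; a list with fields
#'   `complexes`, `n`, `linkage_classes`, `l`, `weakly_reversible`,
#'   `stoich_rank`, `deficiency`, `conservation_laws` (matrix, one law per
#'   row, primitive integer vectors).
#' @export
crn_structure <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  cx <- network_complexes(net)
  n <- nrow(cx$complexes)
  adj <- matrix(FALSE, n, n)
  adj[cbind(cx$source_index, cx$product_index)] <- TRUE
  ## Warshall transitive closure; n is small (complex sets are tiny).
  reach <- adj | diag(TRUE, n)
  for (m in seq_len(n)) reach <- reach | (reach[, m] %o% reach[m, ])
  und <- reach | t(reach)
  ## connected components of the undirected closure
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      members <- which(und[v, ])
      ## grow until stable (closure of symmetrized reachability)
      repeat {
        grown <- which(apply(und[members, , drop = FALSE], 2L, any))
        if (length(grown) == length(members)) break
        members <- grown
      }
      comp[members] <- cid
    }
  }
  l <- max(comp)
  linkage_classes <- split(seq_len(n), comp)
  weakly_reversible <- all(vapply(linkage_classes, function(m) {
    all(reach[m, m] & t(reach[m, m]))
  }, logical(1)))
  reaction_vectors <- net$nu_prime - net$nu
  s <- matrix_rank(reaction_vectors)
  laws <- integer_left_nullspace(t(reaction_vectors))  # rows w: w . (nu'-nu) = 0
  if (nrow(laws)) colnames(laws) <- net$species
  structure(list(complexes = cx$complexes, n = n,
                 linkage_classes = linkage_classes, l = l,
                 weakly_reversible = weakly_reversible,
                 stoich_rank = s, deficiency = n - l - s,
                 conservation_laws = laws,
                 source_index = cx$source_index,
                 product_index = cx$product_index),
            class = "crn_structure")
}

#' @export
print.crn_structure <- function(x, ...) {
  cat("CRN structure: n =", x$n, "complexes, l =", x$l,
      "linkage classes, rank s =", x$stoich_rank, "\n")
  cat("  deficiency  =", x$deficiency, "\n")
  cat("  weakly reversible:", x$weakly_reversible, "\n")
  cat("  conservation laws:", nrow(x$conservation_laws), "\n")
  invisible(x)
}

#' Per-species alpha-partition of source stoichiometries
#'
#' For each species the integer \eqn{\alpha_i} is the gcd of its source
#' stoichiometric coefficients over all reactions. Species with
#' \eqn{\alpha_i > 1} form the scaled set on which theta functions are
#' evaluated along an \eqn{\alpha_i}-strided lattice; species with
#' \eqn{\alpha_i = 1} behave as in the classical theta-product setting. A
#' species that appears in no source complex (all-zero column, gcd over the
#' empty set) gets \eqn{\alpha_i = 1}, so its intensity contribution is an
#' empty product.
#'
#' @param net a [crn_network()].
#' @return Object of class `crn_alpha`: list with `alpha` (length-d integer
#'   vector), `slow_set` (indices with \eqn{\alpha_i = 1}) and `scaled_set`
#'   (indices with \eqn{\alpha_i > 1}).
#' @export
alpha_partition <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  alpha <- unname(apply(net$nu, 2L, gcd_vec))
  alpha[alpha == 0L] <- 1L           # species never consumed
  structure(list(alpha = as.integer(alpha),
                 slow_set = which(alpha == 1L),
                 scaled_set = which(alpha > 1L),
                 species = net$species),
            class = "crn_alpha")
}

#' @export
print.crn_alpha <- function(x, ...) {
  cat("alpha-partition:\n")
  for (i in seq_along(x$alpha))
    cat(sprintf("  %-6s alpha = %d  (%s)\n", x$species[i], x$alpha[i],
                if (x$alpha[i] > 1L) "scaled set" else "slow set"))
  invisible(x)
}
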