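#' Read and write network specification files
#'
#' The on-disk format is JSON with top-level keys `species` (list of
#' strings), `reactions` (list of objects with `reactants` and `products`
#' as species-to-count maps, a positive `rate_constant`, and an optional
#' `label`), and an optional `kinetics` object:
#' `{"mode": "mass_action" | "theta_product" | "alpha_theta_product",
#'   "thetas": {"S1": {"expr": "..."} or {"table": [...]}}}`.
#' Unknown keys anywhere are rejected. Theta strides are not stored: they
#' are recomputed from the network's alpha-partition (alpha-strided mode)
#' or fixed at 1 (classical mode), so a file round-trips to an identical
#' in-memory structure.
#'
#' @param path file path.
#' @return `read_network()`: list with `net` (a [crn_network()]) and `kin`
#'   (a `crn_kinetics`; mass action when the file has no kinetics
#'   section).
#' @export
read_network <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("species", "reactions", "kinetics")
  unknown <- setdiff(names(spec), known)
  if (length(unknown)) stop("unknown top-level keys: ",
                            paste(unknown, collapse = ", "))
  if (is.null(spec$species) || is.null(spec$reactions))
    stop("network file needs 'species' and 'reactions'")
  species <- vapply(spec$species, as.character, character(1))
  reactions <- lapply(seq_along(spec$reactions), function(k) {
    rx <- spec$reactions[[k]]
    bad <- setdiff(names(rx), c("reactants", "products", "rate_constant", "label"))
    if (length(bad)) stop("reaction ", k, ": unknown keys: ",
                          paste(bad, collapse = ", "))
    list(reactants = unlist(rx$reactants) %||% integer(0),
         products = unlist(rx$products) %||% integer(0),
         rate_constant = rx$rate_constant,
         label = rx$label %||% paste0("r", k))
  })
  net <- crn_network(species, reactions)
  kin <- mass_action_kinetics()
  if (!is.null(spec$kinetics)) {
    ks <- spec$kinetics
    bad <- setdiff(names(ks), c("mode", "thetas"))
    if (length(bad)) stop("kinetics: unknown keys: ", paste(bad, collapse = ", "))
    mode <- ks$mode %||% "mass_action"
    if (mode != "mass_action") {
      ap <- alpha_partition(net)
      if (any(!names(ks$thetas) %in% species))
        stop("kinetics thetas name unknown species: ",
             paste(setdiff(names(ks$thetas), species), collapse = ", "))
      thetas <- lapply(names(ks$thetas), function(nm) {
        td <- ks$thetas[[nm]]
        bad <- setdiff(names(td), c("expr", "table"))
        if (length(bad)) stop("theta for ", nm, ": unknown keys: ",
                              paste(bad, collapse = ", "))
        a <- if (mode == "alpha_theta_product")
          ap$alpha[match(nm, species)] else 1L
        if (!is.null(td$expr)) theta_fn(expr = td$expr, alpha = a)
        else theta_fn(table = unlist(td$table), alpha = a)
      })
      names(thetas) <- names(ks$thetas)
      kin <- theta_kinetics(thetas, mode = mode)
    }
  }
  list(net = net, kin = kin)
}

#' @rdname read_network
#' @param net a [crn_network()].
#' @param kin optional `crn_kinetics` to embed (function-based thetas
#'   cannot be serialized and raise an error).
#' @export
write_network <- function(net, path, kin = NULL) {
  stopifnot(inherits(net, "crn_network"))
  rxs <- lapply(seq_len(net$K), function(k) {
    to_map <- function(row) {
      nz <- which(row > 0)
      stats::setNames(as.list(as.integer(row[nz])), net$species[nz])
    }
    list(reactants = to_map(net$nu[k, ]), products = to_map(net$nu_prime[k, ]),
         rate_constant = net$kappa[k], label = net$labels[k])
  })
  out <- list(species = as.list(net$species), reactions = rxs)
  if (!is.null(kin) && kin$mode != "mass_action") {
    ths <- lapply(kin$thetas, function(th) {
      switch(th$type,
             expr = list(expr = th$expr),
             table = list(table = as.numeric(th$table)),
             stop("function-based thetas cannot be serialized; ",
                  "use expr or table"))
    })
    out$kinetics <- list(mode = kin$mode, thetas = ths)
  } else if (!is.null(kin)) {
    out$kinetics <- list(mode = "mass_action")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
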