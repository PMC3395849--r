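# Model definition files: a plain YAML schema mirroring the network
# constructors one-to-one.
#
# species:
#   - {name: S, tracked: true, init: 0.96}            # composition defaults
#   - {name: pS_pS, tracked: true, init: 0, composition: [pS, pS]}
# reactions:
#   - {id: r2, reactants: {pS: 2}, products: {pS_pS: 1}, rate: k2*pS*pS}
# parameters: {k1: 1.37, k2: 0.22}
# inputs:
#   - {name: pR, interpolation: cubic, times: [...], values: [...]}

#' Read a reaction network from a YAML model file
#' @param path Path to a model YAML file.
#' @return An `sl_network`.
#' @export
read_model_yaml <- function(path) {
  m <- yaml::read_yaml(path)
  sp <- lapply(m$species, function(s)
    species(s$name,
            initial_value = if (is.null(s$init)) 0 else s$init,
            tracked = isTRUE(s$tracked),
            composition = if (is.null(s$composition)) s$name
                          else unlist(s$composition)))
  side <- function(x) if (is.null(x) || length(x) == 0L) NULL else unlist(x)
  rx <- lapply(m$reactions, function(r)
    reaction(r$id, side(r$reactants), side(r$products), r$rate))
  ins <- lapply(m$inputs, function(i)
    input_function(i$name, unlist(i$times), unlist(i$values),
                   interpolation = if (is.null(i$interpolation)) "linear"
                                   else i$interpolation))
  reaction_network(sp, rx,
                   parameters = if (is.null(m$parameters)) numeric()
                                else unlist(m$parameters),
                   inputs = ins)
}

#' Write a reaction network to a YAML model file
#' @param network An `sl_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(network, path) {
  m <- list(
    species = lapply(unname(network$species), function(s) {
      out <- list(name = s$name, tracked = s$tracked, init = s$initial_value)
      if (!identical(s$composition, s$name)) out$composition <- s$composition
      out
    }),
    reactions = lapply(unname(network$reactions), function(r) {
      out <- list(id = r$id)
      if (length(r$reactants)) out$reactants <- as.list(r$reactants)
      if (length(r$products)) out$products <- as.list(r$products)
      out$rate <- r$rate_law
      out
    }),
    parameters = as.list(network$parameters))
  if (length(network$inputs))
    m$inputs <- lapply(unname(network$inputs), function(i)
      list(name = i$name, interpolation = i$interpolation,
           times = i$times, values = i$values))
  yaml::write_yaml(m, path, precision = 15L)
  invisible(path)
}

#' Write a characteristic curve as CSV
#' @param curve An `sl_characteristic`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_characteristic_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
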