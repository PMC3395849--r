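#' Declare a species of a reaction network
#'
#' A species is either a single entity (composition of length 1) or a
#' complex of several monomers (composition length >= 2, order significant).
#' Tracked species take part in in silico labeling: a tracked monomer gets a
#' labeled and a free counterpart, a tracked complex gets one counterpart
#' per labeled/free combination over its monomer slots.
#'
#' @param name Species identifier, unique within a network.
#' @param initial_value Initial concentration (>= 0).
#' @param tracked Logical; does the labeling machinery follow this species?
#' @param composition Ordered character vector of monomer names. Defaults to
#'   `name` itself (a monomer). For a tracked complex every entry must be a
#'   declared tracked monomer of the same network; the entries record which
#'   monomer lineage occupies each slot.
#' @return An object of class `sl_species`.
#' @examples
#' species("S", 0.96, tracked = TRUE)
#' species("pS_pS", 0, tracked = TRUE, composition = c("pS", "pS"))
#' @export
species <- function(name, initial_value = 0, tracked = FALSE,
                    composition = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(initial_value) || length(initial_value) != 1L ||
      is.na(initial_value) || initial_value < 0)
    stop("initial_value of species '", name, "' must be a single number >= 0")
  if (length(composition) < 1L)
    stop("composition of species '", name, "' must be non-empty")
  structure(
    list(name = name, tracked = isTRUE(tracked),
         composition = as.character(composition),
         initial_value = as.numeric(initial_value)),
    class = "sl_species")
}

#' Declare a reaction
#'
#' Reactant and product order is significant: the combinatorial expansion of
#' labeled/free assignments works over the ordered list of tracked monomer
#' slots, and labels flow positionally from reactant slots to product slots.
#'
#' @param id Reaction identifier.
#' @param reactants,products Named integer vectors of stoichiometric counts,
#'   e.g. `c(pS = 2)` for a homodimerization, in the intended slot order.
#'   `NULL` or an empty vector denotes a source/sink side.
#' @param rate Rate-law expression as a string over species names, parameter
#'   names and input-function names; operators `+ - * / ^` and functions
#'   `exp`, `log`, `sqrt` are allowed. Non-syntactic names (such as labeled
#'   variants) must be backtick-quoted.
#' @return An object of class `sl_reaction`.
#' @examples
#' reaction("r2", c(pS = 2), c(pS_pS = 1), "k2*pS*pS")
#' @export
reaction <- function(id, reactants, products, rate) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  as_side <- function(x, what) {
    if (is.null(x) || length(x) == 0L)
      return(stats::setNames(integer(0), character(0)))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("reaction '", id, "': ", what, " must be a named vector")
    if (any(x != round(x)) || any(x < 1))
      stop("reaction '", id, "': stoichiometric counts must be positive integers")
    stats::setNames(as.integer(x), names(x))
  }
  stopifnot(is.character(rate), length(rate) == 1L)
  structure(
    list(id = id,
         reactants = as_side(reactants, "reactants"),
         products = as_side(products, "products"),
         rate_law = rate),
    class = "sl_reaction")
}

#' Declare a tabulated input function
#'
#' Time-dependent driving inputs (such as a receptor activity profile) are
#' given as sampled (time, value) pairs with linear or cubic-spline
#' interpolation and constant extrapolation at the boundaries.
#'
#' @param name Input identifier, usable inside rate laws.
#' @param times Strictly increasing sample times.
#' @param values Sample values, same length as `times`.
#' @param interpolation `"linear"` or `"cubic"`.
#' @return An object of class `sl_input` carrying an evaluator `fun(t)`.
#' @export
input_function <- function(name, times, values,
                           interpolation = c("linear", "cubic")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (any(diff(times) <= 0))
    stop("input '", name, "': times must be strictly increasing")
  fun <- if (interpolation == "linear") {
    stats::approxfun(times, values, rule = 2)
  } else {
    sf <- stats::splinefun(times, values, method = "natural")
    lo <- times[1L]; hi <- times[length(times)]
    function(t) sf(pmin(pmax(t, lo), hi))
  }
  structure(
    list(name = name, times = as.numeric(times), values = as.numeric(values),
         interpolation = interpolation, fun = fun),
    class = "sl_input")
}

.SL_ALLOWED_FUNS <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt")

#' Assemble a reaction network
#'
#' Validates name resolution (every name used in a rate law must be a
#' declared species, parameter or input; every composition entry of a
#' tracked complex must be a declared tracked monomer) and returns the
#' container all other operations work on.
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param parameters Named numeric vector or list of parameter values.
#' @param inputs List of [input_function()] objects (may be empty).
#' @return An object of class `sl_network`.
#' @export
reaction_network <- function(species, reactions, parameters = numeric(),
                             inputs = list()) {
  if (inherits(species, "sl_species")) species <- list(species)
  if (inherits(reactions, "sl_reaction")) reactions <- list(reactions)
  if (inherits(inputs, "sl_input")) inputs <- list(inputs)
  stopifnot(all(vapply(species, inherits, TRUE, "sl_species")),
            all(vapply(reactions, inherits, TRUE, "sl_reaction")),
            all(vapply(inputs, inherits, TRUE, "sl_input")))
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names))
    stop("duplicated species names: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  parameters <- unlist(parameters)
  if (length(parameters) && (is.null(names(parameters)) ||
                             any(!nzchar(names(parameters)))))
    stop("parameters must be named")
  in_names <- vapply(inputs, `[[`, "", "name")
  rx_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rx_ids))
    stop("duplicated reaction ids")
  known <- c(sp_names, names(parameters), in_names)
  if (anyDuplicated(known))
    stop("species, parameter and input names must not collide: ",
         paste(unique(known[duplicated(known)]), collapse = ", "))

  # tracked complexes decompose into declared tracked monomers
  tracked <- vapply(species, `[[`, TRUE, "tracked")
  monomers <- sp_names[tracked &
                         vapply(species, function(s) length(s$composition), 0L) == 1L]
  for (s in species) {
    if (s$tracked && length(s$composition) > 1L) {
      bad <- setdiff(s$composition, monomers)
      if (length(bad))
        stop("tracked complex '", s$name, "': composition entries ",
             paste(bad, collapse = ", "),
             " are not declared tracked single entities")
    }
  }

  # rate laws and stoichiometric references resolve
  for (r in reactions) {
    refs <- c(names(r$reactants), names(r$products))
    bad <- setdiff(refs, sp_names)
    if (length(bad))
      stop("reaction '", r$id, "' references unknown species: ",
           paste(bad, collapse = ", "))
    expr <- tryCatch(str2lang(r$rate_law),
                     error = function(e) stop("reaction '", r$id,
                                              "': unparseable rate law: ",
                                              conditionMessage(e)))
    syms <- all.names(expr)
    bad <- setdiff(syms, c(known, .SL_ALLOWED_FUNS))
    if (length(bad))
      stop("reaction '", r$id, "': unresolvable symbol(s) in rate law: ",
           paste(bad, collapse = ", "))
  }

  structure(
    list(species = stats::setNames(species, sp_names),
         reactions = stats::setNames(reactions, rx_ids),
         parameters = parameters,
         inputs = stats::setNames(inputs, in_names)),
    class = "sl_network")
}

#' @export
print.sl_network <- function(x, ...) {
  cat("<sl_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions, ",
      length(x$parameters), " parameters, ",
      length(x$inputs), " inputs\n", sep = "")
  tr <- species_names(x, tracked_only = TRUE)
  if (length(tr)) cat("  tracked:", paste(tr, collapse = ", "), "\n")
  invisible(x)
}

#' Species names of a network
#' @param network An `sl_network`.
#' @param tracked_only Restrict to tracked species.
#' @return Character vector in declaration order.
#' @export
species_names <- function(network, tracked_only = FALSE) {
  nm <- names(network$species)
  if (tracked_only)
    nm <- nm[vapply(network$species, `[[`, TRUE, "tracked")]
  nm
}

#' Initial state vector of a network
#' @param network An `sl_network`.
#' @return Named numeric vector of initial concentrations.
#' @export
initial_state <- function(network) {
  vapply(network$species, `[[`, 0, "initial_value")
}

#' Replace parameter values
#' @param network An `sl_network`.
#' @param values Named numeric vector; must be a subset of the declared
#'   parameter names.
#' @return The modified network.
#' @export
set_parameters <- function(network, values) {
  values <- unlist(values)
  bad <- setdiff(names(values), names(network$parameters))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  network$parameters[names(values)] <- values
  network
}

# Stoichiometric matrices: rows species, columns reactions.
.stoichiometry <- function(network) {
  sp <- species_names(network)
  n <- length(network$reactions)
  A <- B <- matrix(0, length(sp), n, dimnames = list(sp, names(network$reactions)))
  for (j in seq_len(n)) {
    r <- network$reactions[[j]]
    for (k in seq_along(r$reactants))
      B[names(r$reactants)[k], j] <- B[names(r$reactants)[k], j] + r$reactants[k]
    for (k in seq_along(r$products))
      A[names(r$products)[k], j] <- A[names(r$products)[k], j] + r$products[k]
  }
  list(product = A, reactant = B, net = A - B)
}

# Shared evaluation machinery: an environment holding parameters and, per
# call, the current species concentrations and input values.
.flux_evaluator <- function(network, parameters = NULL) {
  sp <- species_names(network)
  exprs <- lapply(network$reactions, function(r) str2lang(r$rate_law))
  ids <- names(network$reactions)
  inputs <- lapply(network$inputs, `[[`, "fun")
  e <- new.env(parent = baseenv())
  pars <- if (is.null(parameters)) network$parameters else parameters
  for (nm in names(pars)) assign(nm, pars[[nm]], envir = e)
  nrx <- length(exprs)
  function(t, state) {
    # negative round-off is clipped to zero in rate evaluation only
    x <- pmax(state, 0)
    for (i in seq_along(sp)) assign(sp[i], x[[i]], envir = e)
    for (nm in names(inputs)) assign(nm, inputs[[nm]](t), envir = e)
    v <- numeric(nrx)
    for (j in seq_len(nrx)) v[j] <- eval(exprs[[j]], e)
    if (any(!is.finite(v)))
      stop("non-finite flux in reaction '", ids[which(!is.finite(v))[1L]],
           "' at t = ", signif(t, 6))
    v
  }
}

#' Build the right-hand side of the network ODE system
#'
#' For each species the derivative is the sum of product-side fluxes minus
#' the sum of reactant-side fluxes, with every flux evaluated at the current
#' state and input values.
#'
#' @param network An `sl_network`.
#' @param parameters Optional named override of the network's parameters.
#' @return A function `f(t, state)` returning the named derivative vector.
#' @export
build_rhs <- function(network, parameters = NULL) {
  ev <- .flux_evaluator(network, parameters)
  Snet <- .stoichiometry(network)$net
  sp <- rownames(Snet)
  function(t, state) {
    v <- ev(t, state)
    stats::setNames(drop(Snet %*% v), sp)
  }
}

#' Evaluate all reaction fluxes at a given time and state
#'
#' @param network An `sl_network`.
#' @param t Time at which input functions are evaluated.
#' @param state Named or positional concentration vector (length = number of
#'   species, in declaration order).
#' @return Named numeric vector of per-reaction flux values.
#' @export
evaluate_fluxes <- function(network, t, state) {
  sp <- species_names(network)
  if (length(state) != length(sp))
    stop("state length ", length(state), " does not match species count ",
         length(sp))
  if (!is.null(names(state))) state <- state[sp]
  stats::setNames(.flux_evaluator(network)(t, state),
                  names(network$reactions))
}

#' Integrate a reaction network
#'
#' Wraps [deSolve::ode()] (lsoda) with an output grid whose spacing never
#' exceeds `max_step`; the same bound is imposed on the internal integrator
#' step (`hmax`) so that threshold crossings interpolated from the samples
#' are accurate.
#'
#' @param network An `sl_network`.
#' @param t_span Numeric length-2, `c(start, end)`.
#' @param initial_state Optional named state override; defaults to the
#'   network's declared initial values.
#' @param max_step Maximum grid spacing and integrator step; defaults to
#'   `diff(t_span)/500`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A data frame of class `sl_trajectory`: first column `time`, one
#'   column per species; attributes record solver settings.
#' @export
integrate_network <- function(network, t_span, initial_state = NULL,
                              max_step = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(max_step)) max_step <- diff(t_span) / 500
  stopifnot(max_step > 0)
  y0 <- vapply(network$species, `[[`, 0, "initial_value")
  if (!is.null(initial_state)) {
    if (is.null(names(initial_state))) {
      stopifnot(length(initial_state) == length(y0))
      y0[] <- initial_state
    } else y0[names(initial_state)] <- initial_state
  }
  rhs <- build_rhs(network)
  .integrate_rhs(rhs, y0, t_span, max_step, rtol, atol)
}

# Core solver call shared by the plain, augmented and extended systems.
.integrate_rhs <- function(rhs, y0, t_span, max_step, rtol, atol) {
  n_out <- max(2L, ceiling(diff(t_span) / max_step))
  times <- seq(t_span[1], t_span[2], length.out = n_out + 1L)
  sol <- tryCatch(
    deSolve::ode(y = y0, times = times,
                 func = function(t, y, p) list(rhs(t, y)),
                 method = "lsoda", rtol = rtol, atol = atol,
                 hmax = max_step),
    warning = function(w) {
      stop("integration failed (", conditionMessage(w), ")")
    })
  if (nrow(sol) < length(times))
    stop("integration stopped early at t = ", sol[nrow(sol), 1L])
  out <- as.data.frame(sol, check.names = FALSE)
  names(out)[1L] <- "time"
  structure(out, class = c("sl_trajectory", "data.frame"),
            max_step = max_step, rtol = rtol, atol = atol)
}

#' Write a trajectory as CSV
#' @param trajectory An `sl_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
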