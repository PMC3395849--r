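# Construction of the extended labeled/free reaction network.
#
# Tracked species are split into labeled (L) and free (F) counterparts, one
# per combination over the tracked monomer slots of a complex; reactions
# touching tracked species get one labeled counterpart per labeled/free
# assignment over their ordered reactant slots, with fluxes slaved to the
# original reaction flux through concentration-ratio weights. Ordering
# convention throughout: F before L, first slot varies fastest.

.variant_name <- function(base, pattern) {
  slots <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  if (length(parts) == length(slots))
    paste(paste0(parts, "^", slots), collapse = "_")
  else
    paste0(base, "^", pattern)
}

.patterns <- function(p) {
  if (p == 0L) return("")
  g <- expand.grid(rep(list(c("F", "L")), p), stringsAsFactors = FALSE)
  apply(as.matrix(g), 1L, paste, collapse = "")
}

#' Enumerate the labeled/free variants of a tracked species
#'
#' A tracked monomer has two variants (free and labeled); a tracked complex
#' with `s` tracked monomer slots has `2^s` variants, ordered slot-wise in
#' the order of the original composition (free before labeled, first slot
#' varying fastest).
#'
#' @param species An [species()] object with `tracked = TRUE`.
#' @return Data frame with columns `name`, `base`, `pattern` and `labels`
#'   (number of labeled slots).
#' @examples
#' enumerate_label_variants(species("pS_pS", tracked = TRUE,
#'                                  composition = c("pS", "pS")))
#' @export
enumerate_label_variants <- function(species) {
  if (!inherits(species, "sl_species")) stop("not an sl_species")
  if (!species$tracked)
    stop("species '", species$name, "' is not tracked")
  pats <- .patterns(length(species$composition))
  data.frame(
    name = vapply(pats, .variant_name, "", base = species$name,
                  USE.NAMES = FALSE),
    base = species$name,
    pattern = pats,
    labels = vapply(strsplit(pats, ""), function(x) sum(x == "L"), 0L),
    stringsAsFactors = FALSE)
}

# Ordered occurrence list of one reaction side, stoichiometry expanded into
# repeated slots and untracked species removed.
.tracked_occurrences <- function(side, network) {
  occ <- rep(names(side), times = side)
  occ <- occ[vapply(occ, function(nm) network$species[[nm]]$tracked, TRUE)]
  slots <- vapply(occ, function(nm)
    length(network$species[[nm]]$composition), 0L, USE.NAMES = FALSE)
  list(species = occ, slots = slots, p = sum(slots))
}

#' Enumerate labeled/free assignments over a reaction's reactant list
#'
#' Stoichiometric counts are first expanded into repeated ordered slots
#' (`A + A` gives two slots), untracked reactants are removed, and the
#' remaining `p` tracked monomer slots across all reactant occurrences are
#' assigned labeled or free in all `2^p` combinations. The first assignment
#' is all-free, the last all-labeled.
#'
#' @param reaction An [reaction()] object.
#' @param network The `sl_network` declaring the species (tracked flags and
#'   compositions).
#' @return List of class `sl_assignments`: `occurrences` (base species per
#'   reactant occurrence), `slots` (tracked slots per occurrence), `p`,
#'   `patterns` (`2^p` slot patterns) and `variant_lists` (one character
#'   vector of labeled/free reactant names per assignment).
#' @export
enumerate_reactant_assignments <- function(reaction, network) {
  occ <- .tracked_occurrences(reaction$reactants, network)
  pats <- .patterns(occ$p)
  ends <- cumsum(occ$slots)
  starts <- ends - occ$slots + 1L
  variant_lists <- lapply(pats, function(pat) {
    vapply(seq_along(occ$species), function(i)
      .variant_name(occ$species[i], substr(pat, starts[i], ends[i])),
      "")
  })
  structure(list(source_reaction = reaction$id,
                 occurrences = occ$species, slots = occ$slots, p = occ$p,
                 patterns = pats, variant_lists = variant_lists),
            class = "sl_assignments")
}

#' Flux weight of one labeled/free assignment
#'
#' The labeled counterpart of a reaction carries the original flux scaled
#' by the ratio of the product of the assigned labeled/free reactant
#' concentrations to the product of the original reactant concentrations.
#' Whenever the denominator falls below `atol` the weight is defined as 0:
#' for mass-action kinetics the original flux vanishes with any factor, and
#' for other rate laws this is the conservative continuous extension.
#'
#' @param variants Character vector of labeled/free reactant names (one
#'   assignment, e.g. one element of `variant_lists`).
#' @param bases Character vector of the original reactant occurrence names.
#' @param state Named concentration vector containing both.
#' @param atol Zero-denominator guard.
#' @return Weight in `[0, 1]`.
#' @export
labeled_flux_weight <- function(variants, bases, state, atol = 1e-10) {
  denom <- prod(state[bases])
  if (!is.finite(denom) || denom < atol) return(0)
  num <- prod(pmax(state[variants], 0))
  num / denom
}

#' Extend a network for label half-life or transit-time computation
#'
#' `extend_for_lhl()` builds the labeled/free subsystem used for the label
#' half-life of `source`: every reaction touching tracked species gets its
#' `2^p` labeled counterparts, and in each of them a labeled product equal
#' to the source species is replaced by its free counterpart, so label can
#' never re-enter the source pool (no double-counting, upstream fluxes
#' excluded).
#'
#' `extend_for_ltt()` builds the subsystem for the label transit-time from
#' `source` to `target`: labeled target products are likewise replaced by
#' their free counterparts and, per removed label, one unit of the
#' artificial returned-label pool `RL` is produced, recording when label
#' reaches the target at least once.
#'
#' Labels flow positionally from reactant slots to product slots (the i-th
#' tracked monomer slot among the reactants maps to the i-th tracked slot
#' among the products); labels on slots without a tracked product slot are
#' destroyed, with one build-time warning per reaction.
#'
#' The original network is untouched and still integrated alongside; the
#' labeled subsystem is slaved to the original fluxes.
#'
#' @param network An `sl_network`.
#' @param source Name of a tracked single entity (the labeled pool).
#' @param target Name of a tracked single entity (LTT only; may equal
#'   `source`).
#' @return An object of class `sl_extended`.
#' @export
extend_for_lhl <- function(network, source) {
  .extend(network, mode = "LHL", source = source, target = NULL)
}

#' @rdname extend_for_lhl
#' @export
extend_for_ltt <- function(network, source, target = source) {
  .extend(network, mode = "LTT", source = source, target = target)
}

.check_tracked_monomer <- function(network, nm, what) {
  s <- network$species[[nm]]
  if (is.null(s)) stop(what, " species '", nm, "' not found")
  if (!s$tracked) stop(what, " species '", nm, "' is not tracked")
  if (length(s$composition) != 1L)
    stop(what, " species '", nm, "' must be a single entity, not a complex")
  invisible(s)
}

.extend <- function(network, mode, source, target) {
  .check_tracked_monomer(network, source, "source")
  if (mode == "LTT") .check_tracked_monomer(network, target, "target")

  tracked <- species_names(network, tracked_only = TRUE)
  variants <- do.call(rbind, lapply(tracked, function(nm)
    enumerate_label_variants(network$species[[nm]])))
  rownames(variants) <- NULL

  labeled_reactions <- list()
  for (r in network$reactions) {
    r_occ <- .tracked_occurrences(r$reactants, network)
    p_occ <- .tracked_occurrences(r$products, network)
    if (r_occ$p == 0L && p_occ$p == 0L) next
    destroyed <- max(0L, r_occ$p - p_occ$p)
    if (destroyed > 0L)
      warning("reaction '", r$id, "': ", destroyed,
              " tracked reactant slot(s) have no tracked product slot; ",
              "their label is destroyed", call. = FALSE)
    asg <- enumerate_reactant_assignments(r, network)
    pends <- cumsum(p_occ$slots)
    pstarts <- pends - p_occ$slots + 1L
    for (j in seq_along(asg$patterns)) {
      rpat <- strsplit(asg$patterns[j], "", fixed = TRUE)[[1L]]
      # positional label flow; surplus product slots are free
      ppat <- rep("F", p_occ$p)
      ncopy <- min(length(rpat), p_occ$p)
      if (ncopy > 0L) ppat[seq_len(ncopy)] <- rpat[seq_len(ncopy)]
      rl <- 0L
      prod_variants <- character(0)
      if (p_occ$p > 0L || length(p_occ$species) > 0L) {
        prod_variants <- vapply(seq_along(p_occ$species), function(i) {
          sl <- ppat[pstarts[i]:pends[i]]
          nm <- p_occ$species[i]
          if (mode == "LHL" && nm == source) sl[sl == "L"] <- "F"
          if (mode == "LTT" && nm == target) {
            nlab <- sum(sl == "L")
            if (nlab > 0L) rl <<- rl + nlab
            sl[sl == "L"] <- "F"
          }
          .variant_name(nm, paste(sl, collapse = ""))
        }, "")
      }
      labeled_reactions[[length(labeled_reactions) + 1L]] <- list(
        source_reaction = r$id,
        pattern = asg$patterns[j],
        reactant_variants = asg$variant_lists[[j]],
        reactant_bases = asg$occurrences,
        product_variants = prod_variants,
        rl = rl)
    }
  }

  structure(list(original = network, variants = variants,
                 labeled_reactions = labeled_reactions,
                 mode = mode, source = source,
                 target = if (mode == "LTT") target else NULL,
                 has_rl = mode == "LTT"),
            class = "sl_extended")
}

#' @export
print.sl_extended <- function(x, ...) {
  cat("<sl_extended> mode ", x$mode, ", source ", x$source,
      if (!is.null(x$target)) paste0(", target ", x$target), "\n",
      "  ", nrow(x$variants), " labeled/free species, ",
      length(x$labeled_reactions), " labeled reactions\n", sep = "")
  invisible(x)
}

# State layout of the extended system: original species, then variants,
# then (LTT) RL. Returns index bookkeeping reused by the rhs and injection.
.extended_layout <- function(ext) {
  sp <- species_names(ext$original)
  vn <- ext$variants$name
  nm <- c(sp, vn, if (ext$has_rl) "RL")
  list(names = nm, n_orig = length(sp), orig = seq_along(sp),
       var = length(sp) + seq_along(vn),
       rl = if (ext$has_rl) length(sp) + length(vn) + 1L else NA_integer_)
}

# RHS of the joint original+labeled system. The labeled part is slaved to
# the original fluxes via the assignment weights.
.extended_rhs <- function(ext, parameters = NULL) {
  net <- ext$original
  lay <- .extended_layout(ext)
  ev <- .flux_evaluator(net, parameters)
  Snet <- .stoichiometry(net)$net
  rx_index <- stats::setNames(seq_along(net$reactions), names(net$reactions))
  pos <- stats::setNames(seq_along(lay$names), lay$names)
  lr <- lapply(ext$labeled_reactions, function(l) {
    rtab <- table(l$reactant_variants)
    ptab <- table(l$product_variants)
    list(j = rx_index[[l$source_reaction]],
         ridx = pos[l$reactant_variants],           # with repeats, for weight
         bidx = pos[l$reactant_bases],
         r_u = pos[names(rtab)], r_c = as.numeric(rtab),
         p_u = pos[names(ptab)], p_c = as.numeric(ptab),
         rl = l$rl)
  })
  rl_idx <- lay$rl
  n_tot <- length(lay$names)
  atol_guard <- 1e-10
  function(t, state) {
    x <- state[lay$orig]
    v <- ev(t, x)
    d <- numeric(n_tot)
    d[lay$orig] <- Snet %*% v
    xc <- pmax(state, 0)
    for (l in lr) {
      denom <- prod(xc[l$bidx])
      if (denom < atol_guard) next
      w <- prod(xc[l$ridx]) / denom
      fl <- w * v[l$j]
      if (fl == 0) next
      d[l$r_u] <- d[l$r_u] - l$r_c * fl
      d[l$p_u] <- d[l$p_u] + l$p_c * fl
      if (l$rl > 0L) d[rl_idx] <- d[rl_idx] + l$rl * fl
    }
    stats::setNames(d, lay$names)
  }
}

# Initial extended state: free variants mirror the original initial values
# (all-free variant of each tracked species), labeled variants and RL at 0.
.extended_initial <- function(ext, orig_state = NULL) {
  lay <- .extended_layout(ext)
  y <- stats::setNames(numeric(length(lay$names)), lay$names)
  x0 <- if (is.null(orig_state)) initial_state(ext$original) else orig_state
  y[lay$orig] <- x0
  allfree <- ext$variants[grepl("^F*$", ext$variants$pattern), ]
  y[allfree$name] <- x0[allfree$base]
  y
}

#' Export an extended network as a plain reaction network
#'
#' Materialises the labeled/free subsystem as ordinary species and
#' reactions: each labeled reaction's rate law is the original rate law
#' times the ratio of labeled/free to original reactant concentration
#' products (variant names are backtick-quoted in the expressions). The
#' result can be inspected, written with [write_model_yaml()] and
#' re-integrated wherever all original reactant concentrations stay
#' positive; the dedicated integrator used by [inject_and_track()] instead
#' guards the zero-concentration limit.
#'
#' @param ext An `sl_extended`.
#' @return An `sl_network` containing originals, variants and (LTT) `RL`.
#' @export
extended_to_network <- function(ext) {
  net <- ext$original
  sp <- unname(net$species)
  for (i in seq_len(nrow(ext$variants))) {
    v <- ext$variants[i, ]
    sp <- c(sp, list(species(v$name,
                             initial_value = if (grepl("^F*$", v$pattern))
                               net$species[[v$base]]$initial_value else 0)))
  }
  if (ext$has_rl) sp <- c(sp, list(species("RL", 0)))
  btick <- function(x) paste0("`", x, "`")
  rx <- unname(net$reactions)
  for (k in seq_along(ext$labeled_reactions)) {
    l <- ext$labeled_reactions[[k]]
    orig <- net$reactions[[l$source_reaction]]
    num <- paste(btick(l$reactant_variants), collapse = "*")
    den <- paste(btick(l$reactant_bases), collapse = "*")
    rate <- if (length(l$reactant_bases))
      sprintf("(%s)/(%s)*(%s)", num, den, orig$rate_law)
    else orig$rate_law
    reac <- if (length(l$reactant_variants))
      table(l$reactant_variants) else NULL
    prods <- l$product_variants
    ptab <- if (length(prods)) table(prods) else NULL
    if (l$rl > 0L) {
      ptab <- c(as.vector(ptab), l$rl)
      names(ptab) <- c(names(table(prods)), "RL")
    }
    rx <- c(rx, list(reaction(
      paste0(l$source_reaction, "^", l$pattern),
      if (is.null(reac)) NULL else stats::setNames(as.integer(reac), names(reac)),
      ptab, rate)))
  }
  reaction_network(sp, rx, net$parameters, unname(net$inputs))
}
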