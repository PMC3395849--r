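# Species half-life: decay characteristic ignoring all influx, computed by
# augmenting the system with an artificial outflux-only variable.

#' Numerical species half-life
#'
#' Augments the network ODE system with one artificial variable `y` whose
#' derivative collects only the outfluxes of the species of interest,
#' `dy/dt = -sum_j b_ij v_j`, initialised at the species' concentration at
#' the reference time `t0`. In these outflux rate laws `y` takes the place
#' of the species' own concentration (a decay-only clone), while all other
#' species and inputs evolve live alongside, so production terms never
#' enter. The half-life is the time until `y` first crosses half its start
#' value, located by linear interpolation of the integration samples.
#' Except for first-order kinetics it depends on `t0` through the
#' concentration `x(t0)`.
#'
#' @param network An `sl_network`.
#' @param species Name of the species of interest.
#' @param t0 Reference (injection) time; the original system is integrated
#'   from 0 to `t0` first.
#' @param horizon Search window after `t0`. Default (`NULL`) starts from a
#'   first-order guess `ln(2)*x0/outflux(t0)` and expands geometrically up
#'   to 100 times that guess before giving up.
#' @param max_step Sampling step for the crossing search; default is
#'   1/300 of the first-order guess.
#' @param rtol,atol Solver tolerances.
#' @return A list of class `sl_half_life`: `value` (duration or `NA`),
#'   `t0`, `crossing_time`, `defined`, `reason`.
#' @export
species_half_life <- function(network, species, t0 = 0, horizon = NULL,
                              max_step = NULL, rtol = 1e-8, atol = 1e-10) {
  sp <- species_names(network)
  if (!species %in% sp) stop("unknown species '", species, "'")
  y0_state <- initial_state(network)
  if (t0 > 0) {
    pre <- integrate_network(network, c(0, t0), rtol = rtol, atol = atol)
    y0_state[] <- as.numeric(pre[nrow(pre), sp])
  } else if (t0 < 0) stop("t0 must be >= 0")

  x0 <- y0_state[[species]]
  if (x0 <= 0)
    return(.hl_result(t0, NA_real_, NA_real_, FALSE,
                      "species concentration zero at t0"))

  B <- .stoichiometry(network)$reactant
  brow <- B[species, ]
  ev <- .flux_evaluator(network)
  rhs <- build_rhs(network)
  nsp <- length(sp)
  i_sp <- match(species, sp)
  # y is a decay-only clone: its outflux rate laws see y in place of the
  # species itself (influx neglected), while all other species and inputs
  # evolve live
  aug_rhs <- function(t, state) {
    x <- state[seq_len(nsp)]
    xm <- x
    xm[i_sp] <- state[[nsp + 1L]]
    c(rhs(t, x), .y. = -sum(brow * ev(t, xm)))
  }

  out0 <- sum(brow * ev(t0, y0_state))
  if (out0 <= 0 && is.null(horizon))
    return(.hl_result(t0, NA_real_, NA_real_, FALSE,
                      "no initial outflux; half-life unbounded"))
  guess <- if (out0 > 0) log(2) * x0 / out0 else horizon / 10
  if (is.null(max_step)) max_step <- guess / 300
  max_horizon <- if (is.null(horizon)) 100 * guess else horizon

  y0 <- c(y0_state, .y. = x0)
  threshold <- x0 / 2
  t_lo <- t0
  chunk <- min(max_horizon, 5 * guess)
  state_lo <- y0
  repeat {
    t_hi <- min(t0 + max_horizon, t_lo + chunk)
    traj <- .integrate_rhs(aug_rhs, state_lo, c(t_lo, t_hi),
                           max_step = max_step, rtol = rtol, atol = atol)
    tc <- find_crossing(traj$time, traj[[".y."]], threshold, "down")
    if (!is.na(tc))
      return(.hl_result(t0, tc - t0, tc, TRUE, NA_character_))
    if (t_hi >= t0 + max_horizon)
      return(.hl_result(t0, NA_real_, NA_real_, FALSE,
                        "no crossing within horizon"))
    state_lo <- stats::setNames(as.numeric(traj[nrow(traj), -1L]),
                                names(y0))
    t_lo <- t_hi
    chunk <- chunk * 2
  }
}

.hl_result <- function(t0, value, crossing, defined, reason) {
  structure(list(t0 = t0, value = value, crossing_time = crossing,
                 defined = defined, reason = reason),
            class = "sl_half_life")
}

#' @export
print.sl_half_life <- function(x, ...) {
  if (x$defined)
    cat("<sl_half_life> t0 =", x$t0, " value =", signif(x$value, 6), "\n")
  else
    cat("<sl_half_life> t0 =", x$t0, " undefined (", x$reason, ")\n")
  invisible(x)
}

#' Closed-form half-lives of simple isolated processes
#'
#' For a species consumed by a single reaction with no influx:
#' order 0 (`dx/dt = -k`): `x0/(2k)`; order 1: `ln(2)/k`;
#' order 2: `1/(x0 k)`; order n > 1: `(2^(n-1)-1)/((n-1) k x0^(n-1))`;
#' Michaelis-Menten (`dx/dt = -Vmax x/(Km+x)`):
#' `(ln(2) Km + x0/2)/Vmax`.
#'
#' @param kind One of `"order0"`, `"order1"`, `"order2"`, `"orderN"`,
#'   `"michaelis_menten"`.
#' @param params Named list/vector: `k` (rate constant) and, for `orderN`,
#'   `n > 1`; for Michaelis-Menten `Vmax` and `Km`.
#' @param x0 Concentration at the reference time (> 0).
#' @return Half-life duration.
#' @export
analytic_half_life <- function(kind = c("order0", "order1", "order2",
                                        "orderN", "michaelis_menten"),
                               params, x0) {
  kind <- match.arg(kind)
  params <- as.list(params)
  if (!is.numeric(x0) || x0 <= 0) stop("x0 must be > 0")
  pk <- function(nm) {
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || v <= 0)
      stop("parameter '", nm, "' must be > 0 for kind '", kind, "'")
    v
  }
  switch(kind,
    order0 = x0 / (2 * pk("k")),
    order1 = log(2) / pk("k"),
    order2 = 1 / (x0 * pk("k")),
    orderN = {
      n <- pk("n"); k <- pk("k")
      if (n <= 1) stop("orderN requires n > 1")
      (2^(n - 1) - 1) / ((n - 1) * k * x0^(n - 1))
    },
    michaelis_menten = {
      (log(2) * pk("Km") + x0 / 2) / pk("Vmax")
    })
}

#' Michaelis-Menten decay time course (implicit form)
#'
#' Solves `x0 - x + Km*log(x0/x) = Vmax*(t - t0)` for `x` by bracketed
#' root-finding on `(0, x0]`. Serves as an independent oracle for
#' saturating decay curves and for cross-checking the closed-form
#' Michaelis-Menten half-life.
#'
#' @param x0 Concentration at `t0` (> 0).
#' @param Km,Vmax Michaelis constant and maximal rate (> 0).
#' @param t Time(s) at which to evaluate; vectorised.
#' @param t0 Reference time.
#' @return Concentration value(s).
#' @export
michaelis_menten_timecourse <- function(x0, Km, Vmax, t, t0 = 0) {
  stopifnot(x0 > 0, Km > 0, Vmax > 0)
  vapply(t, function(ti) {
    if (ti < t0) stop("t must be >= t0")
    if (ti == t0) return(x0)
    rhs <- Vmax * (ti - t0)
    f <- function(x) x0 - x + Km * log(x0 / x) - rhs
    lo <- x0 * 1e-12
    if (f(lo) < 0)
      stop("root not bracketed: concentration below ", lo, " at t = ", ti)
    stats::uniroot(f, c(lo, x0), tol = 1e-14)$root
  }, numeric(1))
}
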