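# Weighted least-squares calibration and profile-likelihood confidence
# envelopes for the label characteristics.

#' Define an observable
#'
#' An observation function maps the model state to a measured quantity,
#' e.g. a scaled pool `scale_pS*(pS + 2*pS_pS)`. The expression may use
#' species and parameter names (so scaling factors can be estimated like
#' any other parameter).
#'
#' @param name Observable identifier (matched against the dataset).
#' @param expression Expression string over species and parameters.
#' @return An object of class `sl_observable`.
#' @export
observable <- function(name, expression) {
  structure(list(name = name, expression = expression,
                 expr = str2lang(expression)),
            class = "sl_observable")
}

# Evaluate observables on a trajectory; returns a matrix [time x observable].
.evaluate_observables <- function(network, traj, observables) {
  e <- list2env(as.list(traj), parent = baseenv())
  for (nm in names(network$parameters))
    assign(nm, network$parameters[[nm]], envir = e)
  vapply(observables, function(ob) eval(ob$expr, e),
         numeric(nrow(traj)))
}

# Residual closure over log-parameters for the free subset.
.residual_fn <- function(network, observables, dataset, free,
                         rtol, atol, max_step) {
  stopifnot(all(c("observable", "time", "value", "sd") %in% names(dataset)))
  if (any(dataset$sd <= 0)) stop("dataset sd values must be > 0")
  obs_names <- vapply(observables, `[[`, "", "name")
  bad <- setdiff(unique(dataset$observable), obs_names)
  if (length(bad)) stop("dataset references unknown observable(s): ",
                        paste(bad, collapse = ", "))
  t_end <- max(dataset$time)
  times <- sort(unique(dataset$time))
  row_t <- match(dataset$time, times)
  row_o <- match(dataset$observable, obs_names)
  function(logp) {
    p <- exp(logp)
    net <- set_parameters(network, p)
    traj <- tryCatch(
      integrate_network(net, c(0, t_end), max_step = max_step,
                        rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(traj)) return(rep(1e6, nrow(dataset)))
    # model values exactly at the data times
    at <- as.data.frame(lapply(traj[-1L], function(col)
      stats::approx(traj$time, col, xout = times)$y))
    at$time <- times
    pred <- .evaluate_observables(net, at, observables)
    (pred[cbind(row_t, row_o)] - dataset$value) / dataset$sd
  }
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Fit network parameters to data by weighted least squares
#'
#' Minimises `sum(((model - data)/sd)^2)` with the Levenberg-Marquardt
#' algorithm ([minpack.lm::nls.lm()]) over log-transformed parameters (all
#' rates positive), using a multistart strategy: the declared values plus
#' `n_restarts - 1` log-uniform perturbations within one decade, seeded for
#' reproducibility.
#'
#' @param network An `sl_network` whose current parameter values are the
#'   starting point.
#' @param observables List of [observable()] objects.
#' @param dataset Data frame with columns `observable`, `time`, `value`,
#'   `sd`.
#' @param free Names of the parameters to estimate; others stay fixed.
#' @param n_restarts Total number of starts (>= 1).
#' @param seed Integer seed for the restart perturbations.
#' @param rtol,atol,max_step Solver settings used during fitting.
#' @return List of class `sl_fit`: `parameters` (full parameter vector with
#'   the fitted values), `chisq`, `free`, `converged`, `starts` (chi-square
#'   per start).
#' @export
fit_parameters <- function(network, observables, dataset, free,
                           n_restarts = 10, seed = 1,
                           rtol = 1e-7, atol = 1e-9, max_step = NULL) {
  stopifnot(length(free) >= 1L, all(free %in% names(network$parameters)))
  if (is.null(max_step)) max_step <- max(dataset$time) / 100
  p_full <- network$parameters
  start0 <- log(p_full[free])
  starts <- list(start0)
  if (n_restarts > 1L)
    starts <- c(starts, .with_seed(seed, lapply(seq_len(n_restarts - 1L),
      function(i) start0 + log(10) * stats::runif(length(free), -1, 1))))
  best <- NULL
  chis <- numeric(length(starts))
  for (i in seq_along(starts)) {
    fitres <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], fn = .free_resfn(
        network, observables, dataset, free, rtol, atol, max_step),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    chis[i] <- if (is.null(fitres)) Inf else fitres$deviance
    if (!is.null(fitres) && (is.null(best) || fitres$deviance < best$deviance))
      best <- fitres
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p_hat <- p_full
  p_hat[free] <- exp(best$par)
  structure(list(parameters = p_hat, chisq = best$deviance, free = free,
                 converged = best$info %in% 1:4, starts = chis),
            class = "sl_fit")
}

# Residual function over the log of the free parameters only.
.free_resfn <- function(network, observables, dataset, free,
                        rtol, atol, max_step) {
  p_full <- network$parameters
  stat_fn <- .residual_fn(network, observables, dataset, free,
                          rtol, atol, max_step)
  # .residual_fn expects the full log-parameter vector; wrap it
  function(logk) {
    logp <- log(p_full)
    logp[free] <- logk
    stat_fn(logp)
  }
}

#' @export
print.sl_fit <- function(x, ...) {
  cat("<sl_fit> chisq =", signif(x$chisq, 6), "\n")
  print(signif(x$parameters[x$free], 4))
  invisible(x)
}

#' Profile likelihood of one parameter
#'
#' Scans the profiled parameter over a log-spaced grid (by default 21
#' points spanning 0.01 to 100 times its fitted value), refitting all other
#' free parameters at each grid point (continuation from the neighbouring
#' fit). Grid intervals in which the profile crosses
#' `chisq_best + threshold` are refined by bisection (`refine_levels`
#' rounds, each with a refit), and the refined settings closest to the
#' threshold on either side are recorded as the confidence-bound parameter
#' settings.
#'
#' @param network An `sl_network`.
#' @param observables,dataset As in [fit_parameters()].
#' @param parameter Name of the profiled parameter.
#' @param free Names of all free parameters (must contain `parameter`).
#' @param fit An `sl_fit` from [fit_parameters()]; its parameters are the
#'   profile center.
#' @param n_points Grid size.
#' @param span Multiplicative range around the fitted value, default
#'   `c(0.01, 100)`.
#' @param threshold Chi-square offset delimiting the confidence region;
#'   3.84 is the 95% quantile of chi-square with 1 degree of freedom
#'   (separate, pointwise interval).
#' @param refine_levels Bisection rounds per crossing interval.
#' @param rtol,atol,max_step Solver settings.
#' @return List of class `sl_profile`: `parameter`, `points` (data frame
#'   `value`, `chisq`, plus refit parameters), `chisq_best`, `threshold`,
#'   and `crossings` (list of full parameter vectors at the confidence
#'   bounds).
#' @export
profile_likelihood <- function(network, observables, dataset, parameter,
                               free, fit, n_points = 21,
                               span = c(0.01, 100), threshold = 3.84,
                               refine_levels = 2,
                               rtol = 1e-7, atol = 1e-9, max_step = NULL) {
  stopifnot(parameter %in% free)
  if (is.null(max_step)) max_step <- max(dataset$time) / 100
  others <- setdiff(free, parameter)
  k_fit <- fit$parameters[[parameter]]
  net0 <- set_parameters(network, fit$parameters)

  refit <- function(k_value, start_pars) {
    p <- start_pars
    p[parameter] <- k_value
    net <- set_parameters(net0, p)
    if (length(others) == 0L) {
      res <- .free_resfn(net, observables, dataset, parameter,
                         rtol, atol, max_step)(log(k_value))
      return(list(chisq = sum(res^2), parameters = net$parameters))
    }
    fr <- tryCatch(
      minpack.lm::nls.lm(par = log(p[others]),
                         fn = .free_resfn(net, observables, dataset, others,
                                          rtol, atol, max_step),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fr)) return(list(chisq = NA_real_, parameters = p))
    p[others] <- exp(fr$par)
    list(chisq = fr$deviance, parameters = p)
  }

  grid <- k_fit * 10^seq(log10(span[1]), log10(span[2]),
                         length.out = n_points)
  i_center <- which.min(abs(log(grid / k_fit)))
  vals <- numeric(n_points); chis <- rep(NA_real_, n_points)
  pars <- vector("list", n_points)
  # scan outwards from the center with continuation
  for (half in list(i_center:n_points, rev(seq_len(i_center)))) {
    start <- fit$parameters
    for (i in half) {
      r <- refit(grid[i], start)
      vals[i] <- grid[i]; chis[i] <- r$chisq; pars[[i]] <- r$parameters
      if (!is.na(r$chisq)) start <- r$parameters
    }
  }
  level <- fit$chisq + threshold
  crossings <- list()
  for (i in seq_len(n_points - 1L)) {
    if (is.na(chis[i]) || is.na(chis[i + 1L])) next
    if ((chis[i] - level) * (chis[i + 1L] - level) < 0) {
      lo <- list(value = grid[i], chisq = chis[i], parameters = pars[[i]])
      hi <- list(value = grid[i + 1L], chisq = chis[i + 1L],
                 parameters = pars[[i + 1L]])
      for (lev in seq_len(refine_levels)) {
        mid_v <- sqrt(lo$value * hi$value)
        r <- refit(mid_v, if ((lo$chisq < level)) lo$parameters
                          else hi$parameters)
        mid <- list(value = mid_v, chisq = r$chisq,
                    parameters = r$parameters)
        if (is.na(mid$chisq)) break
        if ((lo$chisq - level) * (mid$chisq - level) < 0) hi <- mid
        else lo <- mid
      }
      pick <- if (abs(lo$chisq - level) < abs(hi$chisq - level)) lo else hi
      crossings[[length(crossings) + 1L]] <- pick$parameters
    }
  }
  pts <- data.frame(value = vals, chisq = chis)
  structure(list(parameter = parameter, points = pts,
                 parameters = pars, chisq_best = fit$chisq,
                 threshold = threshold, crossings = crossings),
            class = "sl_profile")
}

#' @export
print.sl_profile <- function(x, ...) {
  cat("<sl_profile> parameter ", x$parameter, ", ",
      nrow(x$points), " points, ", length(x$crossings),
      " threshold crossing(s)\n", sep = "")
  invisible(x)
}

#' Profile-likelihood confidence envelope of a label characteristic
#'
#' Recomputes the LHL or LTT curve for every parameter setting at which a
#' profile likelihood crosses the chi-square confidence threshold, plus the
#' best fit, and takes the pointwise minimum and maximum — the envelope
#' displayed as confidence band around the characteristic.
#'
#' @param network An `sl_network`.
#' @param profiles List of `sl_profile` objects (their `crossings` supply
#'   the admitted parameter settings).
#' @param characteristic `"LHL"` or `"LTT"`.
#' @param source,target Labeled source (and, for LTT, target) species.
#' @param protocol An [injection_protocol()] or numeric injection times.
#' @param fit An `sl_fit`; the best-fit curve is always part of the family.
#' @param rtol,atol Solver tolerances for the curve recomputation.
#' @return Data frame of class `sl_envelope` with columns `t_inject`,
#'   `lower`, `best`, `upper`, `n_defined`; attribute `n_settings`.
#' @export
confidence_envelope <- function(network, profiles,
                                characteristic = c("LHL", "LTT"),
                                source, target = source, protocol, fit,
                                rtol = 1e-7, atol = 1e-9) {
  characteristic <- match.arg(characteristic)
  if (!inherits(protocol, "sl_protocol"))
    protocol <- injection_protocol(protocol)
  if (inherits(profiles, "sl_profile")) profiles <- list(profiles)
  settings <- list(fit$parameters)
  for (pr in profiles) settings <- c(settings, pr$crossings)
  if (length(settings) == 1L)
    warning("no profile threshold crossings; envelope has zero width",
            call. = FALSE)
  curves <- lapply(settings, function(p) {
    net <- set_parameters(network, p)
    if (characteristic == "LHL")
      label_half_life_curve(net, source, protocol, rtol = rtol, atol = atol)
    else
      label_transit_time_curve(net, source, target, protocol,
                               rtol = rtol, atol = atol)
  })
  vals <- sapply(curves, `[[`, "value")
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  out <- data.frame(
    t_inject = protocol$injection_times,
    lower = apply(vals, 1L, function(r) if (all(is.na(r))) NA_real_
                                        else min(r, na.rm = TRUE)),
    best = curves[[1L]]$value,
    upper = apply(vals, 1L, function(r) if (all(is.na(r))) NA_real_
                                        else max(r, na.rm = TRUE)),
    n_defined = apply(vals, 1L, function(r) sum(!is.na(r))))
  structure(out, class = c("sl_envelope", "data.frame"),
            characteristic = characteristic, source = source,
            target = if (characteristic == "LTT") target else NULL,
            n_settings = length(settings))
}

#' @export
print.sl_envelope <- function(x, ...) {
  cat("<sl_envelope> ", attr(x, "characteristic"), " over ",
      attr(x, "n_settings"), " parameter setting(s)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
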