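# Fitting toys are kept tiny (one- or two-parameter decay models) so the
# optimizer and profiling machinery are exercised in seconds.

test_that("chi-square is zero when the data equal the model output", {
  prob <- make_decay_fit_problem(k = 0.7)
  dat <- generate_synthetic_data(prob$network, prob$observables,
                                 seq(0.5, 4, 0.5), noise_sd = 0)
  dat$sd <- 0.05
  fit <- fit_parameters(prob$network, prob$observables, dat, free = "k",
                        n_restarts = 1)
  # residual floor set by the two integration grids, not the optimizer
  expect_lt(fit$chisq, 1e-4)
  expect_equal(unname(fit$parameters[["k"]]), 0.7, tolerance = 1e-3)
})

test_that("exponential-decay fit agrees with log-linear regression", {
  prob <- make_decay_fit_problem(k = 0.7, x0 = 2)
  tgrid <- seq(0.5, 4, 0.5)
  dat <- generate_synthetic_data(prob$network, prob$observables, tgrid,
                                 noise_sd = 0, seed = 3)
  # multiplicative perturbation so the log-scale regression is exact-form
  noise <- withr::with_seed(5, exp(rnorm(length(tgrid), 0, 0.02)))
  dat$value <- dat$value * noise
  # constant RELATIVE error makes weighted LS equivalent to log-scale LS
  # to first order in the noise amplitude
  dat$sd <- 0.02 * dat$value
  start <- set_parameters(prob$network, c(k = 0.3))
  fit <- fit_parameters(start, prob$observables, dat, free = "k",
                        n_restarts = 1)
  k_reg <- -coef(lm(log(dat$value / 2) ~ 0 + dat$time))[[1]]
  expect_equal(unname(fit$parameters[["k"]]), k_reg, tolerance = 1e-3)
})

test_that("multistart fitting is deterministic given the seed", {
  prob <- make_decay_fit_problem(k = 0.7)
  dat <- generate_synthetic_data(prob$network, prob$observables,
                                 seq(0.5, 4, 0.5), noise_sd = 0.05, seed = 2)
  start <- set_parameters(prob$network, c(k = 2))
  f1 <- fit_parameters(start, prob$observables, dat, free = "k",
                       n_restarts = 4, seed = 9)
  f2 <- fit_parameters(start, prob$observables, dat, free = "k",
                       n_restarts = 4, seed = 9)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$starts, f2$starts)
})

test_that("profiles are flat for structurally non-identifiable parameters", {
  # two rate constants acting through their product only: k*s*X with
  # observable X — (k, s) has a scaling redundancy
  net <- reaction_network(
    list(species("X", 2, tracked = TRUE), species("P", 0)),
    list(reaction("out", c(X = 1), c(P = 1), "k*s*X")),
    parameters = c(k = 0.5, s = 1.4))
  obs <- list(observable("X_obs", "X"))
  dat <- generate_synthetic_data(net, obs, seq(0.5, 4, 0.5),
                                 noise_sd = 0.02, seed = 4)
  fit <- fit_parameters(net, obs, dat, free = c("k", "s"), n_restarts = 1)
  prof <- profile_likelihood(net, obs, dat, "k", free = c("k", "s"),
                             fit = fit, n_points = 9)
  dchi <- prof$points$chisq - fit$chisq
  expect_lt(max(abs(dchi), na.rm = TRUE), 1e-3)
  expect_length(prof$crossings, 0L)
})

test_that("identifiable profiles cross the 95% threshold on both sides", {
  prob <- make_decay_fit_problem(k = 0.7)
  dat <- generate_synthetic_data(prob$network, prob$observables,
                                 seq(0.5, 4, 0.5), noise_sd = 0.05, seed = 6)
  fit <- fit_parameters(prob$network, prob$observables, dat, free = "k",
                        n_restarts = 2, seed = 1)
  prof <- profile_likelihood(prob$network, prob$observables, dat, "k",
                             free = "k", fit = fit, n_points = 15,
                             refine_levels = 8)
  expect_length(prof$crossings, 2L)
  # profile minimum coincides with the fit
  expect_gte(min(prof$points$chisq, na.rm = TRUE), fit$chisq - 1e-6)
  # admitted settings bracket the fitted value and sit near the threshold
  ks <- vapply(prof$crossings, `[[`, 0, "k")
  expect_true(min(ks) < fit$parameters[["k"]] &&
                max(ks) > fit$parameters[["k"]])
  level <- fit$chisq + prof$threshold
  for (p in prof$crossings) {
    net <- set_parameters(prob$network, p)
    res <- silabel:::.free_resfn(net, prob$observables, dat, "k",
                                 1e-7, 1e-9, max(dat$time) / 100)(
                                   log(p[["k"]]))
    expect_lt(abs(sum(res^2) - level), 1.0)
  }
})

test_that("envelopes contain the best fit and widen with noise", {
  prob <- make_decay_fit_problem(k = 0.7)
  proto <- injection_protocol(c(0, 1, 2), horizon = 15, max_step = 0.02)
  env_for <- function(noise) {
    dat <- generate_synthetic_data(prob$network, prob$observables,
                                   seq(0.5, 4, 0.5), noise_sd = noise,
                                   seed = 8)
    fit <- fit_parameters(prob$network, prob$observables, dat, free = "k",
                          n_restarts = 1)
    prof <- profile_likelihood(prob$network, prob$observables, dat, "k",
                               free = "k", fit = fit, n_points = 15)
    suppressWarnings(confidence_envelope(
      prob$network, prof, "LHL", "X", protocol = proto, fit = fit))
  }
  lo <- env_for(0.02)
  hi <- env_for(0.10)
  expect_true(all(lo$lower <= lo$best + 1e-12 &
                    lo$best <= lo$upper + 1e-12))
  expect_true(all(hi$upper - hi$lower >= lo$upper - lo$lower - 1e-9))
  expect_gt(mean(hi$upper - hi$lower), mean(lo$upper - lo$lower))
})

test_that("a fit with no admitted settings yields a zero-width envelope", {
  prob <- make_decay_fit_problem(k = 0.7)
  dat <- generate_synthetic_data(prob$network, prob$observables,
                                 seq(0.5, 4, 0.5), noise_sd = 0.05, seed = 2)
  fit <- fit_parameters(prob$network, prob$observables, dat, free = "k",
                        n_restarts = 1)
  empty <- structure(list(parameter = "k", crossings = list()),
                     class = "sl_profile")
  env <- NULL
  w <- capture_warnings(
    env <- confidence_envelope(prob$network, empty, "LHL", "X",
                               protocol = injection_protocol(
                                 0, horizon = 10, max_step = 0.02),
                               fit = fit))
  expect_true(any(grepl("zero width", w)))
  expect_equal(env$lower, env$upper)
})
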