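test_that("build_rhs assembles product-minus-reactant flux sums", {
  net <- reaction_network(
    list(species("A", 1, tracked = TRUE), species("B", 0)),
    list(reaction("r1", c(A = 1), c(B = 1), "k*A")),
    parameters = c(k = 0.5))
  rhs <- build_rhs(net)
  d <- rhs(0, c(A = 2, B = 0))
  expect_equal(unname(d), c(-1, 1))
  tr <- integrate_network(net, c(0, 3))
  expect_lt(max(abs(tr$A + tr$B - 1)), 1e-8)
})

test_that("JAK-STAT right-hand side matches the model equations", {
  net <- build_jakstat()
  st <- c(S = 0.5, pS = 0.3, pS_pS = 0.1, npS_npS = 0.05, nS = 0.2)
  t <- 5
  pR <- net$inputs$pR$fun(t)
  p <- net$parameters
  d <- build_rhs(net)(t, st)
  expect_equal(d[["S"]], -p[["k1"]] * 0.5 * pR + p[["k5"]] * 0.2)
  # dimerization consumes pS with coefficient 2, produces one dimer
  expect_equal(d[["pS"]],
               p[["k1"]] * 0.5 * pR - 2 * p[["k2"]] * 0.3^2)
  expect_equal(d[["pS_pS"]], p[["k2"]] * 0.3^2 - p[["k3"]] * 0.1)
  expect_equal(d[["npS_npS"]], p[["k3"]] * 0.1 - p[["k4"]] * 0.05)
  expect_equal(d[["nS"]], 2 * p[["k4"]] * 0.05 - p[["k5"]] * 0.2)
})

test_that("integration reproduces closed forms and honors max_step", {
  net <- make_decay_network("k*X")
  tr <- integrate_network(net, c(0, 1))
  expect_rel_equal(tr$X[nrow(tr)], exp(-1), 1e-7)
  expect_lte(max(diff(tr$time)), attr(tr, "max_step") * (1 + 1e-9))
  # order-2 decay has closed form 1/(1+t)
  tr2 <- integrate_network(make_decay_network("k*X^2"), c(0, 1))
  expect_rel_equal(tr2$X[nrow(tr2)], 0.5, 1e-7)
  # zero-flux network stays constant
  net0 <- reaction_network(
    list(species("A", 1), species("B", 2)),
    list(reaction("r1", c(A = 1), c(B = 1), "0*A")))
  tr0 <- integrate_network(net0, c(0, 5))
  expect_equal(range(tr0$A), c(1, 1))
})

test_that("evaluate_fluxes computes rate laws at given state", {
  net <- reaction_network(
    list(species("A", 2), species("B", 3), species("X", 1)),
    list(reaction("ma", c(A = 1, B = 1), NULL, "k*A*B"),
         reaction("mm", c(X = 1), NULL, "Vmax*X/(Km+X)")),
    parameters = c(k = 0.5, Vmax = 2, Km = 1))
  v <- evaluate_fluxes(net, 0, c(A = 2, B = 3, X = 1))
  expect_equal(unname(v[["ma"]]), 3.0)
  expect_equal(unname(v[["mm"]]), 1.0)  # half-saturation at X = Km
  expect_error(evaluate_fluxes(net, 0, c(A = 1, B = 1)), "state length")
})

test_that("unresolvable rate-law symbols are rejected by name", {
  expect_error(
    reaction_network(
      list(species("A", 1)),
      list(reaction("r1", c(A = 1), NULL, "k_missing*A"))),
    "k_missing")
})

test_that("non-finite fluxes raise an error naming the reaction", {
  net <- reaction_network(
    list(species("A", 1)),
    list(reaction("bad", c(A = 1), NULL, "k/A")),
    parameters = c(k = 1))
  expect_error(evaluate_fluxes(net, 0, c(A = 0)), "bad")
})

test_that("first-order networks scale time inversely with rate constants", {
  cross_time <- function(kval) {
    net <- make_chain_network(k = kval)
    tr <- integrate_network(net, c(0, 10 / kval))
    find_crossing(tr$time, tr$A, 0.3, "down")
  }
  expect_rel_equal(cross_time(2), cross_time(1) / 2, 1e-6)
})

test_that("numerically differentiated trajectories match the rhs", {
  net <- build_jakstat()
  tr <- integrate_network(net, c(0, 10), max_step = 0.002)
  rhs <- build_rhs(net)
  sp <- species_names(net)
  i <- seq(50, nrow(tr) - 1, by = 200)
  for (j in i) {
    h <- tr$time[j + 1] - tr$time[j - 1]
    fd <- (as.numeric(tr[j + 1, sp]) - as.numeric(tr[j - 1, sp])) / h
    an <- rhs(tr$time[j], as.numeric(tr[j, sp]))
    expect_lt(max(abs(fd - an)), 1e-4 * max(1, max(abs(an))))
  }
})

test_that("input functions interpolate and extrapolate as declared", {
  f <- input_function("u", c(0, 1, 2), c(0, 1, 0), "linear")
  expect_equal(f$fun(0.5), 0.5)
  expect_equal(f$fun(-1), 0)   # constant extrapolation
  expect_equal(f$fun(5), 0)
  g <- input_function("u", seq(0, 2, 0.1), sin(seq(0, 2, 0.1)), "cubic")
  expect_lt(abs(g$fun(1.05) - sin(1.05)), 1e-4)
  expect_error(input_function("u", c(0, 0, 1), c(1, 2, 3)), "increasing")
})

test_that("model YAML round-trips", {
  net <- build_jakstat()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(net, path)
  net2 <- read_model_yaml(path)
  expect_equal(species_names(net2), species_names(net))
  expect_equal(net2$parameters, net$parameters)
  expect_equal(net2$species$pS_pS$composition, c("pS", "pS"))
  tr1 <- integrate_network(net, c(0, 5))
  tr2 <- integrate_network(net2, c(0, 5))
  expect_equal(tr2$pS, tr1$pS, tolerance = 1e-10)
})
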