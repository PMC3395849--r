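# Small fixture networks built in code.

# Isolated decay X -> P with a configurable rate law.
make_decay_network <- function(rate, x0 = 1, params = c(k = 1)) {
  reaction_network(
    list(species("X", x0, tracked = TRUE), species("P", 0)),
    list(reaction("out", c(X = 1), c(P = 1), rate)),
    parameters = params)
}

# Decay plus an influx reaction (for influx-invariance and dilution checks).
make_influx_network <- function(rate_out, rate_in, x0 = 1,
                                params = c(k = 1)) {
  reaction_network(
    list(species("X", x0, tracked = TRUE), species("P", 0)),
    list(reaction("in", NULL, c(X = 1), rate_in),
         reaction("out", c(X = 1), c(P = 1), rate_out)),
    parameters = params)
}

# First-order chain A -> B -> C, all species tracked.
make_chain_network <- function(k = 1, a0 = 1) {
  reaction_network(
    list(species("A", a0, tracked = TRUE),
         species("B", 0, tracked = TRUE),
         species("C", 0, tracked = TRUE)),
    list(reaction("r1", c(A = 1), c(B = 1), "k*A"),
         reaction("r2", c(B = 1), c(C = 1), "k*B")),
    parameters = c(k = k))
}

# One-parameter exponential decay with an observable, for fitting toys.
make_decay_fit_problem <- function(k = 0.7, x0 = 2) {
  net <- make_decay_network("k*X", x0 = x0, params = c(k = k))
  list(network = net, observables = list(observable("X_obs", "X")))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
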