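test_that("label variant enumeration follows combinatorial multiplicity", {
  mono <- enumerate_label_variants(species("S", tracked = TRUE))
  expect_equal(mono$name, c("S^F", "S^L"))
  dimer <- enumerate_label_variants(
    species("pS_pS", tracked = TRUE, composition = c("pS", "pS")))
  expect_equal(dimer$name,
               c("pS^F_pS^F", "pS^L_pS^F", "pS^F_pS^L", "pS^L_pS^L"))
  trimer <- enumerate_label_variants(
    species("A3", tracked = TRUE, composition = c("A", "A", "A")))
  expect_equal(nrow(trimer), 8L)
  expect_error(enumerate_label_variants(species("U", tracked = FALSE)),
               "not tracked")
})

# the worked dimer-plus-monomers example: reactants (A, A, pA_pA)
aa_dimer_network <- function() {
  reaction_network(
    list(species("A", 1, tracked = TRUE),
         species("pA", 0, tracked = TRUE),
         species("pA_pA", 1, tracked = TRUE, composition = c("pA", "pA")),
         species("A_A_pA_pA", 0, tracked = TRUE,
                 composition = c("A", "A", "pA", "pA"))),
    list(reaction("cplx", c(A = 2, pA_pA = 1), c(A_A_pA_pA = 1),
                  "k*A*A*pA_pA")),
    parameters = c(k = 1))
}

test_that("reactant assignments expand stoichiometry into ordered slots", {
  net <- aa_dimer_network()
  asg <- enumerate_reactant_assignments(net$reactions$cplx, net)
  expect_equal(asg$p, 4L)
  expect_equal(length(asg$variant_lists), 16L)
  expect_equal(asg$variant_lists[[1]], c("A^F", "A^F", "pA^F_pA^F"))
  expect_equal(asg$variant_lists[[2]], c("A^L", "A^F", "pA^F_pA^F"))
  expect_equal(asg$variant_lists[[16]], c("A^L", "A^L", "pA^L_pA^L"))
  # single monomer reactant: two assignments
  net1 <- make_decay_network("k*X")
  asg1 <- enumerate_reactant_assignments(net1$reactions$out, net1)
  expect_equal(asg1$variant_lists, list("X^F", "X^L"))
  # pure production: a single all-free assignment
  net2 <- make_influx_network("k*X", "0.2")
  asg2 <- enumerate_reactant_assignments(net2$reactions[["in"]], net2)
  expect_equal(asg2$p, 0L)
  expect_equal(length(asg2$variant_lists), 1L)
})

test_that("flux weights partition proportionally and sum to one", {
  # full labeling: all-L assignment carries the whole flux
  st <- c(S = 1, `S^L` = 1, `S^F` = 0)
  expect_equal(labeled_flux_weight("S^L", "S", st), 1)
  expect_equal(labeled_flux_weight("S^F", "S", st), 0)
  # half/half monomer
  st2 <- c(S = 1, `S^L` = 0.5, `S^F` = 0.5)
  expect_equal(labeled_flux_weight("S^L", "S", st2), 0.5)
  # dimerization with pS^L = 0.3, pS^F = 0.7
  st3 <- c(pS = 1, `pS^L` = 0.3, `pS^F` = 0.7)
  w <- sapply(list(c("pS^F", "pS^F"), c("pS^L", "pS^F"),
                   c("pS^F", "pS^L"), c("pS^L", "pS^L")),
              labeled_flux_weight, bases = c("pS", "pS"), state = st3)
  expect_equal(w, c(0.49, 0.21, 0.21, 0.09))
  expect_equal(sum(w), 1)
  # zero-denominator rule
  expect_equal(labeled_flux_weight("S^L", "S", c(S = 0, `S^L` = 0)), 0)
})

test_that("weights over randomized consistent states always sum to one", {
  net <- aa_dimer_network()
  asg <- enumerate_reactant_assignments(net$reactions$cplx, net)
  variants <- do.call(rbind, lapply(c("A", "pA_pA"), function(nm)
    enumerate_label_variants(net$species[[nm]])))
  withr::with_seed(42, for (rep in 1:25) {
    st <- numeric(0)
    # random positive variant concentrations; originals as their sums
    for (base in c("A", "pA_pA")) {
      vn <- variants$name[variants$base == base]
      v <- stats::runif(length(vn), 0.05, 2)
      st[vn] <- v
      st[base] <- sum(v)
    }
    w <- vapply(asg$variant_lists, labeled_flux_weight, 0,
                bases = asg$occurrences, state = st)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  })
})

test_that("LHL extension prohibits label re-entry into the source pool", {
  # A -> S -> P chain: the reaction producing S must emit free S only
  net <- reaction_network(
    list(species("A", 1, tracked = TRUE), species("S", 1, tracked = TRUE),
         species("P", 0)),
    list(reaction("prod", c(A = 1), c(S = 1), "k*A"),
         reaction("cons", c(S = 1), c(P = 1), "k*S")),
    parameters = c(k = 1))
  ext <- suppressWarnings(extend_for_lhl(net, "S"))
  prod_lab <- Filter(function(l) l$source_reaction == "prod" &&
                       l$pattern == "L", ext$labeled_reactions)
  expect_length(prod_lab, 1L)
  expect_equal(prod_lab[[1]]$product_variants, "S^F")
  expect_equal(prod_lab[[1]]$rl, 0L)
  # untracked source/complex rejected
  expect_error(extend_for_lhl(net, "P"), "not tracked")
  jak <- build_jakstat()
  expect_error(extend_for_lhl(jak, "pS_pS"), "single entity")
})

test_that("LTT extension accumulates one RL unit per returned label", {
  net <- build_jakstat()
  ext <- extend_for_ltt(net, "S", "S")
  # nuclear export of labeled nS returns the label and frees the molecule
  exp_lab <- Filter(function(l) l$source_reaction == "r5" &&
                      l$pattern == "L", ext$labeled_reactions)
  expect_equal(exp_lab[[1]]$product_variants, "S^F")
  expect_equal(exp_lab[[1]]$rl, 1L)
  # dissociation of a doubly-labeled nuclear dimer yields two labeled nS
  dis <- Filter(function(l) l$source_reaction == "r4" &&
                  l$pattern == "LL", ext$labeled_reactions)
  expect_equal(sort(dis[[1]]$product_variants), c("nS^L", "nS^L"))
  expect_equal(dis[[1]]$rl, 0L)
})

test_that("all label injected into a closed chain eventually returns", {
  net <- make_chain_network()
  ext <- extend_for_ltt(net, "A", "C")
  run <- inject_and_track(ext, 0, 30, max_step = 0.02)
  expect_equal(tail(run$post$RL, 1), 1, tolerance = 1e-6)
  # total label + RL conserved throughout
  lab <- run$post[["A^L"]] + run$post[["B^L"]] + run$post$RL
  expect_lt(max(abs(lab - run$injected)), 1e-8)
})

test_that("extended network exports to a plain re-integrable model", {
  # strictly positive reactant concentrations so the exported
  # concentration-ratio rate laws are well defined from t = 0 on
  net <- reaction_network(
    list(species("A", 1, tracked = TRUE),
         species("B", 0.5, tracked = TRUE),
         species("C", 0, tracked = TRUE)),
    list(reaction("r1", c(A = 1), c(B = 1), "k*A"),
         reaction("r2", c(B = 1), c(C = 1), "k*B")),
    parameters = c(k = 1))
  ext <- extend_for_ltt(net, "A", "C")
  flat <- extended_to_network(ext)
  expect_true(all(c("A^L", "B^F", "RL") %in% species_names(flat)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(flat, path)
  flat2 <- read_model_yaml(path)
  # re-integrated exported network reproduces the injected-at-0 dynamics
  flat2$species$`A^L`$initial_value <- 1
  flat2$species$`A^F`$initial_value <- 0
  tr <- integrate_network(flat2, c(0, 5))
  run <- inject_and_track(ext, 0, 5, max_step = attr(tr, "max_step"))
  expect_equal(tr$RL, run$post$RL, tolerance = 1e-7)
})

test_that("labeling an untracked-product reaction destroys label with a warning", {
  net <- make_decay_network("k*X")  # P is untracked
  expect_warning(extend_for_lhl(net, "X"), "destroyed")
})
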