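# Network construction, TSV round trips, and mass-action kinetics.

test_that("a reversible pair expands into two irreversible columns with the expected S", {
  net <- fixture_isomerization(k_f = 1, k_r = 1)
  expect_equal(nrow(net$species), 2L)
  expect_equal(ncol(net$S), 2L)
  expect_equal(unname(net$S), matrix(c(-1, 1, 1, -1), 2))
  expect_equal(net$reactions$parent_id, c("r1", "r1"))
})

test_that("mixed reversible/irreversible tables expand to the right column count", {
  # 339 reversible + 172 irreversible declared rows -> 850 columns
  n_rev <- 339L; n_irr <- 172L
  sp <- tibble::tibble(name = c("X", "Y"), initial_nM = c(1, 1))
  rx <- tibble::tibble(
    id = paste0("r", seq_len(n_rev + n_irr)),
    reactants = "X", products = "Y",
    reversible = rep(c(TRUE, FALSE), c(n_rev, n_irr)),
    k_forward = 1, k_reverse = rep(c(1, NA), c(n_rev, n_irr)))
  net <- crn_network(sp, rx)
  expect_equal(ncol(net$S), 850L)
  expect_equal(length(net$k), 850L)
})

test_that("validation errors name the offender", {
  sp <- tibble::tibble(name = c("A", "B"), initial_nM = c(1, 0))
  bad_species <- tibble::tibble(id = "r1", reactants = "A + X",
                                products = "B", reversible = FALSE,
                                k_forward = 1)
  expect_error(crn_network(sp, bad_species), "X")
  expect_error(crn_network(sp, bad_species), "r1")
  bad_k <- tibble::tibble(id = "r1", reactants = "A", products = "B",
                          reversible = FALSE, k_forward = -2)
  expect_error(crn_network(sp, bad_k), "positive")
  dup <- tibble::tibble(name = c("A", "A"), initial_nM = c(1, 1))
  expect_error(crn_network(dup, bad_k[0, ]), "duplicate")
})

test_that("mass-action fluxes follow the product-of-reactants rule", {
  f1 <- fixture_isomerization(k_f = 1, k_r = 1)
  expect_equal(unname(mass_action_fluxes(f1, c(A = 2, B = 3))), c(2, 3))

  # bimolecular flux: A + K with k = 5, x_A = 1, x_K = 2 -> 10
  sp <- tibble::tibble(name = c("A", "K", "AK"), initial_nM = c(1, 2, 0))
  rx <- tibble::tibble(id = "b", reactants = "A + K", products = "AK",
                       reversible = FALSE, k_forward = 5)
  net <- crn_network(sp, rx)
  expect_equal(unname(mass_action_fluxes(net, c(1, 2, 0))), 10)
  # zero-concentration reactant kills the flux
  expect_equal(unname(mass_action_fluxes(net, c(0, 2, 7))), 0)
  # stoichiometric powers: 2 X -> flux k * x^2
  rx2 <- tibble::tibble(id = "d", reactants = "2 A", products = "AK",
                        reversible = FALSE, k_forward = 3)
  net2 <- crn_network(sp, rx2)
  expect_equal(unname(mass_action_fluxes(net2, c(4, 0, 0))), 3 * 16)
  expect_error(mass_action_fluxes(net, c(-1, 2, 0)), "negative")
})

test_that("ode_rhs is S v and vanishes at equilibrium and on constant species", {
  f1 <- fixture_isomerization(k_f = 1, k_r = 1)
  expect_equal(unname(ode_rhs(f1, c(2, 3))), c(1, -1))
  # equilibrium of the isomerization: x_B/x_A = k_f/k_r
  f12 <- fixture_isomerization(k_f = 2, k_r = 1)
  expect_equal(unname(ode_rhs(f12, c(A = 1, B = 2))), c(0, 0))
  # constant species rows are identically zero
  sp <- tibble::tibble(name = c("E", "A", "B"), initial_nM = c(1, 1, 0),
                       constant = c(1, 0, 0))
  rx <- tibble::tibble(id = "r", reactants = "E + A", products = "E + B",
                       reversible = FALSE, k_forward = 2)
  net <- crn_network(sp, rx)
  expect_equal(unname(net$S["E", ]), 0)
  for (x in list(c(1, 1, 0), c(1, 5, 2), c(3, 0.1, 7)))
    expect_equal(ode_rhs(net, x)[["E"]], 0)
})

test_that("flux homogeneity: scaling a first-order reactant scales the flux", {
  net <- fixture_phospho_cycle()
  x <- c(A = 2, K = 3, P = 1, `A*` = 0.5, AK = 0.2, `A*P` = 0.1)
  v1 <- mass_action_fluxes(net, x)
  x2 <- x; x2["A"] <- 4 * x["A"]
  v2 <- mass_action_fluxes(net, x2)
  expect_equal(v2[["bind_f"]], 4 * v1[["bind_f"]])
  expect_equal(v2[["cat"]], v1[["cat"]])
})

test_that("TSV write/read round trip is lossless, including reversible re-merge", {
  dir <- withr::local_tempdir()
  net <- fixture_phospho_cycle(k = c(1.5, 0.5, 2, 1, 0.25, 3))
  write_crn(net, dir)
  net2 <- read_crn(dir)
  expect_equal(net2$S, net$S)
  expect_equal(net2$A, net$A)
  expect_equal(net2$k, net$k)
  expect_equal(net2$species, net$species)
  expect_equal(net2$reactions$parent_id, net$reactions$parent_id)
})

test_that("empty reactant sets are accepted as zero-order boundary fluxes", {
  sp <- tibble::tibble(name = "A", initial_nM = 0)
  rx <- tibble::tibble(id = "in", reactants = "", products = "A",
                       reversible = FALSE, k_forward = 0.7)
  expect_message(net <- crn_network(sp, rx), "zero-order")
  expect_equal(unname(mass_action_fluxes(net, 5)), 0.7)
  expect_equal(unname(ode_rhs(net, 5)), 0.7)
})
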