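# Conservation-law enumeration, elemental structure, exactness.

test_that("isomerization has the single generator (1, 1)", {
  net <- fixture_isomerization()
  gens <- semipositive_generators(net$S)
  expect_length(gens, 1L)
  expect_equal(gens[[1L]], c(A = 1, B = 1))
})

test_that("phospho cycle generators have the three expected supports", {
  net <- fixture_phospho_cycle()
  cs <- conservation_laws(net)
  expect_equal(cs$p, 3L)
  supports <- lapply(cs$generators, function(g) sort(names(g)[g != 0]))
  expect_true(list(sort(c("A", "A*", "AK", "A*P"))) %in% supports ||
                any(vapply(supports, identical, TRUE, sort(c("A", "A*", "AK", "A*P")))))
  expect_true(any(vapply(supports, identical, TRUE, sort(c("AK", "K")))))
  expect_true(any(vapply(supports, identical, TRUE, sort(c("A*P", "P")))))
  expect_true(all(unlist(cs$generators) %in% c(0, 1)))
  # p = n - rank(S): 6 species, rank 3
  expect_equal(cs$rank_S, 3L)
  expect_true(cs$basis_ok)
})

test_that("N S = 0 exactly and generators match the brute-force oracle", {
  nets <- list(fixture_isomerization(), fixture_phospho_cycle(),
               random_conservative_crn(2, 5, seed = 11),
               random_conservative_crn(3, 7, seed = 12),
               random_conservative_crn(4, 6, seed = 13))
  for (net in nets) {
    cs <- conservation_laws(net)
    if (cs$p > 0L)
      expect_true(all(cs$N %*% net$S == 0))
    expect_same_rays(cs$generators, oracle_semipositive_rays(net$S))
  }
})

test_that("verify_conservation_vector is an exact kernel test", {
  f1 <- fixture_isomerization()
  expect_true(verify_conservation_vector(f1, c(1, 1)))
  expect_false(verify_conservation_vector(f1, c(1, 0)))
  f2 <- fixture_phospho_cycle()
  expect_true(verify_conservation_vector(f2, c(A = 1, `A*` = 1, AK = 1, `A*P` = 1)))
  expect_false(verify_conservation_vector(f2, c(A = 1, `A*` = 1)))
})

test_that("elemental selection is deterministic and one-law-per-species", {
  cs <- conservation_laws(fixture_phospho_cycle())
  expect_true(cs$is_weakly_elemented)
  expect_true(cs$is_elemented)
  expect_equal(cs$elemental, c("A", "K", "P"))
  # each elemental species appears in exactly one generator's support
  for (s in cs$elemental)
    expect_equal(sum(cs$N[, s] != 0), 1L)
  # N = [I_p, N2] under the elemental permutation
  expect_equal(unname(cs$N[, cs$elemental]), diag(3))
  expect_equal(unname(cs$N2),
               rbind(c(1, 1, 1), c(0, 1, 0), c(0, 0, 1)))
})

test_that("a lone non-unit generator leaves the network un-elemented", {
  # 3A <-> 2B: gamma = (2, 3), no unit column in N
  sp <- tibble::tibble(name = c("A", "B"), initial_nM = c(1, 0))
  rx <- tibble::tibble(id = "r", reactants = "3 A", products = "2 B",
                       reversible = TRUE, k_forward = 1, k_reverse = 1)
  net <- crn_network(sp, rx)
  cs <- conservation_laws(net)
  expect_equal(cs$p, 1L)
  expect_equal(cs$generators[[1L]], c(A = 2, B = 3))
  expect_false(cs$is_weakly_elemented)
  expect_error(ideal_state(cs, 1), "elemented")
  expect_error(elemental_solve(cs, 1, numeric(0)), "elemented")
})

test_that("elemental_solve inverts the conservation relations", {
  cs <- conservation_laws(fixture_phospho_cycle())
  # x2 = 0 reproduces the ideal state values
  expect_equal(elemental_solve(cs, c(10, 5, 5), c(`A*` = 0, AK = 0, `A*P` = 0)),
               c(A = 10, K = 5, P = 5))
  expect_equal(elemental_solve(cs, c(10, 5, 5), c(`A*` = 2, AK = 1, `A*P` = 3)),
               c(A = 4, K = 4, P = 2))
  # infeasible x2 surfaces as a negative elemental entry
  x1 <- elemental_solve(cs, c(1, 1, 1), c(`A*` = 2, AK = 0, `A*P` = 0))
  expect_lt(x1[["A"]], 0)
})

test_that("conservativity matches support coverage", {
  expect_true(is_conservative(fixture_phospho_cycle()))
  expect_true(is_conservative(random_conservative_crn(3, 5, seed = 4)))
  # open degradation A -> nothing: no semi-positive law covers A
  sp <- tibble::tibble(name = "A", initial_nM = 1)
  rx <- tibble::tibble(id = "deg", reactants = "A", products = "",
                       reversible = FALSE, k_forward = 1)
  open_net <- crn_network(sp, rx)
  expect_false(is_conservative(open_net))
  expect_length(semipositive_generators(open_net$S), 0L)
})

test_that("constant species yield trivial laws flagged as such", {
  sp <- tibble::tibble(name = c("E", "A", "B"), initial_nM = c(2, 1, 0),
                       constant = c(1, 0, 0))
  rx <- tibble::tibble(id = "r", reactants = "E + A", products = "E + B",
                       reversible = FALSE, k_forward = 1)
  cs <- conservation_laws(crn_network(sp, rx))
  expect_equal(cs$p, 2L)
  expect_equal(sum(cs$trivial), 1L)
  triv <- which(cs$trivial)
  expect_equal(names(which(cs$N[triv, ] != 0)), "E")
})

test_that("excess generators disable elemental operations with a warning", {
  net <- fixture_isomerization()
  expect_warning(
    cs <- build_conservation_set(net, list(c(A = 1, B = 1), c(A = 2, B = 2))),
    "not a basis")
  expect_false(cs$basis_ok)
  expect_false(cs$is_weakly_elemented)
})
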