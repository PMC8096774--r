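# LoF/GoF projection operators and their composition.

f2 <- fixture_phospho_cycle()
cs2 <- conservation_laws(f2)

test_that("LoF projection zeroes the moiety and redistributes shared compounds", {
  x <- c(A = 4, K = 4, P = 2, `A*` = 2, AK = 1, `A*P` = 3)
  out <- lof_project(cs2, x, "K")
  expect_equal(out, c(A = 5, K = 0, P = 2, `A*` = 2, AK = 0, `A*P` = 3))
  # note A *increased*: it reclaimed the molecule bound in AK
  expect_gt(out[["A"]], x[["A"]])
  # idempotence
  expect_equal(lof_project(cs2, out, "K"), out)
  # ideal states: only the target concentration changes
  xi <- ideal_state(cs2, c(10, 5, 5))
  expect_equal(lof_project(cs2, xi, "K"),
               c(A = 10, K = 0, P = 5, `A*` = 0, AK = 0, `A*P` = 0))
})

test_that("LoF is rejected for non-elemental targets", {
  expect_error(lof_project(cs2, ideal_state(cs2, c(1, 1, 1)), "AK"), "elemental")
  expect_error(lof_project(cs2, ideal_state(cs2, c(1, 1, 1)), "nope"), "elemental")
})

test_that("LoF maps classes to classes: c~ = c with the target entry zeroed", {
  for (seed in 1:5) {
    c_vec <- c(4, 3, 2)
    x <- sample_class_point(cs2, c_vec, seed = seed)
    y <- sample_class_point(cs2, c_vec, seed = seed + 100)
    px <- lof_project(cs2, x, "A")
    py <- lof_project(cs2, y, "A")
    expect_equal(unname(class_of(cs2, px)), c(0, 3, 2))
    expect_equal(class_of(cs2, px), class_of(cs2, py))
  }
})

test_that("GoF zeroes columns, keeps k, and is idempotent", {
  H <- c("debind_f", "decat")
  mnet <- gof_project(f2, H)
  expect_equal(unname(mnet$S[, H]), matrix(0, 6, 2))
  expect_equal(mnet$S[, setdiff(colnames(f2$S), H)],
               f2$S[, setdiff(colnames(f2$S), H)])
  expect_equal(mnet$k, f2$k)
  expect_equal(dim(mnet$S), dim(f2$S))
  expect_equal(gof_project(mnet, H)$S, mnet$S)
  # zeroing everything gives the zero matrix
  allz <- gof_project(f2, colnames(f2$S))
  expect_true(all(allz$S == 0))
  expect_warning(gof_project(f2, character(0)), "no-op")
})

test_that("rank preservation certifies unchanged conservation structure", {
  expect_true(check_rank_preserved(f2, character(0))$preserved)
  # the deactivation block of A* preserves rank 3
  rk <- check_rank_preserved(f2, c("debind_f", "decat"), cs2)
  expect_true(rk$preserved)
  expect_equal(rk$rank_original, 3L)
  expect_true(rk$kernel_certified)
  # removing one direction of the isomerization keeps rank 1
  f1 <- fixture_isomerization()
  expect_true(check_rank_preserved(f1, "r1_f")$preserved)
  # zeroing the whole phosphatase side (binding, release, catalysis) drops rank
  rk2 <- check_rank_preserved(f2, c("debind_f", "debind_r", "decat"))
  expect_false(rk2$preserved)
  expect_equal(rk2$rank_mutated, 2L)
})

test_that("deactivation_reactions recovers the phosphatase pattern", {
  expect_setequal(deactivation_reactions(f2, "A*"), c("debind_f", "decat"))
  # a terminal species with no consuming reactions
  sp <- tibble::tibble(name = c("A", "B"), initial_nM = c(1, 0))
  rx <- tibble::tibble(id = "r", reactants = "A", products = "B",
                       reversible = FALSE, k_forward = 1)
  net <- crn_network(sp, rx)
  expect_warning(H <- deactivation_reactions(net, "B"), "no consuming")
  expect_length(H, 0L)
})

test_that("an empty mutation spec is the identity", {
  res <- apply_mutation_spec(f2, cs2, mutation_spec(), x_e = ideal_state(cs2, c(10, 5, 5)))
  expect_equal(res$network$S, f2$S)
  expect_equal(res$x0, ideal_state(cs2, c(10, 5, 5)))
  expect_true(res$rank_preserved)
})

test_that("LoF order does not change the mutated class", {
  x_e <- integrate_to_steady(f2, t_end = 1e6)$x_e
  a <- apply_mutation_spec(f2, cs2, mutation_spec(lof = c("A", "K")), x_e)
  b <- apply_mutation_spec(f2, cs2, mutation_spec(lof = c("K", "A")), x_e)
  expect_equal(a$class, b$class)
  expect_equal(unname(a$class), c(0, 0, unname(class_of(cs2, x_e))[3L]))
})

test_that("rank-dropping GoF stamps the result as class-changing", {
  spec <- mutation_spec(gof = list(c("debind_f", "debind_r", "decat")))
  expect_warning(res <- apply_mutation_spec(f2, cs2, spec), "rank")
  expect_true(res$scc_changing)
})

test_that("direct and iterative mutation routes coincide for a single mutation", {
  x_e <- integrate_to_steady(f2, t_end = 1e6)$x_e
  spec <- mutation_spec(lof = "K")
  direct <- apply_mutation_spec(f2, cs2, spec, x_e)
  ss_direct <- integrate_to_steady(direct$network, direct$x0, t_end = 1e6)
  path <- iterative_mutation_path(f2, cs2, spec, x_e, t_end = 1e6)
  expect_equal(nrow(path), 1L)
  final <- attr(path, "final")
  expect_lt(max(abs(final - ss_direct$x_e)) / (1 + max(ss_direct$x_e)), 1e-6)
  # analytic endpoint: the kinase arm is dead, all A-moiety free
  c_e <- class_of(cs2, x_e)
  expect_equal(unname(ss_direct$x_e), c(c_e[[1L]], 0, c_e[[3L]], 0, 0, 0),
               tolerance = 1e-6)
})

test_that("permuted mutation orders reach the same endpoint on a random fixture", {
  net <- random_conservative_crn(3, 4, seed = 21)
  cs <- conservation_laws(net)
  x_e <- integrate_to_steady(net, t_end = 1e6, conservation = cs)$x_e
  spec <- mutation_spec(lof = cs$elemental[1:2])
  finals <- lapply(list(1:2, 2:1), function(ord)
    attr(iterative_mutation_path(net, cs, spec, x_e, order = ord, t_end = 1e6),
         "final"))
  expect_lt(max(abs(finals[[1L]] - finals[[2L]])) / (1 + max(finals[[1L]])), 1e-6)
})
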