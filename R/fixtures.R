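# Built-in example networks with known analytic structure.
#
# These small networks carry their own ground truth (conservation-law
# generators, elemental species, and -- where available -- closed-form
# steady states), so every other component can be exercised and checked
# without any external data.

#' Reversible isomerization A <-> B ("FIX1")
#'
#' The smallest reversible network: one moiety, one conservation law
#' `A + B = c`, and the closed-form steady state
#' `A_e = c k_r / (k_f + k_r)`, `B_e = c k_f / (k_f + k_r)` -- a linear
#' system with a provably unique, globally stable equilibrium per class.
#'
#' @param k_f,k_r forward/reverse rate constants (defaults 1, 1).
#' @param a0,b0 initial concentrations, nM (defaults 1, 0).
#' @return a `crn` object with 2 species and 2 irreversible columns.
#' @export
fixture_isomerization <- function(k_f = 1, k_r = 1, a0 = 1, b0 = 0) {
  crn_network(
    species = tibble(name = c("A", "B"), initial_nM = c(a0, b0),
                     constant = FALSE),
    reactions = tibble(id = "r1", reactants = "A", products = "B",
                       reversible = TRUE, k_forward = k_f, k_reverse = k_r)
  )
}

#' Phosphorylation/dephosphorylation futile cycle ("FIX2")
#'
#' The canonical kinase/phosphatase motif: a substrate `A` is activated
#' by a kinase `K` (`A + K <-> AK -> A* + K`) and deactivated by a
#' phosphatase `P` (`A* + P <-> A*P -> A + P`).  Six species, six
#' irreversible columns, three conservation laws with supports
#' `{A, A*, AK, A*P}`, `{K, AK}`, `{P, A*P}`, elemental species
#' `{A, K, P}`; the network is elemented and conservative.
#'
#' @param k numeric vector of 6 rate constants for the columns
#'   (`bind_f`, `bind_r`, `cat`, `debind_f`, `debind_r`, `decat`),
#'   default all 1.
#' @param c0 totals for the three moieties (A, K, P), default
#'   `c(10, 5, 5)` nM, used as the ideal initial state.
#' @return a `crn` object.
#' @export
fixture_phospho_cycle <- function(k = c(1, 1, 1, 1, 1, 1),
                                  c0 = c(10, 5, 5)) {
  stopifnot(length(k) == 6L, all(k > 0), length(c0) == 3L)
  crn_network(
    species = tibble(name = c("A", "K", "P", "A*", "AK", "A*P"),
                     initial_nM = c(c0[1], c0[2], c0[3], 0, 0, 0),
                     constant = FALSE),
    reactions = tibble(
      id = c("bind", "cat", "debind", "decat"),
      reactants = c("A + K", "AK", "A* + P", "A*P"),
      products = c("AK", "A* + K", "A*P", "A + P"),
      reversible = c(TRUE, FALSE, TRUE, FALSE),
      k_forward = c(k[1], k[3], k[4], k[6]),
      k_reverse = c(k[2], NA, k[5], NA)
    )
  )
}

#' Random conservative network built from binding and conversion motifs
#'
#' Generates a mass-action network whose conservation structure is known
#' by construction.  Starting from `n_moieties` free species (one per
#' moiety), each added motif either reversibly binds two existing species
#' into a new complex (`X + Y <-> XY`) or reversibly converts an existing
#' species into a modified form (`X <-> X'`).  Every species then carries
#' at least one moiety, the network is elemented and conservative, and
#' the extreme rays of the conservation cone are exactly the per-moiety
#' counting vectors, returned as the attribute `moiety_matrix`
#' (`n_moieties` x n).
#'
#' Random matrices almost never have sign-constrained left kernels, which
#' is why the generator composes motifs instead.
#'
#' @param n_moieties number of moieties / free species (>= 1).
#' @param n_motifs number of added motif species; total species count is
#'   `n_moieties + n_motifs`.
#' @param seed integer seed.
#' @param p_conversion probability that a motif is a conversion rather
#'   than a binding (default 0.3; forced conversion when only one species
#'   exists).
#' @param k_range range for log-uniform rate-constant draws (default
#'   `c(0.1, 10)`).
#' @return a `crn` object with attribute `moiety_matrix` (ground-truth
#'   generator matrix, moieties x species).
#' @export
random_conservative_crn <- function(n_moieties = 3, n_motifs = 5, seed = 1,
                                    p_conversion = 0.3,
                                    k_range = c(0.1, 10)) {
  stopifnot(n_moieties >= 1L, n_motifs >= 0L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  names <- paste0("M", seq_len(n_moieties))
  moiety <- diag(n_moieties)           # columns grow with species
  colnames(moiety) <- names
  rx <- list()
  draw_k <- function() 10^runif(1L, log10(k_range[1L]), log10(k_range[2L]))
  for (t in seq_len(n_motifs)) {
    convert <- length(names) < 2L || runif(1L) < p_conversion
    if (convert) {
      x <- sample(names, 1L)
      new <- paste0(x, "p")
      while (new %in% names) new <- paste0(new, "p")
      rx[[length(rx) + 1L]] <- tibble(
        id = paste0("m", t), reactants = x, products = new,
        reversible = TRUE, k_forward = draw_k(), k_reverse = draw_k())
      moiety <- cbind(moiety, moiety[, x, drop = FALSE])
    } else {
      pair <- sample(names, 2L)
      new <- paste0("C", t)
      rx[[length(rx) + 1L]] <- tibble(
        id = paste0("m", t),
        reactants = paste(pair[1L], "+", pair[2L]), products = new,
        reversible = TRUE, k_forward = draw_k(), k_reverse = draw_k())
      moiety <- cbind(moiety, moiety[, pair[1L]] + moiety[, pair[2L]])
    }
    colnames(moiety)[ncol(moiety)] <- new
    names <- c(names, new)
  }
  init <- c(round(runif(n_moieties, 0.5, 5), 2), numeric(n_motifs))
  net <- crn_network(
    species = tibble(name = names, initial_nM = init, constant = FALSE),
    reactions = if (length(rx)) dplyr::bind_rows(rx) else
      tibble(id = "m1", reactants = names[1L], products = names[1L],
             reversible = FALSE, k_forward = 1)[0, ]
  )
  rownames(moiety) <- paste0("gamma_", seq_len(n_moieties))
  attr(net, "moiety_matrix") <- moiety
  net
}
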