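# Stoichiometric compatibility classes (SCCs).
#
# Trajectories of dx/dt = S v(x,k) are confined to (x0 + span S) %i% R^n_+,
# equivalently to {y >= 0 : N y = N x0} when the generators form a basis of
# ker(S^T).  The invariant vector c = N x therefore identifies a class, and
# points within one class can be constructed deterministically (ideal
# state) or sampled randomly (the Monte-Carlo stability protocol).

#' Class invariants of a state
#'
#' Returns `c = N x`, the total moiety concentrations identifying the
#' stoichiometric compatibility class of `x`.
#'
#' @param cs a `crn_conservation` object.
#' @param x concentration vector (named or in species-table order).
#' @return numeric vector of length `p`, named by law.
#' @export
class_of <- function(cs, x) {
  stopifnot(inherits(cs, "crn_conservation"))
  x <- order_state(cs, x)
  drop(cs$N %*% x)
}

#' Do two states share a compatibility class?
#'
#' `TRUE` iff `max|N x - N y| <= tol * (1 + max|N x|)`.
#'
#' @inheritParams class_of
#' @param y second concentration vector.
#' @param tol relative tolerance (default `1e-6`).
#' @export
same_class <- function(cs, x, y, tol = 1e-6) {
  cx <- class_of(cs, x)
  cy <- class_of(cs, y)
  max(abs(cx - cy)) <= tol * (1 + max(abs(cx)))
}

#' Ideal state of a class
#'
#' The state in which only the elemental species are populated: the
#' elemental species of law `j` takes the full total `c_j`, every
#' secondary (compound) species is 0, and species in no law are 0.
#'
#' @param cs a `crn_conservation` object (weakly elemented).
#' @param c class invariants, length `p`, non-negative.
#' @return named concentration vector in species-table order.
#' @export
ideal_state <- function(cs, c) {
  stopifnot(inherits(cs, "crn_conservation"))
  if (!cs$is_weakly_elemented)
    abort("ideal states need a weakly elemented network")
  if (length(c) != cs$p || any(c < 0)) abort("c must be non-negative, length p")
  x <- setNames(numeric(nrow(cs$species)), cs$species$name)
  x[cs$elemental] <- as.numeric(c)
  x
}

#' Sample a random state within a compatibility class
#'
#' Draws one point of `{x >= 0 : N x = c}` by the sequential scheme used
#' in the numerical global-stability protocol:
#' 1. species in no conservation law get log10-uniform values on
#'    `unconserved_range`;
#' 2. the non-elemental conserved species are visited in a random
#'    permutation; each is set to `u * min_{j in Gamma(i)} c_j / gamma_ji`
#'    with `u ~ U(0,1)` and the *residual* totals `c_j` are then reduced
#'    by `gamma_ji * x_i`;
#' 3. each elemental species absorbs the residual total of its unique law.
#'
#' Constant (inflow) species keep their declared values and are excluded
#' from the random draws; their trivial laws are forced consistent with
#' those values.  By construction `N x = c` to machine precision and
#' `x >= 0`.
#'
#' @param cs a `crn_conservation` object (weakly elemented).
#' @param c class invariants, length `p`, non-negative.
#' @param seed optional integer; when given, the draw is made reproducible
#'   without disturbing the caller's RNG state.
#' @param unconserved_range range for stage-1 draws (default `c(1e-5, 1e5)`
#'   nM, log10-uniform).
#' @return named concentration vector with `N x = c`.
#' @export
sample_class_point <- function(cs, c, seed = NULL,
                               unconserved_range = c(1e-5, 1e5)) {
  stopifnot(inherits(cs, "crn_conservation"))
  if (!cs$is_weakly_elemented)
    abort("class sampling needs a weakly elemented network")
  if (length(c) != cs$p || any(c < 0)) abort("c must be non-negative, length p")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  sp <- cs$species$name
  const <- cs$species$constant
  x <- setNames(numeric(length(sp)), sp)
  c_res <- as.numeric(c)

  # constant species: declared values, their (trivial) laws made consistent
  if (any(const)) {
    x[const] <- cs$species$initial_nM[const]
    for (j in which(cs$trivial)) {
      supp <- which(cs$N[j, ] != 0)
      c_res[j] <- cs$N[j, supp] * x[supp]
    }
  }

  # stage 1: unconserved species
  for (s in setdiff(cs$unconserved, sp[const])) {
    lo <- log10(unconserved_range[1L]); hi <- log10(unconserved_range[2L])
    x[s] <- 10^runif(1L, lo, hi)
  }

  # stage 2: secondary conserved species, random order, residual update
  sec <- setdiff(sp[colSums(cs$N != 0) > 0], c(cs$elemental, sp[const]))
  if (length(sec) > 1L) sec <- sample(sec)
  for (s in sec) {
    i <- match(s, sp)
    Gi <- which(cs$N[, i] != 0)
    x[s] <- runif(1L) * min(c_res[Gi] / cs$N[Gi, i])
    c_res[Gi] <- pmax(c_res[Gi] - cs$N[Gi, i] * x[s], 0)
  }

  # stage 3: elemental species take the residuals of their unique laws
  for (j in seq_len(cs$p)) {
    s <- cs$elemental[j]
    if (const[match(s, sp)]) next
    x[s] <- c_res[j]
  }
  x
}

# reorder a possibly-named state vector into species-table order
order_state <- function(cs, x) {
  sp <- cs$species$name
  if (!is.null(names(x))) {
    miss <- setdiff(sp, names(x))
    if (length(miss)) abort(paste0("state is missing species: ",
                                   paste(miss, collapse = ", ")))
    x <- x[sp]
  }
  if (length(x) != length(sp)) abort("state has the wrong length")
  as.numeric(x)
}
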