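# Mutation projection operators.
#
# A null loss-of-function (LoF) mutation of an elemental species zeroes
# that species' total moiety: the state projector sets every compound
# carrying the moiety to zero and re-solves the conservation relations for
# the elemental part, so other elemental species may *increase* (they
# reclaim molecules freed from shared compounds).  A gain-of-function
# (GoF) mutation removes the deactivation reactions of a constitutively
# active protein: a column-zeroing projector on S that leaves the species
# set, the state space and the rate-constant vector untouched.

#' Loss-of-function state projection
#'
#' Projects a state `x` onto the class in which the `target` elemental
#' species' total is zero: every secondary species containing the target's
#' moiety (`gamma_ji != 0`) is set to 0, the invariant vector `c = N x`
#' has its `j`-th entry zeroed, and the elemental part is recomputed as
#' `x1 = c~ - N2 x2~`.  Applied to an ideal state this reduces to setting
#' the target's own concentration to zero.  The operator is idempotent and
#' maps compatibility classes to compatibility classes.
#'
#' @param cs a `crn_conservation` object (weakly elemented).
#' @param x concentration vector (named or species order), non-negative.
#' @param target name (or index into `cs$elemental`) of the elemental
#'   species losing function.
#' @return named concentration vector in species-table order.
#' @export
lof_project <- function(cs, x, target) {
  stopifnot(inherits(cs, "crn_conservation"))
  if (!cs$is_weakly_elemented)
    abort("LoF projection needs a weakly elemented network")
  if (is.numeric(target)) target <- cs$elemental[target]
  j <- match(target, cs$elemental)
  if (is.na(j))
    abort(paste0("'", target, "' is not an elemental species: ",
                 "LoF mutations are defined only for elemental species"))
  sp <- cs$species$name
  x <- setNames(order_state(cs, x), sp)
  if (any(x < 0)) abort("state must be non-negative")
  ct <- drop(cs$N %*% x)
  ct[j] <- 0
  sec <- colnames(cs$N2)
  x2 <- x[sec]
  x2[cs$N2[j, ] != 0] <- 0
  x1 <- as.numeric(ct) - drop(cs$N2 %*% x2)
  out <- x
  out[cs$elemental] <- x1
  out[sec] <- x2
  pmax(out, 0)
}

#' Gain-of-function stoichiometric projection
#'
#' Returns the network whose stoichiometric matrix has the columns in `H`
#' set to zero -- the reactions in `H` (the deactivation reactions of the
#' gained protein) are removed while species, state space and rate
#' constants are kept, so the operation is exactly invertible and
#' idempotent.
#'
#' @param net a `crn` object.
#' @param H reaction ids (character) or column indices to zero.
#' @return the mutated `crn` object; `zeroed_reactions` records the
#'   cumulative set of zeroed columns.
#' @export
gof_project <- function(net, H) {
  stopifnot(inherits(net, "crn"))
  if (length(H) == 0L) {
    warn("empty reaction set: GoF projection is a no-op")
    return(net)
  }
  idx <- resolve_reactions(net, H)
  net$S[, idx] <- 0
  net$zeroed_reactions <- union(net$zeroed_reactions, colnames(net$S)[idx])
  net
}

resolve_reactions <- function(net, H) {
  if (is.character(H)) {
    idx <- match(H, colnames(net$S))
    if (anyNA(idx))
      abort(paste0("unknown reaction id(s): ",
                   paste(H[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(H)
    if (any(idx < 1L | idx > ncol(net$S))) abort("reaction index out of range")
  }
  idx
}

#' Does a GoF projection preserve the conservation structure?
#'
#' Checks the rank condition `rank(G_H(S)) = rank(S)` with exact integer
#' arithmetic.  When it holds, `ker(G_H(S)^T) = ker(S^T)`, so the mutated
#' network has the same conservation laws and the same compatibility
#' classes as the original; the certificate verifies each original
#' generator against the projected matrix.  When it fails, the projected
#' network defines *different* classes and the order-independence
#' guarantees for composed mutations no longer apply.
#'
#' @param net a `crn` object (the unmutated network).
#' @param H reaction ids or indices to zero.
#' @param cs optional `crn_conservation` object for the certificate.
#' @return list with `preserved` (logical), `rank_original`,
#'   `rank_mutated`, and `kernel_certified` (logical, `NA` without `cs`).
#' @export
check_rank_preserved <- function(net, H, cs = NULL) {
  stopifnot(inherits(net, "crn"))
  S2 <- net$S
  if (length(H)) S2[, resolve_reactions(net, H)] <- 0
  r0 <- integer_rank(net$S)
  r1 <- integer_rank(S2)
  cert <- NA
  if (r1 == r0 && !is.null(cs)) {
    cert <- all(vapply(cs$generators, function(g)
      all(drop(crossprod(S2, order_state(cs, g))) == 0), TRUE))
  }
  list(preserved = r1 == r0, rank_original = r0, rank_mutated = r1,
       kernel_certified = cert)
}

#' Declare a set of mutations
#'
#' Bundles an ordered list of LoF targets (elemental species names) and
#' GoF reaction sets.  The order is recorded for trajectory-level studies
#' but -- provided the composed GoF projection preserves rank and all the
#' systems involved are globally stable per class -- the final steady
#' state does not depend on it.
#'
#' @param lof character vector of elemental species names (may be empty).
#' @param gof list of reaction-id/index vectors, one per GoF mutation
#'   (may be empty).
#' @return an object of class `crn_mutation_spec`.
#' @export
mutation_spec <- function(lof = character(0), gof = list()) {
  if (is.character(gof) || is.numeric(gof)) gof <- list(gof)
  structure(list(lof = as.character(lof), gof = gof),
            class = "crn_mutation_spec")
}

#' @export
print.crn_mutation_spec <- function(x, ...) {
  cat("<crn_mutation_spec>", length(x$lof), "LoF,", length(x$gof), "GoF\n")
  if (length(x$lof)) cat("  LoF:", paste(x$lof, collapse = ", "), "\n")
  for (h in x$gof) cat("  GoF reactions:", paste(h, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a mutation set in one shot
#'
#' Implements the direct (single-step) procedure: the mutated
#' stoichiometric matrix is the composition of all GoF column-zeroing
#' projections, and the initial state is the composition of all LoF
#' projections applied to the physiological steady state `x_e`.
#' Integrating the mutated system from this initial state yields the
#' mutated steady state.  The resulting class invariants equal `N x_e`
#' with every LoF-targeted entry zeroed, independently of order.
#'
#' @param net a `crn` object (physiological network).
#' @param cs its `crn_conservation` structure.
#' @param spec a [mutation_spec()].
#' @param x_e physiological steady state (defaults to the declared
#'   initial concentrations, useful for ideal-state studies).
#' @return list with `network` (mutated `crn`), `x0` (projected state),
#'   `class` (mutated invariants), `rank_preserved`, `scc_changing`
#'   (logical: rank condition failed, so the theorems' order-independence
#'   guarantee is void).
#' @export
apply_mutation_spec <- function(net, cs, spec, x_e = NULL) {
  stopifnot(inherits(net, "crn"), inherits(cs, "crn_conservation"),
            inherits(spec, "crn_mutation_spec"))
  x_e <- as_concentration(net, x_e %||% setNames(net$species$initial_nM,
                                                 net$species$name))
  H_all <- unique(unlist(lapply(spec$gof, function(h)
    colnames(net$S)[resolve_reactions(net, h)])))
  rk <- check_rank_preserved(net, H_all, cs)
  if (!rk$preserved)
    warn("GoF projection changes rank(S): compatibility classes differ and the mutated steady state may depend on mutation order")
  mnet <- net
  for (h in spec$gof) mnet <- gof_project(mnet, h)
  x0 <- x_e
  for (j in spec$lof) x0 <- lof_project(cs, x0, j)
  list(network = mnet, x0 = x0, class = drop(cs$N %*% x0),
       rank_preserved = rk$preserved, scc_changing = !rk$preserved)
}

#' Apply mutations one at a time, re-converging after each
#'
#' The iterative alternative to [apply_mutation_spec()]: each mutation is
#' applied in sequence (`order`, defaulting to all GoF mutations first,
#' then the LoF mutations, as in the one-at-a-time protocol) and the
#' system is re-integrated to its steady state after every step, so the
#' effect of each individual mutation can be quantified.  Under the rank
#' condition and global stability of every intermediate system, the final
#' state equals the direct route's.
#'
#' @inheritParams apply_mutation_spec
#' @param order optional integer permutation of the mutations, indexing
#'   the concatenation `c(gof, lof)` of the spec; default is the identity
#'   (GoF first, then LoF).
#' @param ... passed to [integrate_to_steady()] (e.g. `t_end`, `rtol`).
#' @return tibble with one row per stage: `stage`, `kind` (`"gof"` or
#'   `"lof"`), `label`, `converged`, and a list-column `steady` of the
#'   intermediate steady states; the attribute `final` holds the last one.
#' @export
iterative_mutation_path <- function(net, cs, spec, x_e = NULL, order = NULL,
                                    ...) {
  stopifnot(inherits(spec, "crn_mutation_spec"))
  x_e <- as_concentration(net, x_e %||% setNames(net$species$initial_nM,
                                                 net$species$name))
  muts <- c(lapply(spec$gof, function(h) list(kind = "gof", val = h)),
            lapply(spec$lof, function(j) list(kind = "lof", val = j)))
  m <- length(muts)
  order <- order %||% seq_len(m)
  if (!setequal(order, seq_len(m))) abort("order must be a permutation of the mutations")
  cur_net <- net
  cur_x <- x_e
  rows <- vector("list", m)
  for (s in seq_len(m)) {
    mu <- muts[[order[s]]]
    if (mu$kind == "gof") {
      cur_net <- gof_project(cur_net, mu$val)
      x0 <- cur_x
      label <- paste0("GoF{", paste(mu$val, collapse = ","), "}")
    } else {
      x0 <- lof_project(cs, cur_x, mu$val)
      label <- paste0("LoF(", mu$val, ")")
    }
    ss <- tryCatch(integrate_to_steady(cur_net, x0, ...),
                   error = function(e)
                     abort(paste0("non-convergence at stage ", s, " (", label,
                                  "): ", conditionMessage(e))))
    cur_x <- ss$x_e
    rows[[s]] <- tibble(stage = s, kind = mu$kind, label = label,
                        converged = ss$converged, steady = list(ss$x_e))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "final") <- cur_x
  out
}

#' Suggest the deactivation reactions of an active species
#'
#' Heuristic helper for choosing the GoF reaction set `H`: returns the
#' reactions consuming the active species whose products do not contain
#' it (e.g. binding to a phosphatase), plus the downstream conversion
#' steps of the intermediates so formed (e.g. the complex releasing the
#' inactive form).  This mirrors the usual kinase/phosphatase deactivation
#' motif `X* + Pase -> X*_Pase -> X + Pase`.  The result is a suggestion:
#' inspect it before projecting.
#'
#' @param net a `crn` object.
#' @param species name of the active species.
#' @return character vector of reaction ids (possibly empty, with a
#'   warning when the species has no consuming reactions).
#' @export
deactivation_reactions <- function(net, species) {
  stopifnot(inherits(net, "crn"))
  if (!species %in% net$species$name)
    abort(paste0("unknown species '", species, "'"))
  rx <- net$reactions
  consumes <- function(s) vapply(seq_len(nrow(rx)), function(i)
    s %in% names(rx$reactants[[i]]) && !s %in% names(rx$products[[i]]), TRUE)
  first <- which(consumes(species))
  if (length(first) == 0L) {
    warn(paste0("'", species, "' has no consuming reactions"))
    return(character(0))
  }
  H <- rx$id[first]
  intermediates <- unique(unlist(lapply(first, function(i) names(rx$products[[i]]))))
  for (im in intermediates) {
    down <- which(consumes(im))
    down <- down[vapply(down, function(i)
      !species %in% names(rx$products[[i]]), TRUE)]
    H <- union(H, rx$id[down])
  }
  H
}
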