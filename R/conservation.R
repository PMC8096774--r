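# Moiety conservation-law analysis.
#
# A semi-positive conservation vector is a non-negative integer vector in
# ker(S^T); the quantity gamma^T x is then constant along every trajectory
# and counts the molecules of one conserved moiety.  The generators of the
# cone ker(S^T) %i% R^n_+ are computed exactly (see exact-linalg.R), the
# matrix N stacks them row-wise, and -- when N contains an identity minor
# -- the species indexing that minor are the "elemental" (basic) species:
# free-form proteins, each belonging to exactly one conservation law.

#' Compute the conservation-law structure of a network
#'
#' Enumerates the minimal semi-positive conservation vectors of the
#' stoichiometric matrix, stacks them into the matrix `N`, checks
#' `N S = 0` exactly, and searches `N` for an identity minor to select a
#' deterministic set of elemental species (species are scanned in table
#' order and the first unit column matching each law is taken).  The
#' network is *weakly elemented* when such a minor exists and *elemented*
#' when, in addition, every species occurs in some law (equivalently, the
#' network is conservative).
#'
#' @param net a `crn` object.
#' @return an object of class `crn_conservation`: a list with
#'   `generators` (list of named integer vectors), `N` (p x n), `p`,
#'   `rank_S`, `basis_ok` (`p == n - rank(S)`), `elemental` (character),
#'   `permutation` (species order realizing `N = [I_p, N2]`), `N2`,
#'   `is_weakly_elemented`, `is_elemented`, `unconserved` (character),
#'   `trivial` (logical per law: support is a single constant species).
#' @examples
#' cs <- conservation_laws(fixture_phospho_cycle())
#' cs$elemental       # "A" "K" "P"
#' @export
conservation_laws <- function(net) {
  stopifnot(inherits(net, "crn"))
  gens <- semipositive_generators(net$S)
  build_conservation_set(net, gens)
}

#' Assemble a conservation set from verified generators
#'
#' Lower-level constructor behind [conservation_laws()]; accepts an
#' explicit generator list (each is checked with
#' [verify_conservation_vector()] before use).
#'
#' @param net a `crn` object.
#' @param generators list of non-negative integer vectors in `ker(S^T)`.
#' @return see [conservation_laws()].
#' @export
build_conservation_set <- function(net, generators) {
  stopifnot(inherits(net, "crn"))
  S <- net$S
  n <- nrow(S)
  sp_names <- net$species$name
  for (g in generators) {
    if (!verify_conservation_vector(net, g))
      abort("a supplied generator is not in ker(S^T)")
    if (any(g < 0) || any(g != round(g)))
      abort("generators must be non-negative integer vectors")
  }
  p <- length(generators)
  rank_S <- integer_rank(S)
  basis_ok <- p == n - rank_S
  if (p > n - rank_S)
    warn(paste0("cone needs ", p, " generators but ker(S^T) has dimension ",
                n - rank_S, ": the generators are not a basis and ",
                "elemental operations are disabled"))
  N <- if (p > 0L) do.call(rbind, lapply(generators, as.numeric)) else
    matrix(0, 0L, n)
  colnames(N) <- sp_names
  rownames(N) <- if (p > 0L) paste0("CL", seq_len(p)) else character(0)

  unconserved <- sp_names[colSums(N != 0) == 0]
  trivial <- vapply(seq_len(p), function(j) {
    supp <- sp_names[N[j, ] != 0]
    length(supp) == 1L && net$species$constant[match(supp, sp_names)]
  }, TRUE)

  # greedy deterministic elemental selection: for each law, the first
  # species (table order) whose N-column is the corresponding unit vector
  elemental <- rep(NA_character_, p)
  if (basis_ok && p > 0L) {
    taken <- rep(FALSE, n)
    for (j in seq_len(p)) {
      ej <- as.numeric(seq_len(p) == j)
      for (i in seq_len(n)) {
        if (!taken[i] && all(N[, i] == ej)) {
          elemental[j] <- sp_names[i]
          taken[i] <- TRUE
          break
        }
      }
    }
  }
  is_weakly <- basis_ok && p > 0L && !anyNA(elemental)
  is_elem <- is_weakly && length(unconserved) == 0L

  permutation <- NULL
  N2 <- NULL
  if (is_weakly) {
    sec <- setdiff(sp_names, elemental)
    permutation <- c(elemental, sec)
    N2 <- N[, sec, drop = FALSE]
  }
  structure(
    list(generators = generators, N = N, p = p, rank_S = rank_S,
         basis_ok = basis_ok, elemental = if (is_weakly) elemental else character(0),
         permutation = permutation, N2 = N2,
         is_weakly_elemented = is_weakly, is_elemented = is_elem,
         unconserved = unconserved, trivial = trivial,
         species = net$species),
    class = "crn_conservation"
  )
}

#' Check a candidate conservation vector
#'
#' `TRUE` iff `S^T gamma = 0` exactly (integer arithmetic), i.e. iff
#' `gamma^T x` is constant along every trajectory of the network.
#'
#' @param net a `crn` object.
#' @param gamma numeric vector of length `n` (named or in species order).
#' @export
verify_conservation_vector <- function(net, gamma) {
  stopifnot(inherits(net, "crn"))
  if (!is.null(names(gamma))) {
    g <- setNames(numeric(nrow(net$species)), net$species$name)
    g[names(gamma)] <- gamma
    gamma <- g
  }
  if (length(gamma) != nrow(net$species))
    abort("gamma has the wrong length")
  all(drop(crossprod(net$S, gamma)) == 0)
}

#' Is the network conservative?
#'
#' A network is conservative when a strictly positive vector lies in
#' `ker(S^T)`, i.e. when every species carries at least one conserved
#' moiety; concentrations are then globally bounded.
#'
#' @param net a `crn` object.
#' @param cs optional precomputed [conservation_laws()] result.
#' @export
is_conservative <- function(net, cs = NULL) {
  cs <- cs %||% conservation_laws(net)
  length(cs$unconserved) == 0L && cs$p > 0L
}

#' Solve the conservation relations for the elemental species
#'
#' Given the class invariants `c` and the secondary (non-elemental)
#' concentrations `x2`, returns the elemental concentrations
#' `x1 = c - N2 x2`.  A negative entry in the result means `x2` is
#' infeasible for the class `c` (the caller decides how to handle it).
#'
#' @param cs a `crn_conservation` object (weakly elemented).
#' @param c numeric vector of length `p` (total moiety concentrations, nM).
#' @param x2 numeric vector of secondary concentrations, named or ordered
#'   as `setdiff(cs$permutation, cs$elemental)`.
#' @return named numeric vector `x1` over the elemental species.
#' @export
elemental_solve <- function(cs, c, x2) {
  stopifnot(inherits(cs, "crn_conservation"))
  if (!cs$is_weakly_elemented)
    abort("network is not weakly elemented: N has no identity minor")
  if (length(c) != cs$p) abort("c must have length p")
  sec <- colnames(cs$N2)
  if (!is.null(names(x2))) x2 <- x2[sec]
  if (length(x2) != length(sec)) abort("x2 has the wrong length")
  x1 <- as.numeric(c) - drop(cs$N2 %*% as.numeric(x2))
  setNames(x1, cs$elemental)
}

#' @export
print.crn_conservation <- function(x, ...) {
  cat("<crn_conservation> ", x$p, " semi-positive conservation law(s); ",
      "rank(S) = ", x$rank_S, "\n", sep = "")
  cat("  basis assumption p = n - rank(S):", if (x$basis_ok) "holds" else "VIOLATED", "\n")
  if (x$is_weakly_elemented)
    cat("  ", if (x$is_elemented) "elemented" else "weakly elemented",
        "; elemental species: ", paste(x$elemental, collapse = ", "), "\n", sep = "")
  else cat("  no identity minor: elemental operations disabled\n")
  if (length(x$unconserved))
    cat("  species in no law:", paste(x$unconserved, collapse = ", "), "\n")
  if (any(x$trivial))
    cat("  trivial laws (single constant species):", sum(x$trivial), "\n")
  invisible(x)
}

#' @describeIn conservation_laws tidy the generators into a long tibble
#'   with columns `law`, `species`, `coefficient`, `trivial`.
#' @param x a `crn_conservation` object.
#' @param ... unused.
#' @method tidy crn_conservation
#' @export
tidy.crn_conservation <- function(x, ...) {
  if (x$p == 0L)
    return(tibble(law = character(0), species = character(0),
                  coefficient = numeric(0), trivial = logical(0)))
  purrr::map_dfr(seq_len(x$p), function(j) {
    g <- x$generators[[j]]
    g <- g[g != 0]
    tibble(law = rownames(x$N)[j], species = names(g),
           coefficient = unname(g), trivial = x$trivial[j])
  })
}

#' @describeIn conservation_laws one-row summary (counts and flags).
#' @method glance crn_conservation
#' @export
glance.crn_conservation <- function(x, ...) {
  tibble(p = x$p, rank_S = x$rank_S, basis_ok = x$basis_ok,
         weakly_elemented = x$is_weakly_elemented,
         elemented = x$is_elemented,
         n_trivial = sum(x$trivial),
         n_unconserved = length(x$unconserved))
}
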