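# Network representation and mass-action kinetics.
#
# A `crn` object stores the species table, the expanded (irreversible)
# reaction table, the stoichiometric matrix S (n x r), the reactant-order
# matrix A (n x r, the exponents of the flux monomials) and the rate
# constant vector k.  Reversible reactions are always expanded into two
# irreversible columns sharing a `parent_id`, so a network declared with
# 339 reversible and 172 irreversible reactions has r = 850 columns and
# gain-of-function column deletion can act on a single direction.

#' Construct a reaction network
#'
#' Builds a mass-action chemical reaction network from a species table and
#' a reaction table.  The ODE system is `dx/dt = S v(x, k)` with
#' `v_j = k_j prod_i x_i^{a_ij}`, where `a_ij` is the stoichiometry of
#' species `i` as a reactant of reaction `j`.  Concentrations are in nM.
#' Species flagged `constant` keep a null time derivative (their rows of S
#' are forced to zero); they model non-consumable inflows such as external
#' growth factors.
#'
#' @param species data frame with columns `name`, `initial_nM`
#'   (non-negative), and optionally `constant` (logical or 0/1, default
#'   `FALSE`).
#' @param reactions data frame with columns `id`, `reactants`, `products`
#'   (formula strings such as `"A + K"`, `"2 X"`, or `""` for a zero-order
#'   boundary flux), `reversible` (logical or 0/1), `k_forward` and, for
#'   reversible rows, `k_reverse`.
#' @return an object of class `crn` with elements `species` (tibble),
#'   `reactions` (tibble of expanded irreversible reactions), `S`, `A`
#'   (integer matrices, species x reactions) and `k` (numeric).
#' @examples
#' net <- crn_network(
#'   species   = data.frame(name = c("A", "B"), initial_nM = c(1, 0)),
#'   reactions = data.frame(id = "r1", reactants = "A", products = "B",
#'                          reversible = 1, k_forward = 2, k_reverse = 1)
#' )
#' net$S
#' @export
crn_network <- function(species, reactions) {
  species <- as_tibble(species)
  reactions <- as_tibble(reactions)
  need <- setdiff(c("name", "initial_nM"), names(species))
  if (length(need)) abort(paste0("species table is missing column(s): ",
                                 paste(need, collapse = ", ")))
  if (!"constant" %in% names(species)) species$constant <- FALSE
  species$constant <- as.logical(as.integer(species$constant))
  species$name <- as.character(species$name)
  if (anyDuplicated(species$name))
    abort(paste0("duplicate species name(s): ",
                 paste(unique(species$name[duplicated(species$name)]), collapse = ", ")))
  if (any(is.na(species$initial_nM)) || any(species$initial_nM < 0))
    abort("initial_nM must be non-negative")

  need <- setdiff(c("id", "reactants", "products", "k_forward"), names(reactions))
  if (length(need)) abort(paste0("reaction table is missing column(s): ",
                                 paste(need, collapse = ", ")))
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  reactions$reversible <- as.logical(as.integer(reactions$reversible))
  if (!"k_reverse" %in% names(reactions)) reactions$k_reverse <- NA_real_
  reactions$id <- as.character(reactions$id)
  if (anyDuplicated(reactions$id))
    abort(paste0("duplicate reaction id(s): ",
                 paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", ")))

  sp_names <- species$name
  parse_side <- function(txt, row_id) {
    txt <- trimws(txt %||% "")
    if (is.na(txt) || txt == "" || txt == "0") return(integer(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
    out <- integer(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]+)?\\s*(\\S+)$", tm))[[1L]]
      if (length(m) == 0L)
        abort(paste0("cannot parse term '", tm, "' in reaction '", row_id, "'"))
      coef <- if (m[2L] == "") 1L else as.integer(m[2L])
      name <- m[3L]
      if (!name %in% sp_names)
        abort(paste0("reaction '", row_id, "' references undeclared species '",
                     name, "'"))
      out[name] <- coef + (if (name %in% names(out)) out[[name]] else 0L)
    }
    out
  }

  exp_rows <- list()
  for (i in seq_len(nrow(reactions))) {
    rr <- reactions[i, ]
    if (is.na(rr$k_forward) || rr$k_forward <= 0)
      abort(paste0("reaction '", rr$id, "': rate constant must be positive"))
    rct <- parse_side(rr$reactants, rr$id)
    prd <- parse_side(rr$products, rr$id)
    if (length(rct) == 0L)
      inform(paste0("reaction '", rr$id,
                    "' has no reactants: treated as a zero-order boundary flux"))
    if (rr$reversible) {
      if (is.na(rr$k_reverse) || rr$k_reverse <= 0)
        abort(paste0("reaction '", rr$id,
                     "': reversible rows need a positive k_reverse"))
      exp_rows[[length(exp_rows) + 1L]] <-
        list(id = paste0(rr$id, "_f"), parent_id = rr$id,
             reactants = rct, products = prd, k = rr$k_forward)
      exp_rows[[length(exp_rows) + 1L]] <-
        list(id = paste0(rr$id, "_r"), parent_id = rr$id,
             reactants = prd, products = rct, k = rr$k_reverse)
    } else {
      exp_rows[[length(exp_rows) + 1L]] <-
        list(id = rr$id, parent_id = NA_character_,
             reactants = rct, products = prd, k = rr$k_forward)
    }
  }

  n <- nrow(species)
  r <- length(exp_rows)
  S <- matrix(0, n, r, dimnames = list(sp_names, vapply(exp_rows, `[[`, "", "id")))
  A <- S
  for (j in seq_len(r)) {
    rct <- exp_rows[[j]]$reactants
    prd <- exp_rows[[j]]$products
    if (length(rct)) {
      A[names(rct), j] <- rct
      S[names(rct), j] <- S[names(rct), j] - rct
    }
    if (length(prd)) S[names(prd), j] <- S[names(prd), j] + prd
  }
  S[species$constant, ] <- 0   # null time derivative for inflow species

  rx <- tibble(
    id = colnames(S),
    parent_id = vapply(exp_rows, `[[`, "", "parent_id"),
    reactants = lapply(exp_rows, `[[`, "reactants"),
    products = lapply(exp_rows, `[[`, "products"),
    k = vapply(exp_rows, `[[`, 0, "k")
  )
  structure(
    list(species = species, reactions = rx, S = S, A = A, k = rx$k,
         zeroed_reactions = character(0)),
    class = "crn"
  )
}

#' Read a network from its TSV description
#'
#' Reads `species.tsv` (columns `name`, `initial_nM`, `constant`) and
#' `reactions.tsv` (columns `id`, `reactants`, `products`, `reversible`,
#' `k_forward`, `k_reverse`) from a directory.  Files are UTF-8,
#' tab-separated, with `#` comment lines.
#'
#' @param dir directory containing `species.tsv` and `reactions.tsv`.
#' @return a [crn_network()] object.
#' @export
read_crn <- function(dir) {
  sp_path <- file.path(dir, "species.tsv")
  rx_path <- file.path(dir, "reactions.tsv")
  for (p in c(sp_path, rx_path)) if (!file.exists(p)) abort(paste0("missing file: ", p))
  rd <- function(p) utils::read.delim(p, comment.char = "#", sep = "\t",
                                      stringsAsFactors = FALSE, check.names = FALSE)
  crn_network(rd(sp_path), rd(rx_path))
}

#' Write a network to TSV files
#'
#' Inverse of [read_crn()]: re-merges expanded reversible pairs (via
#' `parent_id`) back into single reversible rows and writes the standard
#' `species.tsv`/`reactions.tsv` dialect.
#'
#' @param net a `crn` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_crn <- function(net, dir) {
  stopifnot(inherits(net, "crn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- net$species
  sp$constant <- as.integer(sp$constant)
  utils::write.table(sp, file.path(dir, "species.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fmt_side <- function(stoich) {
    if (length(stoich) == 0L) return("")
    paste(ifelse(stoich == 1L, names(stoich), paste(stoich, names(stoich))),
          collapse = " + ")
  }
  rx <- net$reactions
  rows <- list()
  done <- character(0)
  for (i in seq_len(nrow(rx))) {
    pid <- rx$parent_id[i]
    if (!is.na(pid)) {
      if (pid %in% done) next
      pair <- which(rx$parent_id == pid)
      fwd <- pair[grepl("_f$", rx$id[pair])][1L]
      rev <- pair[grepl("_r$", rx$id[pair])][1L]
      rows[[length(rows) + 1L]] <- data.frame(
        id = pid, reactants = fmt_side(rx$reactants[[fwd]]),
        products = fmt_side(rx$products[[fwd]]), reversible = 1L,
        k_forward = rx$k[fwd], k_reverse = rx$k[rev])
      done <- c(done, pid)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        id = rx$id[i], reactants = fmt_side(rx$reactants[[i]]),
        products = fmt_side(rx$products[[i]]), reversible = 0L,
        k_forward = rx$k[i], k_reverse = NA_real_)
    }
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

# coerce/validate a concentration vector against the network's species order
as_concentration <- function(net, x, neg_tol = 0) {
  n <- nrow(net$species)
  if (!is.null(names(x))) {
    miss <- setdiff(net$species$name, names(x))
    if (length(miss)) abort(paste0("concentration vector missing species: ",
                                   paste(miss, collapse = ", ")))
    x <- x[net$species$name]
  } else if (length(x) != n) {
    abort(paste0("concentration vector has length ", length(x),
                 ", expected ", n))
  }
  x <- as.numeric(x)
  if (any(x < -neg_tol))
    abort("negative concentration beyond tolerance")
  names(x) <- net$species$name
  pmax(x, 0)
}

#' Mass-action reaction fluxes
#'
#' Evaluates `v_j = k_j prod_i x_i^{a_ij}` for every (irreversible)
#' reaction column, `a_ij` being the reactant stoichiometry.
#'
#' @param net a `crn` object.
#' @param x concentration vector (named or in species-table order), nM.
#' @return named numeric vector of length `r` (nM/time units of `k`).
#' @export
mass_action_fluxes <- function(net, x) {
  stopifnot(inherits(net, "crn"))
  x <- as_concentration(net, x)
  v <- net$k * apply(x^net$A, 2L, prod)   # x^0 = 1 even at x = 0
  names(v) <- colnames(net$S)
  v
}

#' Right-hand side of the mass-action ODE system
#'
#' Returns `S v(x, k)`, the time derivative of the concentration vector.
#' Rows of S belonging to constant (inflow) species are identically zero,
#' so their components are exactly 0.
#'
#' @inheritParams mass_action_fluxes
#' @return named numeric vector of length `n`.
#' @export
ode_rhs <- function(net, x) {
  v <- mass_action_fluxes(net, x)
  drop(net$S %*% v)
}

#' @export
print.crn <- function(x, ...) {
  n_rev <- length(unique(stats::na.omit(x$reactions$parent_id)))
  cat("<crn> mass-action reaction network\n")
  cat("  species:   ", nrow(x$species), " (", sum(x$species$constant),
      " constant)\n", sep = "")
  cat("  reactions: ", ncol(x$S), " irreversible columns (", n_rev,
      " reversible pairs)\n", sep = "")
  if (length(x$zeroed_reactions))
    cat("  GoF-zeroed columns:", paste(x$zeroed_reactions, collapse = ", "), "\n")
  invisible(x)
}
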