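# Exact integer linear algebra used by the conservation-law machinery.
#
# Stoichiometric coefficients are small integers, so all values are stored
# in doubles but kept integer-valued throughout: Bareiss (fraction-free)
# elimination for ranks and the Schuster-Hoefer tableau for cone generators
# only ever divide by quantities that divide exactly.  Doubles represent
# integers exactly up to 2^53, far beyond what networks of this size reach.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0L) return(1)
  Reduce(gcd2, v)
}

#' Exact rank of an integer matrix
#'
#' Computes `rank(M)` by fraction-free (Bareiss) Gaussian elimination, so
#' the result is exact for integer matrices -- no floating-point rank
#' tolerance is involved.  Used wherever the theory requires the identity
#' `p = n - rank(S)` or the rank-preservation condition of a
#' gain-of-function projection to hold exactly.
#'
#' @param M numeric matrix with integer-valued entries.
#' @return integer rank.
#' @export
integer_rank <- function(M) {
  M <- as.matrix(M)
  if (any(M != round(M))) abort("integer_rank() requires integer-valued entries")
  n <- nrow(M); m <- ncol(M)
  if (n == 0L || m == 0L) return(0L)
  rank <- 0L
  prev <- 1
  row <- 1L
  for (col in seq_len(m)) {
    piv <- which(M[row:n, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    if (row < n) {
      for (i in (row + 1L):n) {
        # Bareiss step: exact division by the previous pivot
        M[i, ] <- (M[row, col] * M[i, ] - M[i, col] * M[row, ]) / prev
      }
    }
    prev <- M[row, col]
    rank <- rank + 1L
    row <- row + 1L
    if (row > n) break
  }
  rank
}

#' Minimal semi-positive generators of the left-null cone
#'
#' Enumerates the extreme rays of `ker(S^T) %i% R^n_+`, i.e. the minimal
#' semi-positive integer conservation vectors of a stoichiometric matrix,
#' with a tableau (double-description) scheme over exact integer
#' arithmetic.  Each returned generator is scaled to coprime integer
#' entries; the output order is deterministic (lexicographic by support,
#' then by entries).
#'
#' @param S integer stoichiometric matrix, species in rows, reactions in
#'   columns.
#' @return list of named integer vectors (length `nrow(S)`); empty list if
#'   the cone is trivial.
#' @export
semipositive_generators <- function(S) {
  S <- as.matrix(S)
  if (any(S != round(S))) abort("semipositive_generators() requires an integer matrix")
  n <- nrow(S)
  r <- ncol(S)
  sp_names <- rownames(S)
  # tableau rows: [gamma | gamma^T S]; start from the standard basis
  Tb <- cbind(diag(n), S)
  for (j in seq_len(r)) {
    col <- n + j
    vals <- Tb[, col, drop = TRUE]
    keep <- which(vals == 0)
    pos <- which(vals > 0)
    neg <- which(vals < 0)
    new_rows <- list()
    if (length(pos) && length(neg)) {
      zero_sets <- apply(Tb == 0, 1L, which, simplify = FALSE)
      for (a in pos) {
        for (b in neg) {
          zab <- intersect(zero_sets[[a]], zero_sets[[b]])
          # minimality (adjacency) test: no third row's zero set contains
          # the common zero set of the combined pair
          dominated <- FALSE
          for (c in seq_len(nrow(Tb))) {
            if (c == a || c == b) next
            if (all(zab %in% zero_sets[[c]])) { dominated <- TRUE; break }
          }
          if (dominated) next
          w <- abs(vals[b]) * Tb[a, ] + abs(vals[a]) * Tb[b, ]
          w <- w / gcd_vec(w)
          new_rows[[length(new_rows) + 1L]] <- w
        }
      }
    }
    Tb <- rbind(Tb[keep, , drop = FALSE], do.call(rbind, new_rows))
    if (nrow(Tb) == 0L) break
    Tb <- unique(Tb)
  }
  if (nrow(Tb) == 0L) return(list())
  G <- Tb[, seq_len(n), drop = FALSE]
  G <- G[rowSums(G != 0) > 0, , drop = FALSE]
  if (nrow(G) == 0L) return(list())
  # deterministic order: by first supported species (table order), then
  # lexicographic on support and entries
  first <- apply(G != 0, 1L, which.max)
  key <- apply(G, 1L, function(g) paste(c(as.integer(g != 0), g), collapse = ","))
  G <- G[order(first, key), , drop = FALSE]
  lapply(seq_len(nrow(G)), function(i) setNames(G[i, ], sp_names))
}
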