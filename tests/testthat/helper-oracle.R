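# Brute-force oracle for semi-positive conservation vectors.
#
# Independent of the package's tableau algorithm: enumerates candidate
# supports exhaustively and builds the (unique up to scale) kernel vector
# on each support from exact integer determinants (Cramer minors), so the
# result is the set of extreme rays of ker(S^T) %i% R^n_+ computed by a
# completely different route.

oracle_det <- function(M) {
  # fraction-free (integer-exact) determinant
  n <- nrow(M)
  if (n == 0L) return(1)
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1L)) {
    if (M[k, k] == 0) {
      piv <- which(M[(k + 1L):n, k] != 0)
      if (length(piv) == 0L) return(0)
      piv <- piv[1L] + k
      M[c(k, piv), ] <- M[c(piv, k), ]
      sign <- -sign
    }
    for (i in (k + 1L):n) {
      M[i, ] <- (M[k, k] * M[i, ] - M[i, k] * M[k, ]) / prev
    }
    prev <- M[k, k]
  }
  sign * M[n, n]
}

oracle_rank <- function(M) {
  n <- nrow(M); m <- ncol(M)
  if (n == 0L || m == 0L) return(0L)
  rank <- 0L; prev <- 1; row <- 1L
  for (col in seq_len(m)) {
    piv <- which(M[row:n, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    if (row < n) for (i in (row + 1L):n)
      M[i, ] <- (M[row, col] * M[i, ] - M[i, col] * M[row, ]) / prev
    prev <- M[row, col]
    rank <- rank + 1L; row <- row + 1L
    if (row > n) break
  }
  rank
}

oracle_gcd <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  Reduce(function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }, v)
}

# independent rows of M spanning its row space (indices)
oracle_independent_rows <- function(M) {
  keep <- integer(0)
  r <- 0L
  for (i in seq_len(nrow(M))) {
    cand <- M[c(keep, i), , drop = FALSE]
    if (oracle_rank(cand) > r) { keep <- c(keep, i); r <- r + 1L }
  }
  keep
}

# All extreme rays of ker(S^T) %i% R^n_+ as coprime integer vectors.
# Exhaustive support search: for each candidate support T, the kernel of
# the rows of S^T indexed by T must be one-dimensional, strictly signed,
# and supported on exactly T; minimal supports win.
oracle_semipositive_rays <- function(S) {
  n <- nrow(S)
  St <- t(S)                      # r x n
  found <- list()
  found_supports <- list()
  for (size in seq_len(n)) {
    for (T in utils::combn(n, size, simplify = FALSE)) {
      # prune supersets of already-found (hence smaller, minimal) supports
      if (any(vapply(found_supports, function(s) all(s %in% T), TRUE))) next
      M <- St[, T, drop = FALSE]
      if (oracle_rank(M) != size - 1L) next
      if (size == 1L) {
        v <- 1
      } else {
        R <- oracle_independent_rows(M)
        v <- vapply(seq_len(size), function(i)
          (-1)^(i + 1) * oracle_det(M[R, -i, drop = FALSE]), 0)
      }
      if (any(v == 0)) next             # true support is smaller
      if (all(v < 0)) v <- -v
      if (any(v < 0)) next              # mixed signs: not in the orthant
      ray <- numeric(n)
      ray[T] <- v / oracle_gcd(v)
      found[[length(found) + 1L]] <- ray
      found_supports[[length(found_supports) + 1L]] <- T
    }
  }
  found
}

# order-insensitive comparison of two generator sets (coprime integer rays)
expect_same_rays <- function(got, want, species = NULL) {
  canon <- function(lst) {
    m <- vapply(lst, function(g) as.numeric(g), numeric(length(lst[[1L]])))
    m <- t(m)
    m[order(apply(m, 1L, paste, collapse = ",")), , drop = FALSE]
  }
  got <- lapply(got, unname)
  want <- lapply(want, unname)
  expect_equal(length(got), length(want))
  if (length(got)) expect_equal(canon(got), canon(want))
}
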