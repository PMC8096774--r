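# Monte-Carlo verification of the global-stability condition.
#
# A network satisfies the global-stability condition when every
# stoichiometric compatibility class contains exactly one globally
# asymptotically stable steady state.  For networks too large for
# analytic results, the condition is probed numerically: draw random
# classes, integrate many random initial states per class, and check
# that the dispersion of the terminal states (coefficient of variation
# across runs) collapses relative to the dispersion of the initial
# states.

#' Coefficient of variation
#'
#' Sample standard deviation (denominator `m - 1`) divided by the mean;
#' with 30 samples the variance denominator is 29.  Undefined (NA) when
#' the mean is not positive.
#'
#' @param samples numeric vector of non-negative values, length >= 2.
#' @return non-negative scalar, or `NA` for a zero mean.
#' @export
coefficient_of_variation <- function(samples) {
  if (length(samples) < 2L)
    abort("coefficient of variation needs at least 2 samples")
  m <- mean(samples)
  if (m <= 0) return(NA_real_)
  sd(samples) / m
}

#' Numerical check of per-class global stability
#'
#' For each of `n_classes` compatibility classes (total concentrations of
#' the non-trivial laws drawn log10-uniformly from `c_range`; trivial
#' laws keep the declared constant-species values), draws `n_points`
#' random states of the class with [sample_class_point()], verifies their
#' co-membership, integrates each to `t_end`, and compares the per-species
#' coefficients of variation of the initial values (`eps0`) and of the
#' terminal states (`eps_e`) over the non-constant species.  The class
#' passes when its mean `eps_e` is at least `separation` times below its
#' mean `eps0` -- terminal states agree even though initial states were
#' scattered, the signature of a single attracting steady state per class.
#'
#' @param net a `crn` object.
#' @param cs optional precomputed `crn_conservation` (must be weakly
#'   elemented).
#' @param n_classes,n_points protocol sizes (defaults 5 and 30).
#' @param c_range range of the log10-uniform class draws (default
#'   `c(1e-2, 1e3)` nM).
#' @param t_end integration horizon (default `2.5e7`).
#' @param seed integer seed driving all draws (one stream).
#' @param separation required `mean(eps0)/mean(eps_e)` factor (default 10).
#' @param ... passed to [integrate_to_steady()].
#' @return an object of class `crn_stability`: list with `per_species`
#'   (tibble: `class_id`, `species`, `eps0`, `eps_e`, `mu_e`), `classes`
#'   (tibble: `class_id`, `mean_eps0`, `sem_eps0`, `mean_eps_e`,
#'   `sem_eps_e`, `n_failed`, `pass`), `pass` (all classes pass and are
#'   complete), `worst` (10 species with largest `eps_e`), `seed`.
#' @export
verify_global_stability <- function(net, cs = NULL, n_classes = 5,
                                    n_points = 30, c_range = c(1e-2, 1e3),
                                    t_end = 2.5e7, seed = 1,
                                    separation = 10, ...) {
  stopifnot(inherits(net, "crn"))
  cs <- cs %||% conservation_laws(net)
  if (!cs$is_weakly_elemented)
    abort("the stability protocol needs a weakly elemented network")
  if (n_points < 2L) abort("n_points must be >= 2 (coefficient of variation undefined)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  sp <- net$species$name
  nonconst <- sp[!net$species$constant]
  per_species <- list()
  class_rows <- list()
  for (cl in seq_len(n_classes)) {
    c_cl <- 10^runif(cs$p, log10(c_range[1L]), log10(c_range[2L]))
    if (any(cs$trivial)) {
      for (j in which(cs$trivial)) {
        s <- which(cs$N[j, ] != 0)
        c_cl[j] <- cs$N[j, s] * net$species$initial_nM[s]
      }
    }
    X0 <- matrix(NA_real_, n_points, length(sp), dimnames = list(NULL, sp))
    Xe <- X0
    n_failed <- 0L
    for (k in seq_len(n_points)) {
      x0 <- sample_class_point(cs, c_cl)
      if (!same_class(cs, x0, ideal_state(cs, c_cl), tol = 1e-8))
        abort("sampled point left its compatibility class (internal error)")
      X0[k, ] <- x0
      ss <- tryCatch(
        integrate_to_steady(net, x0, t_end = t_end, conservation = cs, ...),
        error = function(e) NULL)
      if (is.null(ss)) n_failed <- n_failed + 1L else Xe[k, ] <- ss$x_e
    }
    ok <- !is.na(Xe[, 1L])
    eps0 <- apply(X0[, nonconst, drop = FALSE], 2L, coefficient_of_variation)
    eps_e <- if (sum(ok) >= 2L)
      apply(Xe[ok, nonconst, drop = FALSE], 2L, coefficient_of_variation)
    else rep(NA_real_, length(nonconst))
    mu_e <- if (sum(ok) >= 1L) colMeans(Xe[ok, nonconst, drop = FALSE])
    else rep(NA_real_, length(nonconst))
    per_species[[cl]] <- tibble(class_id = cl, species = nonconst,
                                eps0 = unname(eps0), eps_e = unname(eps_e),
                                mu_e = unname(mu_e))
    sem <- function(v) sd(v) / sqrt(length(v))
    e0 <- eps0[!is.na(eps0) & !is.na(eps_e)]
    ee <- eps_e[!is.na(eps0) & !is.na(eps_e)]
    class_rows[[cl]] <- tibble(
      class_id = cl,
      mean_eps0 = mean(e0), sem_eps0 = sem(e0),
      mean_eps_e = mean(ee), sem_eps_e = sem(ee),
      n_excluded = sum(is.na(eps_e)), n_failed = n_failed,
      pass = n_failed == 0L && mean(ee) * separation <= mean(e0))
  }
  per_species <- dplyr::bind_rows(per_species)
  classes <- dplyr::bind_rows(class_rows)
  worst <- dplyr::slice_max(dplyr::filter(per_species, !is.na(.data$eps_e)),
                            .data$eps_e, n = 10, with_ties = FALSE)
  structure(
    list(per_species = per_species, classes = classes,
         pass = all(classes$pass), worst = worst, seed = seed,
         separation = separation),
    class = "crn_stability"
  )
}

#' @export
print.crn_stability <- function(x, ...) {
  cat("<crn_stability> ", nrow(x$classes), " classes, pass = ", x$pass,
      " (separation factor ", x$separation, ")\n", sep = "")
  print(x$classes)
  invisible(x)
}

#' @describeIn verify_global_stability per-class, per-species coefficients
#'   of variation as a tibble.
#' @param x a `crn_stability` object.
#' @param ... unused.
#' @method tidy crn_stability
#' @export
tidy.crn_stability <- function(x, ...) x$per_species

#' @describeIn verify_global_stability one-row summary across classes.
#' @method glance crn_stability
#' @export
glance.crn_stability <- function(x, ...) {
  tibble(n_classes = nrow(x$classes),
         mean_eps0 = mean(x$classes$mean_eps0),
         mean_eps_e = mean(x$classes$mean_eps_e),
         min_separation = min(x$classes$mean_eps0 / x$classes$mean_eps_e),
         pass = x$pass)
}

#' @describeIn verify_global_stability bar chart of the per-class mean
#'   (with SEM) of `eps0` and `eps_e`.
#' @param object a `crn_stability` object.
#' @method autoplot crn_stability
#' @export
autoplot.crn_stability <- function(object, ...) {
  df <- tidyr::pivot_longer(object$classes,
                            c("mean_eps0", "mean_eps_e"),
                            names_to = "which", values_to = "mean")
  df$sem <- ifelse(df$which == "mean_eps0", object$classes$sem_eps0[
    match(df$class_id, object$classes$class_id)],
    object$classes$sem_eps_e[match(df$class_id, object$classes$class_id)])
  df$which <- factor(df$which, c("mean_eps0", "mean_eps_e"),
                     c("initial states", "steady states"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$class_id), .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::facet_wrap(~which, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "compatibility class",
                  y = "mean coefficient of variation (non-constant species)") +
    ggplot2::theme_minimal()
}
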