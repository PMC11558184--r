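#' Donor-paired sign-flip permutation test
#'
#' Compares two conditions measured on the same donors. The statistic is
#' the mean within-donor difference (group a minus group b). The null
#' distribution is built by independently flipping the sign of each
#' donor's difference — the exchangeability implied by the paired design —
#' either over all `2^n` sign patterns (`exact = TRUE`, the default for
#' 15 or fewer donors) or by Monte-Carlo sampling of `n_perm` patterns.
#' The two-sided sampled p-value uses the add-one rule
#' `(1 + #{|T*| >= |T|}) / (n_perm + 1)`, so it is never exactly zero;
#' the exact p-value is the fraction of all sign patterns (identity
#' included) at least as extreme as the observed statistic.
#'
#' @param data A data frame with one measurement per donor and group.
#' @param value Column with the measured values (tidy-eval).
#' @param group Column identifying the two groups.
#' @param donor Column identifying donors; every donor must appear exactly
#'   once in each group.
#' @param n_perm Number of sampled sign patterns when not exhaustive.
#' @param seed RNG seed for the sampled null.
#' @param exact Force exhaustive enumeration (`TRUE`), sampling (`FALSE`),
#'   or choose automatically (`NULL`).
#' @return A `paired_permutation` object; see [tidy.paired_permutation()].
#' @examples
#' df <- data.frame(
#'   donor = rep(1:6, 2),
#'   group = rep(c("a", "b"), each = 6),
#'   y = c(rnorm(6, 1), rnorm(6))
#' )
#' paired_permutation_test(df, y, group, donor, seed = 1)
#' @export
paired_permutation_test <- function(data, value, group, donor,
                                    n_perm = 9999, seed = 1,
                                    exact = NULL) {
  stopifnot(is.data.frame(data), n_perm >= 99)
  df <- dplyr::transmute(
    data,
    value = {{ value }},
    group = as.character({{ group }}),
    donor = as.character({{ donor }})
  )
  groups <- sort(unique(df$group))
  if (length(groups) != 2) {
    stop("exactly two groups are required", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(df,
    names_from = "group",
    values_from = "value"
  )
  if (anyNA(wide[[groups[1]]]) || anyNA(wide[[groups[2]]])) {
    stop("every donor must be observed in both groups", call. = FALSE)
  }
  diffs <- wide[[groups[1]]] - wide[[groups[2]]]
  n <- length(diffs)
  t_obs <- mean(diffs)
  if (is.null(exact)) exact <- n <= 15

  if (exact) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    t_null <- as.vector(flips %*% diffs) / n
    p <- mean(abs(t_null) >= abs(t_obs) - 1e-12)
    n_used <- nrow(flips)
  } else {
    set.seed(seed)
    signs <- matrix(
      sample(c(1, -1), n_perm * n, replace = TRUE),
      nrow = n_perm
    )
    t_null <- as.vector(signs %*% diffs) / n
    p <- (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }

  structure(
    list(
      statistic = t_obs, p_value = p, n_donors = n,
      n_permutations = n_used, exact = exact, seed = seed,
      groups = groups, differences = diffs
    ),
    class = "paired_permutation"
  )
}

#' @export
print.paired_permutation <- function(x, ...) {
  cat(sprintf(
    "Donor-paired sign-flip permutation test (%s)\n  %s - %s: mean difference %.4g, p = %.4g (%d donors, %d permutations)\n",
    if (x$exact) "exact" else "sampled",
    x$groups[1], x$groups[2], x$statistic, x$p_value,
    x$n_donors, x$n_permutations
  ))
  invisible(x)
}

#' Tidy a paired permutation test
#'
#' @param x A `paired_permutation` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `p.value`, `n_donors`,
#'   `n_permutations`, `method`.
#' @export
tidy.paired_permutation <- function(x, ...) {
  tibble::tibble(
    estimate = x$statistic,
    p.value = x$p_value,
    n_donors = x$n_donors,
    n_permutations = x$n_permutations,
    method = paste0(
      "donor-paired sign-flip permutation (",
      if (x$exact) "exact" else "sampled", ")"
    )
  )
}

#' @rdname tidy.paired_permutation
#' @export
glance.paired_permutation <- function(x, ...) tidy(x, ...)

#' Bonferroni adjustment
#'
#' `min(1, m * p)` across a family of `m` comparisons, via
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Monotone trend across ordered condition levels
#'
#' Measures the monotone association (Spearman rank correlation) between
#' ordered condition levels (e.g. packing densities or velocities) and
#' per-condition summaries (e.g. mean clot volume), reporting the
#' correlation and its sign. With exactly two levels the sign of the
#' difference is reported with correlation +/-1.
#'
#' @param levels Numeric condition levels.
#' @param summaries Per-level summary values.
#' @return A one-row tibble with `rho` and `sign`.
#' @examples
#' trend_effect(c(0.4, 0.5, 0.6), c(10, 14, 25))
#' @export
trend_effect <- function(levels, summaries) {
  stopifnot(length(levels) == length(summaries), length(levels) >= 2)
  if (length(levels) == 2) {
    s <- sign(diff(summaries[order(levels)]))
    return(tibble::tibble(rho = s, sign = s))
  }
  rho <- stats::cor(levels, summaries, method = "spearman")
  tibble::tibble(rho = rho, sign = sign(rho))
}
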