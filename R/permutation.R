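#' Difference of group means
#'
#' The test statistic of the permutation test: `mean(control) -
#' mean(experimental)`.
#'
#' @param control,experimental Non-empty numeric vectors of descriptor
#'   values (e.g. per-cell AUC under two conditions).
#' @return Scalar difference of means.
#' @export
delta_mean <- function(control, experimental) {
  if (!length(control) || !length(experimental))
    stop("both groups must be non-empty", call. = FALSE)
  if (!all(is.finite(control)) || !all(is.finite(experimental)))
    stop("descriptor values must be finite", call. = FALSE)
  mean(control) - mean(experimental)
}

new_permutation_result <- function(delta_obs, exceed, n_perm, p, seed,
                                   alternative, exact, descriptor_name) {
  structure(list(delta_mean_observed = delta_obs,
                 p_value = p,
                 exceed_count = exceed,
                 n_permutations = n_perm,
                 seed = seed,
                 alternative = alternative,
                 exact = exact,
                 descriptor_name = descriptor_name),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s permutation test%s: delta mean = %.4g, p = %.3g (%s, %s permutations%s)\n",
              if (x$exact) "Exhaustive" else "Monte-Carlo",
              if (is.null(x$descriptor_name)) "" else paste0(" [", x$descriptor_name, "]"),
              x$delta_mean_observed, x$p_value, x$alternative,
              format(x$n_permutations, big.mark = ","),
              if (x$exact) "" else paste0(", seed ", x$seed)))
  invisible(x)
}

#' Monte-Carlo permutation test on a difference of means
#'
#' Pools the two groups and redistributes the values into pseudo-control and
#' pseudo-experimental bins without replacement, preserving the original
#' group sizes; the two-tailed p value is the fraction of permutations whose
#' |delta mean| reaches the observed |delta mean|. Ties count as exceedances
#' and the add-one estimator `(exceed + 1)/(n + 1)` keeps p strictly
#' positive, so `p < 1/n_permutations` is never reported — at the default
#' 10^6 permutations the floor is just above 10^-6.
#'
#' @param control,experimental Numeric vectors (non-empty, finite).
#' @param n_permutations Number of random permutations (default 10^6).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`
#'   (`delta_perm >= delta_obs`, the literal one-sided rule).
#' @param descriptor_name Optional label carried into the result.
#' @return A `permutation_result`: observed delta mean, exceedance count,
#'   p value, permutation count, seed.
#' @export
#' @examples
#' permutation_test(rnorm(10), rnorm(10) + 2, n_permutations = 1000, seed = 1)
permutation_test <- function(control, experimental, n_permutations = 1e6,
                             seed = 1L,
                             alternative = c("two.sided", "greater"),
                             descriptor_name = NULL) {
  alternative <- match.arg(alternative)
  stop_if_not_scalar_number(n_permutations, "n_permutations", lower = 1)
  d_obs <- delta_mean(control, experimental)
  pooled <- c(control, experimental)
  n_c <- length(control)
  B <- as.integer(n_permutations)
  tol <- 1e-12 * max(1, abs(d_obs))   # float-safe tie detection

  two_sided <- alternative == "two.sided"
  thr <- if (two_sided) abs(d_obs) - tol else d_obs - tol
  set.seed(seed)
  exceed <- .perm_exceed_count(pooled, n_c, B, thr, two_sided)
  new_permutation_result(d_obs, exceed, B, (exceed + 1) / (B + 1),
                         as.integer(seed), alternative, FALSE, descriptor_name)
}

#' Exhaustive permutation test (exact oracle)
#'
#' Enumerates every assignment of the pooled observations into a control bin
#' of the original size and reports the exact exceedance fraction. Serves as
#' the exact reference for [permutation_test()]; guarded to pooled sizes
#' <= 20 (184,756 assignments at 10+10).
#'
#' @inheritParams permutation_test
#' @return A `permutation_result` with `exact = TRUE` and the raw exceedance
#'   fraction as p (no add-one correction).
#' @export
#' @examples
#' exhaustive_permutation_test(c(0, 0), c(1, 1))$p_value  # 1/3
exhaustive_permutation_test <- function(control, experimental,
                                        alternative = c("two.sided", "greater"),
                                        descriptor_name = NULL) {
  alternative <- match.arg(alternative)
  d_obs <- delta_mean(control, experimental)
  pooled <- c(control, experimental)
  n <- length(pooled)
  n_c <- length(control)
  n_e <- n - n_c
  if (n > 20L)
    stop("pooled size > 20: enumeration infeasible, use permutation_test()",
         call. = FALSE)
  idx <- utils::combn(n, n_c)
  s <- colSums(matrix(pooled[idx], nrow = n_c))
  deltas <- s / n_c - (sum(pooled) - s) / n_e
  tol <- 1e-12 * max(1, abs(d_obs))
  exceed <- if (alternative == "two.sided") sum(abs(deltas) >= abs(d_obs) - tol)
            else sum(deltas >= d_obs - tol)
  new_permutation_result(d_obs, as.integer(exceed), ncol(idx),
                         exceed / ncol(idx), NA_integer_, alternative, TRUE,
                         descriptor_name)
}
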