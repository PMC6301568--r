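## Branching-process model of the frequency of a pre-twinning de novo mutation,
## and the beta prior obtained from it by moment matching.

#' Distribution of a pre-twinning de novo mutation's frequency
#'
#' During each early cleavage division the number of homologous chromosomes in
#' the embryo doubles, and the k-th cycle synthesises `2^(k+1)` nascent
#' chromosomes, each an equally likely mutation target. A variant arising in
#' cycle k therefore has frequency `1/2^(k+1)` among the chromosomes present
#' after that cycle, with probability proportional to the number of targets in
#' cycle k. After `m` cycles this gives
#' `P(p = 1/2^(k+1)) = 2^(k-1) / (2^m - 1)` for `k = 1, ..., m`.
#'
#' @param m Number of pre-twinning cell division cycles. Must be a single
#'   positive integer: the pmf counts discrete cycles. (The moment functions
#'   [expected_frequency()] and [frequency_variance()] accept real `m`.)
#'
#' @return A data frame with one row per cycle `k = 1, ..., m` and columns
#'   `cycle`, `frequency` (`1/2^(k+1)`) and `probability`.
#'
#' @examples
#' pretwinning_pmf(3) # probabilities 1/7, 2/7, 4/7
#' sum(pretwinning_pmf(10)$probability) # 1
#' @seealso [expected_frequency()], [frequency_variance()], [beta_from_moments()]
#' @export
pretwinning_pmf <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
      m != round(m)) {
    stop("'m' must be a single positive integer: the pre-twinning frequency ",
         "pmf counts discrete cell division cycles (use expected_frequency()/",
         "frequency_variance() for real-valued m)", call. = FALSE)
  }
  k <- seq_len(m)
  data.frame(
    cycle = k,
    frequency = 1 / 2^(k + 1),
    probability = 2^(k - 1) / (2^m - 1)
  )
}

#' Moments of the pre-twinning mutation frequency
#'
#' Closed-form expectation and variance of the frequency `p` of a de novo
#' mutation that arose during the first `m` cell division cycles of the embryo:
#' `E(p) = m / (2^(m+2) - 4)` and
#' `Var(p) = [ (2^m - 1)/2^(m-1) - m^2/(2^m - 1) ] / (16 (2^m - 1))`.
#' For integer `m` these equal the mean and variance of [pretwinning_pmf()];
#' both formulas extend smoothly to real `m > 0`, which is how the default
#' casework value `m = 5.5` is used.
#'
#' @param m Number of pre-twinning cell division cycles; a single real > 0.
#'
#' @return A single numeric value.
#'
#' @examples
#' expected_frequency(5.5) # 0.0311
#' frequency_variance(5.5) # 0.0018
#' @export
expected_frequency <- function(m) {
  check_positive_real_m(m)
  m / (2^(m + 2) - 4)
}

#' @rdname expected_frequency
#' @export
frequency_variance <- function(m) {
  check_positive_real_m(m)
  ((2^m - 1) / 2^(m - 1) - m^2 / (2^m - 1)) / (16 * (2^m - 1))
}

check_positive_real_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0) {
    stop("'m' must be a single positive number of cell division cycles",
         call. = FALSE)
  }
  invisible(m)
}

#' Moment-match a beta distribution
#'
#' Solves `mean = alpha/(alpha+beta)` and
#' `variance = alpha*beta / ((1+alpha+beta) * (alpha+beta)^2)` for the shape
#' parameters. Applied to the pre-twinning moments at `m = 5.5` this yields the
#' casework prior shapes (alpha ~ 0.49, beta ~ 15.3, rounded to 0.5 and 15).
#'
#' @param mean Target mean, in (0, 1).
#' @param variance Target variance; must satisfy
#'   `0 < variance < mean * (1 - mean)`, otherwise no beta distribution has
#'   these moments.
#'
#' @return A list with components `alpha` and `beta`.
#'
#' @examples
#' beta_from_moments(0.5, 1 / 12) # uniform: alpha = beta = 1
#' beta_from_moments(expected_frequency(5.5), frequency_variance(5.5))
#' @export
beta_from_moments <- function(mean, variance) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) ||
      mean <= 0 || mean >= 1) {
    stop("'mean' must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance <= 0) {
    stop("'variance' must be a single positive number", call. = FALSE)
  }
  if (variance >= mean * (1 - mean)) {
    stop("no beta distribution has these moments: 'variance' must be below ",
         "mean * (1 - mean) = ", format(mean * (1 - mean)), call. = FALSE)
  }
  s <- mean * (1 - mean) / variance - 1
  list(alpha = mean * s, beta = (1 - mean) * s)
}

#' Beta prior specification
#'
#' A lightweight container for the beta prior of the pre-twinning variant
#' frequency, recording the shape parameters together with the division count
#' `m` they were derived from and whether the casework rounding (to
#' Beta(0.5, 15)) was applied.
#'
#' @param alpha,beta Positive beta shape parameters.
#' @param m Number of pre-twinning division cycles the prior was derived from
#'   (`NA` if the shapes were supplied directly).
#' @param rounded Logical; whether the shapes are the rounded casework values.
#'
#' @return An object of class `"prior_spec"`.
#' @examples
#' prior_spec(0.5, 15, m = 5.5, rounded = TRUE)
#' @seealso [default_prior()]
#' @export
prior_spec <- function(alpha, beta, m = NA_real_, rounded = NA) {
  for (nm in c("alpha", "beta")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         m = as.numeric(m), rounded = rounded),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Beta prior: alpha = %.4f, beta = %.4f (mean %.4f)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  if (!is.na(x$m)) {
    cat(sprintf("  derived from m = %g pre-twinning division cycles%s\n",
                x$m,
                if (isTRUE(x$rounded)) ", shapes rounded for casework" else ""))
  }
  invisible(x)
}

#' Default casework prior for the pre-twinning variant frequency
#'
#' Moment matching of the branching-process frequency distribution at
#' `m = 5.5` division cycles gives shape parameters alpha = 0.4895 and
#' beta = 15.265, rounded for casework to Beta(0.5, 15). The rounded prior is
#' the default because every downstream reference likelihood uses it; set
#' `exact = TRUE` for the unrounded moment-matched shapes.
#'
#' @param exact Logical; if `TRUE`, return the unrounded moment-matched
#'   shapes instead of the casework rounding Beta(0.5, 15).
#' @param m Division-cycle count used for the exact prior (default 5.5).
#'
#' @return A [prior_spec()] object.
#' @examples
#' default_prior()
#' default_prior(exact = TRUE)
#' @export
default_prior <- function(exact = FALSE, m = 5.5) {
  if (exact) {
    ab <- beta_from_moments(expected_frequency(m), frequency_variance(m))
    prior_spec(ab$alpha, ab$beta, m = m, rounded = FALSE)
  } else {
    prior_spec(0.5, 15, m = m, rounded = TRUE)
  }
}

#' Average number of pre-twinning cell divisions
#'
#' MZ twinning occurs before the end of the first gestational week in >98% of
#' cases, with about 25% of splits pre-dating blastocyst formation at day 5,
#' and early cleavage proceeds at roughly one division per day. Weighting the
#' plausible division counts accordingly,
#' `0.25 * mean(1:5) + 0.75 * mean(6:7)`, gives 5.625. Casework convention
#' nevertheless uses `m = 5.5`, and all default constants in this package
#' follow that convention; this helper exposes the averaging so the small
#' discrepancy is visible.
#'
#' @return The weighted average, 5.625.
#' @examples
#' mean_pretwinning_divisions()
#' @export
mean_pretwinning_divisions <- function() {
  0.25 * mean(1:5) + 0.75 * mean(6:7)
}
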