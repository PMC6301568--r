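## Conjugate beta update of the prior with somatic NGS read counts, and
## posterior summaries (mean, tail probability above a detection threshold).

#' Variant and wild-type read counts
#'
#' NGS read counts for one variant in one sample: `v` reads carrying the
#' variant allele and `w` carrying the wild type. `v = w = 0` is permitted and
#' leaves the prior unchanged on update.
#'
#' @param v,w Single non-negative integer counts.
#' @return An object of class `"read_count"`.
#' @examples
#' read_count(25, 50)
#' @export
read_count <- function(v, w) {
  for (nm in c("v", "w")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
        x != round(x)) {
      stop("'", nm, "' must be a single non-negative integer read count",
           call. = FALSE)
    }
  }
  structure(list(v = as.numeric(v), w = as.numeric(w)), class = "read_count")
}

#' @export
print.read_count <- function(x, ...) {
  cat(sprintf("read counts: %g variant / %g wild-type\n", x$v, x$w))
  invisible(x)
}

#' Bayesian update of the beta prior with read counts
#'
#' The beta prior on the germline frequency of a variant is conjugate to the
#' binomial read-count likelihood, so observing `v` variant and `w` wild-type
#' reads in a twin's somatic sample updates Beta(alpha, beta) to
#' Beta(alpha + v, beta + w).
#'
#' @param prior A [prior_spec()] (or any list with `alpha` and `beta`).
#' @param reads A [read_count()] object.
#' @param twin Optional label ("A" or "B") recording which twin the somatic
#'   sample came from.
#' @param variant_id Optional variant identifier.
#'
#' @return An object of class `"posterior_beta"` with fields `alpha`, `beta`,
#'   `twin`, `variant_id`.
#' @examples
#' update_posterior(default_prior(), read_count(25, 50)) # Beta(25.5, 65)
#' @export
update_posterior <- function(prior, reads, twin = NA_character_,
                             variant_id = NA_character_) {
  stopifnot(is.list(prior), is.numeric(prior$alpha), is.numeric(prior$beta))
  if (!inherits(reads, "read_count")) {
    reads <- read_count(reads$v, reads$w)
  }
  structure(
    list(alpha = prior$alpha + reads$v, beta = prior$beta + reads$w,
         twin = twin, variant_id = variant_id),
    class = "posterior_beta"
  )
}

#' @export
print.posterior_beta <- function(x, ...) {
  lab <- if (!is.na(x$twin) || !is.na(x$variant_id)) {
    sprintf(" [variant %s, twin %s]", x$variant_id, x$twin)
  } else ""
  cat(sprintf("posterior Beta(%g, %g)%s: mean %.4g, P(p >= 0.05) = %.4g\n",
              x$alpha, x$beta, lab,
              posterior_mean(x), exceedance_probability(x, 0.05)))
  invisible(x)
}

#' Posterior mean germline frequency
#'
#' `E(p) = alpha / (alpha + beta)` for a Beta(alpha, beta) posterior. In the
#' paternity scenario this is the probability that a sperm cell drawn at
#' random from the twin's germline carries the variant, i.e. the per-variant
#' likelihood of that twin being the father of a child who inherited it.
#'
#' @param post A `"posterior_beta"` (or any list with `alpha` and `beta`).
#' @return A single numeric value in (0, 1).
#' @examples
#' posterior_mean(update_posterior(default_prior(), read_count(25, 50)))
#' @export
posterior_mean <- function(post) {
  stopifnot(is.list(post), is.numeric(post$alpha), is.numeric(post$beta))
  post$alpha / (post$alpha + post$beta)
}

#' Posterior probability that the germline frequency exceeds a threshold
#'
#' `P(p >= t)` under a Beta(alpha, beta) posterior, the upper tail of the
#' regularized incomplete beta function. With `t` set to the Sanger detection
#' limit (about 5%), this is the per-variant likelihood that the variant would
#' be seen in a Sanger-sequenced germline-derived sample from that twin. The
#' distribution is continuous, so `P(p >= t)` and `P(p > t)` coincide.
#'
#' @param post A `"posterior_beta"` (or any list with `alpha` and `beta`).
#' @param threshold Detection threshold `t` in \[0, 1\].
#' @return A single numeric value in \[0, 1\].
#' @examples
#' exceedance_probability(list(alpha = 0.5, beta = 80), 0.05) # 4.23e-3
#' @export
exceedance_probability <- function(post, threshold = 0.05) {
  stopifnot(is.list(post), is.numeric(post$alpha), is.numeric(post$beta))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("'threshold' must be a single number in [0, 1]", call. = FALSE)
  }
  stats::pbeta(threshold, post$alpha, post$beta, lower.tail = FALSE)
}
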