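## Scenario-specific likelihoods, per-variant and combined likelihood ratios,
## and posterior odds for a two-hypothesis MZ-twin case.

#' One discriminating variant observed in both twins
#'
#' Holds the somatic NGS read counts of one variant in both twins together
#' with the germline observation: in the sperm scenario, whether targeted
#' Sanger sequencing detected the variant in the sperm sample; in the
#' paternity scenario, whether the child inherited it.
#'
#' @param variant_id Variant identifier (unique within a case).
#' @param chrom Chromosome label (used only for the independence caveat:
#'   variants on the same chromosome may not be stochastically independent).
#' @param vA,wA Variant and wild-type read counts in twin A's somatic sample.
#' @param vB,wB The same for twin B.
#' @param germline_detected Logical; the germline observation described above.
#'
#' @return An object of class `"variant_observation"`.
#' @examples
#' variant_observation("snv1", "chr7", vA = 25, wA = 50, vB = 0, wB = 75,
#'                     germline_detected = TRUE)
#' @export
variant_observation <- function(variant_id, chrom, vA, wA, vB, wB,
                                germline_detected) {
  if (!is.character(chrom) && !is.factor(chrom)) chrom <- as.character(chrom)
  chrom <- as.character(chrom)
  if (length(chrom) != 1L || is.na(chrom) || !nzchar(chrom)) {
    stop("'chrom' must be a single non-empty chromosome label", call. = FALSE)
  }
  if (!is.logical(germline_detected) || length(germline_detected) != 1L ||
      is.na(germline_detected)) {
    stop("'germline_detected' must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(variant_id = as.character(variant_id), chrom = chrom,
         reads_A = read_count(vA, wA), reads_B = read_count(vB, wB),
         germline_detected = germline_detected),
    class = "variant_observation"
  )
}

#' Case configuration for a two-hypothesis MZ-twin comparison
#'
#' @param scenario `"sperm"` (donor identification of a sperm sample; the
#'   per-variant likelihood is the posterior probability that the germline
#'   frequency exceeds the Sanger detection limit) or `"paternity"` (the
#'   likelihood is the posterior mean germline frequency, i.e. the
#'   transmission probability).
#' @param detection_threshold Sanger detection limit used in the sperm
#'   scenario; default 0.05.
#' @param prior Beta prior for the pre-twinning variant frequency, a
#'   [prior_spec()]; default the casework Beta(0.5, 15).
#' @param prior_odds Prior odds of hypothesis A (twin A is the donor) to
#'   hypothesis B; default 1 (equal priors).
#' @param use_absence Logical; if `TRUE`, variants *not* observed in the
#'   germline-derived sample contribute the complement likelihood
#'   (`1 - P(p >= t)` or `1 - E(p)`). By default such variants are treated as
#'   non-informative and excluded, which reproduces standard casework
#'   behaviour.
#'
#' @return An object of class `"scenario_config"`.
#' @examples
#' scenario_config("sperm")
#' scenario_config("paternity", prior = default_prior(exact = TRUE))
#' @export
scenario_config <- function(scenario = c("sperm", "paternity"),
                            detection_threshold = 0.05,
                            prior = default_prior(),
                            prior_odds = 1,
                            use_absence = FALSE) {
  scenario <- match.arg(scenario)
  if (!is.numeric(detection_threshold) || length(detection_threshold) != 1L ||
      !is.finite(detection_threshold) ||
      detection_threshold <= 0 || detection_threshold >= 1) {
    stop("'detection_threshold' must be a single number in (0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(prior_odds) || length(prior_odds) != 1L ||
      !is.finite(prior_odds) || prior_odds <= 0) {
    stop("'prior_odds' must be a single positive number", call. = FALSE)
  }
  if (!is.list(prior) || !is.numeric(prior$alpha) || !is.numeric(prior$beta)) {
    stop("'prior' must be a prior_spec (see default_prior())", call. = FALSE)
  }
  structure(
    list(scenario = scenario, detection_threshold = detection_threshold,
         prior = prior, prior_odds = prior_odds,
         use_absence = isTRUE(use_absence)),
    class = "scenario_config"
  )
}

#' Per-variant likelihood of one hypothesis
#'
#' Likelihood of the germline observation for one variant under the
#' hypothesis that the twin whose posterior is supplied is the donor. For a
#' variant detected in the germline-derived sample: the exceedance probability
#' `P(p >= t)` in the sperm scenario, the posterior mean `E(p)` in the
#' paternity scenario. With `detected = FALSE` the complement is returned
#' (used only when absence evidence is explicitly enabled, see
#' [scenario_config()]).
#'
#' @param post A `"posterior_beta"` for the variant in one twin, built from
#'   the case prior.
#' @param config A [scenario_config()].
#' @param detected Logical; whether the variant was observed in the
#'   germline-derived sample.
#'
#' @return A single likelihood in \[0, 1\].
#' @examples
#' cfg <- scenario_config("sperm")
#' post <- update_posterior(cfg$prior, read_count(0, 65))
#' variant_likelihood(post, cfg) # 4.23e-3
#' @export
variant_likelihood <- function(post, config, detected = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  lik <- switch(config$scenario,
    sperm = exceedance_probability(post, config$detection_threshold),
    paternity = posterior_mean(post)
  )
  if (isTRUE(detected)) lik else 1 - lik
}

#' Likelihood ratio for one variant
#'
#' Ratio of the likelihood of the data under hypothesis A (twin A is the
#' donor) to that under hypothesis B.
#'
#' @param lik_A,lik_B Per-variant likelihoods in (0, 1\].
#' @return `lik_A / lik_B`.
#' @examples
#' variant_lr(0.4372, 4.33e-3) # about 101
#' @export
variant_lr <- function(lik_A, lik_B) {
  for (nm in c("lik_A", "lik_B")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
      stop("'", nm, "' must be a single likelihood in [0, 1]", call. = FALSE)
    }
  }
  if (lik_B == 0) {
    stop("'lik_B' is exactly 0; the beta model never assigns probability 0 ",
         "to detection below threshold 1, so a zero likelihood indicates an ",
         "upstream error (e.g. a degenerate posterior)", call. = FALSE)
  }
  lik_A / lik_B
}

#' Combined likelihood ratio and posterior odds for a case
#'
#' For every variant, the prior is updated with each twin's somatic read
#' counts and the scenario-specific likelihood is computed under both
#' hypotheses; assuming stochastic independence of the variants (reasonable
#' when they lie on different chromosomes), the combined LR is the product of
#' the per-variant LRs, and the posterior odds are the prior odds times the
#' combined LR.
#'
#' Variants not observed in the germline-derived sample are non-informative
#' under the default model and are excluded from the product (with a note in
#' `warnings`); set `use_absence = TRUE` in the configuration to include their
#' complement likelihoods instead. A warning is recorded for every pair of
#' variants sharing a chromosome, where independence may fail.
#'
#' @param observations A list of [variant_observation()] objects (or a
#'   case-table data frame as returned by [read_case_tsv()]).
#' @param config A [scenario_config()].
#'
#' @return An object of class `"twin_case_result"`: a list with
#'   `per_variant` (data frame with posterior parameters, likelihoods, `lr`
#'   and an `included` flag), `combined_lr`, `posterior_odds`, `warnings`,
#'   and the `config` used.
#' @examples
#' obs <- list(variant_observation("snv1", "chr7", 25, 50, 0, 65, TRUE))
#' combine_case(obs, scenario_config("sperm"))
#' @export
combine_case <- function(observations, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.data.frame(observations)) {
    observations <- as_observation_list(observations)
  }
  if (!is.list(observations) || length(observations) == 0L) {
    stop("'observations' must be a non-empty list of variant observations",
         call. = FALSE)
  }
  observations <- lapply(observations, function(o) {
    if (!inherits(o, "variant_observation")) {
      stop("each observation must be a variant_observation()", call. = FALSE)
    }
    o
  })

  ids <- vapply(observations, `[[`, character(1), "variant_id")
  if (anyDuplicated(ids)) {
    stop("duplicate variant_id in case: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  warnings <- character(0)
  rows <- lapply(observations, function(o) {
    post_A <- update_posterior(config$prior, o$reads_A, "A", o$variant_id)
    post_B <- update_posterior(config$prior, o$reads_B, "B", o$variant_id)
    included <- o$germline_detected || config$use_absence
    if (included) {
      lik_A <- variant_likelihood(post_A, config, o$germline_detected)
      lik_B <- variant_likelihood(post_B, config, o$germline_detected)
      lr <- variant_lr(lik_A, lik_B)
    } else {
      lik_A <- lik_B <- lr <- NA_real_
    }
    data.frame(
      variant_id = o$variant_id, chrom = o$chrom,
      germline_detected = o$germline_detected,
      alpha_A = post_A$alpha, beta_A = post_A$beta,
      alpha_B = post_B$alpha, beta_B = post_B$beta,
      lik_A = lik_A, lik_B = lik_B, lr = lr, included = included
    )
  })
  per_variant <- do.call(rbind, rows)

  excluded <- per_variant$variant_id[!per_variant$included]
  if (length(excluded) > 0L) {
    warnings <- c(warnings, paste0(
      "variant(s) not observed in the germline-derived sample treated as ",
      "non-informative and excluded from the combined LR: ",
      paste(excluded, collapse = ", "),
      " (set use_absence = TRUE to use absence as evidence)"))
  }
  if (!any(per_variant$included)) {
    stop("no informative variants: none was observed in the germline-derived ",
         "sample and absence evidence is disabled (use_absence = FALSE)",
         call. = FALSE)
  }

  shared <- unique(per_variant$chrom[per_variant$included][
    duplicated(per_variant$chrom[per_variant$included])])
  if (length(shared) > 0L) {
    warnings <- c(warnings, paste0(
      "variants share chromosome(s) ", paste(shared, collapse = ", "),
      ": stochastic independence may not hold; the combined LR still ",
      "multiplies their contributions"))
  }

  combined_lr <- prod(per_variant$lr[per_variant$included])
  structure(
    list(per_variant = per_variant,
         combined_lr = combined_lr,
         posterior_odds = config$prior_odds * combined_lr,
         warnings = warnings,
         config = config),
    class = "twin_case_result"
  )
}

as_observation_list <- function(df) {
  required <- c("variant_id", "chrom", "vA", "wA", "vB", "wB",
                "germline_detected")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("case table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    variant_observation(df$variant_id[i], df$chrom[i], df$vA[i], df$wA[i],
                        df$vB[i], df$wB[i],
                        as.logical(df$germline_detected[i]))
  })
}

#' @export
print.twin_case_result <- function(x, ...) {
  cat(sprintf("MZ-twin germline case (%s scenario, prior Beta(%g, %g))\n",
              x$config$scenario, x$config$prior$alpha, x$config$prior$beta))
  tab <- x$per_variant
  disp <- data.frame(
    variant = tab$variant_id, chrom = tab$chrom,
    `Beta_A` = sprintf("(%g, %g)", tab$alpha_A, tab$beta_A),
    `Beta_B` = sprintf("(%g, %g)", tab$alpha_B, tab$beta_B),
    lik_A = format_lik(tab$lik_A), lik_B = format_lik(tab$lik_B),
    LR = format_lik(tab$lr),
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  cat(sprintf("combined LR (A vs B): %s  (nearest integer: %s)\n",
              format_lik(x$combined_lr),
              format(round(x$combined_lr))))
  cat(sprintf("posterior odds (prior odds %g): %s\n",
              x$config$prior_odds, format_lik(x$posterior_odds)))
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}
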