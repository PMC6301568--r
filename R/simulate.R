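## Forward simulation of pre-twinning mutation, the twinning split,
## post-twinning growth and sequencing: the synthetic-case generator and the
## brute-force counterpart of the closed-form branching-process model.

#' Simulation settings for a synthetic MZ-twin case
#'
#' Defaults reflect the casework conditions the likelihood model was built
#' for: about five pre-twinning cleavage divisions, somatic sequencing depth
#' near 100x (casework coverage ranges 75x-125x), a 5% Sanger detection
#' limit, and two candidate pre-twinning variants per case.
#'
#' @param m_pre Integer >= 1; pre-twinning cell division cycles.
#' @param m_post Integer >= 0; post-twinning divisions before read-out. With
#'   no post-twinning mutations and synchronous doubling these leave carrier
#'   fractions unchanged; the parameter is retained to make that explicit.
#' @param coverage_mean Expected NGS depth per sample (>= 1). Fixed depth by
#'   default; see `poisson_depth`.
#' @param threshold Sanger detection limit applied to the donor twin's
#'   variant-chromosome fraction, in (0, 1).
#' @param n_variants Number of candidate pre-twinning de novo variants drawn
#'   per case.
#' @param seed Integer seed; identical configuration and seed give a
#'   bit-identical case.
#' @param true_donor `"A"` or `"B"`; which twin's germline sources the
#'   germline-derived sample.
#' @param error_rate Per-read probability of reading the opposite allele;
#'   default 0 (casework treats even single stray reads as real signal).
#' @param poisson_depth Logical; if `TRUE`, depth is Poisson(`coverage_mean`)
#'   per sample instead of fixed.
#'
#' @return An object of class `"simulation_config"`.
#' @examples
#' simulation_config(seed = 1)
#' @export
simulation_config <- function(m_pre = 5, m_post = 10, coverage_mean = 100,
                              threshold = 0.05, n_variants = 2, seed = 1,
                              true_donor = c("A", "B"), error_rate = 0,
                              poisson_depth = FALSE) {
  true_donor <- match.arg(true_donor)
  is_count <- function(x, lo) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo &&
      x == round(x)
  }
  if (!is_count(m_pre, 1)) stop("'m_pre' must be an integer >= 1", call. = FALSE)
  if (!is_count(m_post, 0)) stop("'m_post' must be an integer >= 0", call. = FALSE)
  if (!is_count(coverage_mean, 1)) {
    stop("'coverage_mean' must be an integer >= 1", call. = FALSE)
  }
  if (!is_count(n_variants, 1)) {
    stop("'n_variants' must be an integer >= 1", call. = FALSE)
  }
  if (!is_count(seed, -2^31 + 1)) stop("'seed' must be an integer", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate < 0 || error_rate >= 0.5) {
    stop("'error_rate' must be in [0, 0.5)", call. = FALSE)
  }
  structure(
    list(m_pre = as.integer(m_pre), m_post = as.integer(m_post),
         coverage_mean = as.integer(coverage_mean), threshold = threshold,
         n_variants = as.integer(n_variants), seed = as.integer(seed),
         true_donor = true_donor, error_rate = error_rate,
         poisson_depth = isTRUE(poisson_depth)),
    class = "simulation_config"
  )
}

#' Simulate the frequency of a pre-twinning de novo mutation
#'
#' Brute-force counterpart of [pretwinning_pmf()]: each replicate places a
#' single mutation uniformly at random on one of the `sum(2^(2:(m+1)))`
#' nascent chromosomes synthesised during cycles 1..m, and records the
#' resulting frequency `1/2^(k+1)` of the mutant lineage after cycle m.
#'
#' @param m Integer >= 1; number of division cycles.
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#'
#' @return A data frame with columns `cycle`, `frequency`, `count` and
#'   `proportion` summarising the empirical distribution; every cycle
#'   1..m is present (possibly with count 0).
#' @examples
#' simulate_pretwinning_frequency(3, 1000, seed = 1)
#' @export
simulate_pretwinning_frequency <- function(m, n_reps, seed = NULL) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("'m' must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    stop("'n_reps' must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- seq_len(m)
  # sampling a cycle with weight 2^(k+1) is uniform over nascent chromosomes
  draws <- sample.int(m, n_reps, replace = TRUE, prob = 2^(k + 1))
  counts <- tabulate(draws, nbins = m)
  data.frame(cycle = k, frequency = 1 / 2^(k + 1), count = counts,
             proportion = counts / n_reps)
}

#' Simulate Polya's urn
#'
#' The growth of a mutant cell lineage can be viewed as Polya's urn: balls
#' are drawn one at a time and returned together with one more ball of the
#' same colour (a cell divides into two of its kind). The relative frequency
#' of black balls converges to a Beta(black, white) limit, which motivates
#' the beta law used for the germline variant frequency.
#'
#' @param black,white Initial ball counts (>= 1).
#' @param n_draws Number of draw-and-reinforce steps (>= 0).
#' @param n_reps Number of independent urns to run.
#' @param seed Optional integer seed.
#'
#' @return A numeric vector of length `n_reps`: the final fraction of black
#'   balls in each urn.
#' @examples
#' simulate_polya_urn(1, 1, 500, n_reps = 4, seed = 1)
#' @export
simulate_polya_urn <- function(black, white, n_draws, n_reps = 1,
                               seed = NULL) {
  is_count <- function(x, lo) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo &&
      x == round(x)
  }
  if (!is_count(black, 1) || !is_count(white, 1)) {
    stop("'black' and 'white' must be integers >= 1", call. = FALSE)
  }
  if (!is_count(n_draws, 0)) stop("'n_draws' must be an integer >= 0", call. = FALSE)
  if (!is_count(n_reps, 1)) stop("'n_reps' must be an integer >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  b <- rep.int(as.numeric(black), n_reps)
  total <- black + white
  for (i in seq_len(n_draws)) {
    drew_black <- stats::runif(n_reps) < b / total
    b <- b + drew_black
    total <- total + 1
  }
  b / total
}

#' Simulate one synthetic MZ-twin case
#'
#' Forward simulation of the generative model behind the likelihood
#' framework. Per variant:
#'
#' 1. a mutation cycle `k` is drawn with probability proportional to the
#'    number of nascent chromosomes synthesised in that cycle (equivalently,
#'    per [pretwinning_pmf()]), making `2^(m_pre - k)` of the `2^m_pre`
#'    pre-twinning cells heterozygous carriers;
#' 2. the twinning split allocates the cells half/half to the two embryos by
#'    sampling without replacement (hypergeometric carrier counts), inducing
#'    the negative cross-twin frequency correlation characteristic of the
#'    split;
#' 3. each embryo grows `m_post` synchronous divisions with carriers breeding
#'    true and no new mutations, leaving carrier fractions unchanged;
#' 4. sequencing draws variant reads binomially at the configured depth with
#'    success probability half the carrier-cell fraction (heterozygous
#'    autosomal site: one of two homologous chromosomes carries the variant),
#'    optionally perturbed by a symmetric per-read error rate;
#' 5. the variant is flagged `germline_detected` when the donor twin's
#'    variant-chromosome fraction reaches the Sanger detection limit.
#'
#' The truth table additionally flags each variant as `discriminating` when
#' it is germline-detected *and* at most one variant read was observed in the
#' other twin's somatic sample — the ascertainment under which casework
#' actually reports a variant.
#'
#' @param config A [simulation_config()].
#'
#' @return An object of class `"simulated_case"`: a list with `observations`
#'   (a list of [variant_observation()]), `true_donor`, and `truth`, a data
#'   frame with per-variant columns `variant_id`, `cycle`, `carriers_A`,
#'   `carriers_B`, `freq_A`, `freq_B` (variant-chromosome fractions),
#'   `germline_detected` and `discriminating`.
#' @examples
#' simulate_twin_case(simulation_config(seed = 7))
#' @export
simulate_twin_case <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must be a simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_variants
  N <- 2^config$m_pre
  k <- sample.int(config$m_pre, n, replace = TRUE,
                  prob = 2^(seq_len(config$m_pre) + 1))
  carriers <- 2^(config$m_pre - k)
  # twinning split: N/2 cells per embryo, sampled without replacement
  carriers_A <- stats::rhyper(n, carriers, N - carriers, N / 2)
  carriers_B <- carriers - carriers_A
  # carrier-cell fractions; unchanged by m_post synchronous true-breeding
  # divisions, so read-out after growth equals read-out at the split
  cellfrac_A <- carriers_A / (N / 2)
  cellfrac_B <- carriers_B / (N / 2)
  freq_A <- cellfrac_A / 2 # heterozygous: variant on one of two homologues
  freq_B <- cellfrac_B / 2

  depth <- function() {
    if (config$poisson_depth) {
      stats::rpois(n, config$coverage_mean)
    } else {
      rep.int(config$coverage_mean, n)
    }
  }
  read_prob <- function(f) f * (1 - config$error_rate) + (1 - f) * config$error_rate
  depth_A <- depth()
  depth_B <- depth()
  vA <- stats::rbinom(n, depth_A, read_prob(freq_A))
  vB <- stats::rbinom(n, depth_B, read_prob(freq_B))
  wA <- depth_A - vA
  wB <- depth_B - vB

  donor_freq <- if (config$true_donor == "A") freq_A else freq_B
  other_v <- if (config$true_donor == "A") vB else vA
  detected <- donor_freq >= config$threshold
  discriminating <- detected & other_v <= 1

  ids <- sprintf("var%03d", seq_len(n))
  observations <- lapply(seq_len(n), function(i) {
    variant_observation(ids[i], chrom = as.character(i), vA = vA[i],
                        wA = wA[i], vB = vB[i], wB = wB[i],
                        germline_detected = detected[i])
  })
  structure(
    list(observations = observations,
         true_donor = config$true_donor,
         truth = data.frame(
           variant_id = ids, cycle = k,
           carriers_A = carriers_A, carriers_B = carriers_B,
           freq_A = freq_A, freq_B = freq_B,
           germline_detected = detected, discriminating = discriminating),
         config = config),
    class = "simulated_case"
  )
}

#' Simulate a batch of synthetic MZ-twin cases
#'
#' Runs [simulate_twin_case()] `n_cases` times, re-seeding case `i` with
#' `config$seed + i - 1` so the batch is reproducible and individual cases
#' can be regenerated in isolation.
#'
#' @param n_cases Number of cases.
#' @param config A [simulation_config()]; its `seed` seeds the first case.
#' @return A list of `"simulated_case"` objects.
#' @examples
#' cases <- simulate_twin_cases(3, simulation_config(seed = 1))
#' @export
simulate_twin_cases <- function(n_cases, config) {
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases < 1) {
    stop("'n_cases' must be >= 1", call. = FALSE)
  }
  lapply(seq_len(n_cases), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    simulate_twin_case(cfg)
  })
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("simulated MZ-twin case: %d variant(s), true donor %s\n",
              nrow(x$truth), x$true_donor))
  print(x$truth, row.names = FALSE)
  invisible(x)
}
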