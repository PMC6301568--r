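test_that("scenario likelihoods reproduce reference values", {
  sperm <- scenario_config("sperm")
  paternity <- scenario_config("paternity")

  expect_equal(signif(variant_likelihood(list(alpha = 0.5, beta = 115),
                                         sperm, TRUE), 3), 6.01e-4)
  expect_equal(signif(variant_likelihood(list(alpha = 1.5, beta = 80),
                                         sperm, TRUE), 3), 0.0414)
  expect_equal(signif(variant_likelihood(list(alpha = 1.5, beta = 115),
                                         paternity, TRUE), 4), 0.01288)
  # absence evidence is the exact complement
  post <- list(alpha = 1.5, beta = 80)
  expect_equal(variant_likelihood(post, sperm, FALSE),
               1 - variant_likelihood(post, sperm, TRUE))
})

test_that("per-variant LR reproduces the published odds span", {
  expect_equal(round(variant_lr(0.4372, 4.33e-3)), 101)
  expect_equal(round(variant_lr(0.9999, 0.0414)), 24)
  expect_equal(variant_lr(0.37, 0.37), 1)
  expect_error(variant_lr(1.2, 0.5), "likelihood")
  expect_error(variant_lr(0.5, 0), "exactly 0")
})

test_that("single-variant sperm case reproduces the reference likelihoods", {
  res <- combine_case(list(make_obs(vA = 25, wA = 50, vB = 0, wB = 65)),
                      scenario_config("sperm"))
  expect_gt(res$per_variant$lik_A, 0.9999)
  expect_equal(signif(res$per_variant$lik_B, 3), 4.23e-3)
  expect_equal(res$combined_lr, res$per_variant$lr)
  expect_equal(res$posterior_odds, res$combined_lr)
})

test_that("combined LR follows the product rule", {
  cfg <- scenario_config("sperm")
  one <- combine_case(list(make_obs()), cfg)

  # two independent copies square the LR
  two <- combine_case(list(make_obs("a", "chr1"), make_obs("b", "chr2")), cfg)
  expect_equal(two$combined_lr, one$combined_lr^2,
               tolerance = 1e-12)

  # three heterogeneous variants: engine product equals re-multiplication of
  # individually computed LRs
  obs <- list(make_obs("a", "chr1", 25, 50, 0, 65),
              make_obs("b", "chr2", 50, 50, 1, 65),
              make_obs("c", "chr3", 50, 65, 1, 100))
  res <- combine_case(obs, cfg)
  single_lrs <- vapply(obs, function(o) {
    combine_case(list(o), cfg)$combined_lr
  }, numeric(1))
  expect_equal(res$combined_lr, prod(single_lrs), tolerance = 1e-12)
  expect_equal(res$posterior_odds, res$combined_lr)
})

test_that("combined LR is permutation invariant and lr = 1 is neutral", {
  cfg <- scenario_config("paternity")
  obs <- list(make_obs("a", "chr1", 25, 50, 0, 65),
              make_obs("b", "chr2", 50, 50, 1, 65),
              make_obs("c", "chr3", 50, 65, 1, 100))
  base <- combine_case(obs, cfg)$combined_lr
  expect_equal(combine_case(obs[c(3, 1, 2)], cfg)$combined_lr, base,
               tolerance = 1e-12)

  # identical reads in both twins give lr exactly 1
  neutral <- make_obs("d", "chr4", 10, 90, 10, 90)
  expect_equal(combine_case(list(neutral), cfg)$combined_lr, 1)
  expect_equal(combine_case(c(obs, list(neutral)), cfg)$combined_lr, base,
               tolerance = 1e-12)
})

test_that("swapping twin labels inverts the combined LR", {
  cfg <- scenario_config("sperm")
  obs <- list(make_obs("a", "chr1", 25, 50, 0, 65),
              make_obs("b", "chr2", 50, 50, 1, 100))
  swapped <- lapply(obs, function(o) {
    variant_observation(o$variant_id, o$chrom,
                        vA = o$reads_B$v, wA = o$reads_B$w,
                        vB = o$reads_A$v, wB = o$reads_A$w,
                        o$germline_detected)
  })
  expect_equal(combine_case(swapped, cfg)$combined_lr,
               1 / combine_case(obs, cfg)$combined_lr, tolerance = 1e-12)
})

test_that("carrier likelihood saturates and non-carrier likelihood decays", {
  cfg <- scenario_config("sperm")
  # read fraction fixed at 1/3, well above the 5% threshold
  lik_carrier <- vapply(c(5, 10, 40, 160, 640), function(v) {
    variant_likelihood(update_posterior(cfg$prior, read_count(v, 2 * v)),
                       cfg, TRUE)
  }, numeric(1))
  # non-decreasing (equal once saturated at 1 in double precision)
  expect_true(all(diff(lik_carrier) >= 0))
  expect_true(any(diff(lik_carrier) > 0))
  expect_gt(lik_carrier[5], 0.99999)

  lik_noncarrier <- vapply(c(50, 100, 200, 400), function(w) {
    variant_likelihood(update_posterior(cfg$prior, read_count(1, w)),
                       cfg, TRUE)
  }, numeric(1))
  expect_true(all(diff(lik_noncarrier) < 0))
})

test_that("non-detected variants are excluded by default, used on opt-in", {
  cfg <- scenario_config("sperm")
  obs <- list(make_obs("a", "chr1", 25, 50, 0, 65, detected = TRUE),
              make_obs("b", "chr2", 30, 60, 1, 80, detected = FALSE))
  res <- combine_case(obs, cfg)
  expect_false(res$per_variant$included[2])
  expect_true(is.na(res$per_variant$lr[2]))
  expect_equal(res$combined_lr, res$per_variant$lr[1])
  expect_match(res$warnings, "non-informative", all = FALSE)

  cfg_abs <- scenario_config("sperm", use_absence = TRUE)
  res_abs <- combine_case(obs, cfg_abs)
  expect_true(all(res_abs$per_variant$included))
  pA <- update_posterior(cfg$prior, read_count(30, 60))
  pB <- update_posterior(cfg$prior, read_count(1, 80))
  expect_equal(res_abs$per_variant$lr[2],
               (1 - exceedance_probability(pA, 0.05)) /
                 (1 - exceedance_probability(pB, 0.05)))

  expect_error(
    combine_case(list(make_obs(detected = FALSE)), cfg),
    "no informative variants")
})

test_that("same-chromosome variants multiply but carry a warning", {
  cfg <- scenario_config("sperm")
  obs <- list(make_obs("a", "chr7", 25, 50, 0, 65),
              make_obs("b", "chr7", 50, 50, 1, 65))
  res <- combine_case(obs, cfg)
  expect_match(res$warnings, "share chromosome", all = FALSE)
  expect_equal(res$combined_lr, prod(res$per_variant$lr), tolerance = 1e-12)
})

test_that("case-table data frames and invalid inputs are handled", {
  df <- data.frame(variant_id = c("a", "b"), chrom = c("1", "2"),
                   vA = c(25, 50), wA = c(50, 50), vB = c(0, 1),
                   wB = c(65, 65), germline_detected = c(TRUE, TRUE))
  cfg <- scenario_config("sperm")
  expect_equal(combine_case(df, cfg)$combined_lr,
               combine_case(as_obs_list <- list(
                 make_obs("a", "1", 25, 50, 0, 65),
                 make_obs("b", "2", 50, 50, 1, 65)), cfg)$combined_lr)

  expect_error(combine_case(list(), cfg), "non-empty")
  expect_error(
    combine_case(list(make_obs("x"), make_obs("x", "chr2")), cfg),
    "duplicate variant_id")
  expect_error(scenario_config("sperm", detection_threshold = 0), "\\(0, 1\\)")
  expect_error(scenario_config("sperm", prior_odds = -2), "positive")
})
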