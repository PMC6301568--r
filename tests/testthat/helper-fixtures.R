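# Casework reference scenarios: somatic read-count combinations spanning the
# observed range (variant:wild-type from 1:1 to 1:3 in the carrier twin, at
# most one variant read in the other twin) with their published posterior
# summaries under the Beta(0.5, 15) prior. Wild-type counts are chosen so the
# posteriors are Beta(., 65), Beta(., 80) and Beta(., 115).
# tail_ref / mean_ref carry the published display precision; carrier-twin tail
# probabilities are published only as the bound > 0.9999. mean_ref is NA for
# the one combination whose published posterior mean (0.2537) is inconsistent
# with E(p) = alpha/(alpha+beta) (= 0.2417) and is excluded from checks.
reference_rows <- function() {
  data.frame(
    twin = c("A", "A", "A", "A", "B", "B", "B", "B"),
    v = c(25, 50, 25, 50, 0, 0, 1, 1),
    w = c(50, 50, 65, 65, 65, 100, 65, 100),
    alpha = c(25.5, 50.5, 25.5, 50.5, 0.5, 0.5, 1.5, 1.5),
    beta = c(65, 65, 80, 80, 80, 115, 80, 115),
    tail_ref = c(NA, NA, NA, NA, 4.23e-3, 6.01e-4, 0.0414, 8.01e-3),
    tail_sigfig = c(NA, NA, NA, NA, 3, 3, 3, 3),
    mean_ref = c(0.2818, 0.4372, NA, 0.3870, 6.21e-3, 4.33e-3, 0.0184,
                 0.01288),
    mean_sigfig = c(4, 4, NA, 4, 3, 3, 3, 4)
  )
}

# the strongest carrier-twin / weakest non-carrier reference pairing, whose
# paternity LR rounds to 101
make_obs <- function(id = "snv1", chrom = "chr1", vA = 25, wA = 50, vB = 0,
                     wB = 65, detected = TRUE) {
  variant_observation(id, chrom, vA, wA, vB, wB, detected)
}

write_case_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

case_header <- "variant_id\tchrom\tvA\twA\tvB\twB\tgermline_detected"
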