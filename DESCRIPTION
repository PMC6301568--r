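Package: twinlr
Title: Likelihood Ratios for Germline Discrimination Between Monozygotic Twins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the evidence that one of two monozygotic twins is the
    source of germline-derived cells (a sperm sample, or the paternal alleles of
    a child) from next-generation sequencing read counts of discriminating
    somatic variants. A branching-process model of pre-twinning embryonic cell
    divisions yields a beta prior for the frequency of an early de novo
    mutation; Bayesian updating with somatic variant and wild-type read counts
    gives per-twin beta posteriors, from which scenario-specific likelihoods
    (a Sanger detection-limit tail probability for sperm samples, a posterior
    mean transmission probability for paternity disputes), per-variant
    likelihood ratios, combined likelihood ratios and posterior odds are
    computed. Includes a forward simulator of pre-twinning mutation, the
    twinning split and sequencing, a TSV/JSON case interface and a command-line
    tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
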