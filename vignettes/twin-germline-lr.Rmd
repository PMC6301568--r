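---
title: "Quantifying germline evidence between monozygotic twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying germline evidence between monozygotic twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlr)
```

## The problem

Monozygotic (MZ) twins arise from a single zygote and are genetically
identical at every marker used in routine forensic work, so short tandem
repeat profiling cannot say which twin donated a sperm sample, or which twin
fathered a child. What does distinguish them are post-zygotic de novo
mutations: variants that arose during embryonic development and are therefore
present at different cell fractions in the two twins. Deep sequencing of
somatic tissue (saliva or blood) identifies such *discriminating variants* —
present in the soma and germline of one twin but absent, or seen in at most a
stray read, in the other — and targeted Sanger sequencing then checks whether
each variant is present in the germline-derived material (the sperm sample,
or the paternal alleles of the child).

Courts require that this evidence be summarised as a likelihood ratio (LR)
between the two exhaustive hypotheses

* **A**: the germline-derived cells came from twin A, and
* **B**: they came from twin B,

third-party donors having been excluded beforehand by conventional STR
evidence. `twinlr` implements the full chain from read counts to posterior
odds.

## A beta prior from the embryonic branching process

The quantity the data inform is $p_{X,k}$, the frequency of the $k$-th
variant among the germ cells of twin $X$. Two observations motivate a beta
law for it.

First, the growth of a mutant cell lineage through successive divisions is a
realisation of Polya's urn: drawing a ball (a cell divides) returns it with
another of the same colour, and the black-ball fraction converges to a beta
distribution. `simulate_polya_urn()` reproduces this convergence and is
exercised in the test suite against the Beta(1, 1) limit of the symmetric
urn.

Second, the beta family is conjugate to binomial read counts, so the whole
analysis reduces to parameter arithmetic.

The prior is anchored in the discrete branching process of the pre-twinning
embryo. During cycle $k$ the embryo synthesises $2^{k+1}$ nascent
chromosomes, each an equally likely mutation target, and a mutation in cycle
$k$ ends up at frequency $1/2^{k+1}$. After $m$ cycles,

$$P\!\left(p = \tfrac{1}{2^{k+1}}\right) = \frac{2^{k-1}}{2^m - 1},
\qquad k = 1, \dots, m,$$

implemented in `pretwinning_pmf()` (integer $m$ only — the derivation counts
discrete cycles). Its moments have closed forms that extend smoothly to real
$m$:

$$\mathrm{E}(p) = \frac{m}{2^{m+2} - 4}, \qquad
\mathrm{Var}(p) = \frac{1}{16\,(2^m-1)}\left[\frac{2^m - 1}{2^{m-1}} -
\frac{m^2}{2^m - 1}\right].$$

Both are verified in the tests against brute-force enumeration of every
nascent-chromosome target for $m \le 15$ at tolerance $10^{-12}$, and against
a Monte-Carlo simulator (`simulate_pretwinning_frequency()`) by total
variation distance.

### Choice of m and of the prior shapes

MZ twinning almost always occurs within the first week, about a quarter of
splits pre-dating day-5 blastocyst formation, at roughly one division per
day. Weighting division counts accordingly gives
`mean_pretwinning_divisions()` $= 0.25\cdot\overline{1..5} +
0.75\cdot\overline{6..7} = 5.625$; casework convention nevertheless works
with $m = 5.5$, and the package follows that convention as its default while
exposing the averaging helper so the small discrepancy stays visible.

At $m = 5.5$, $\mathrm{E}(p) = 0.03107$ and $\mathrm{Var}(p) = 0.0017968$.
Matching a Beta($\alpha$, $\beta$) to these moments
(`beta_from_moments()`) gives $\alpha = 0.4895$, $\beta = 15.2652$. Note that
matching the 3-significant-figure *rounded* moments instead gives
$\beta \approx 15.251$; `twinlr` always matches the full-precision moments.
For casework the shapes are rounded to the memorable **Beta(0.5, 15)**
(`default_prior()`), and every reference number below uses that rounding;
`default_prior(exact = TRUE)` opts into the unrounded shapes.

```{r prior}
default_prior()
beta_from_moments(expected_frequency(5.5), frequency_variance(5.5))
```

## Bayesian updating and the two scenarios

Observing $v_{X,k}$ variant and $w_{X,k}$ wild-type reads in twin $X$'s
somatic sample updates the prior to

$$p_{X,k} \sim \mathrm{Beta}(\alpha + v_{X,k},\; \beta + w_{X,k}).$$

A single shared prior is used for both twins. This is deliberately
conservative: the twinning split allocates the pre-twinning cells to the two
embryos *without* replacement, so a high variant frequency in one twin if
anything argues for a *lower* frequency in the other; raising the
non-carrier twin's prior to match the carrier's data would favour the
non-carrier hypothesis. By the same conservative logic a single variant read
in the "other" twin is treated as genuine low-level pre-twinning signal,
never filtered as sequencing error.

The per-variant likelihood of hypothesis $X$ depends on the scenario
(`scenario_config()`):

* **Sperm-donor identification.** The variant was called by Sanger
  sequencing in the sperm sample, and the Sanger detection limit is about
  5%. Conservatively,
  $\mathrm{lik}_k(X) = P(p_{X,k} \ge 0.05)$, the upper tail of the
  regularized incomplete beta function (`exceedance_probability()`,
  evaluated by `stats::pbeta`; the distribution is continuous so
  $\ge$ and $>$ coincide). The accuracy contract is $10^{-6}$ relative,
  checked against adaptive quadrature of the beta density.
* **Paternity.** Inheritance of the variant by the child is a random draw
  from the father's germline, so
  $\mathrm{lik}_k(X) = \mathrm{E}(p_{X,k}) =
  \alpha_{X,k}/(\alpha_{X,k}+\beta_{X,k})$ (`posterior_mean()`).

Variants on different chromosomes are treated as stochastically independent,
so `combine_case()` multiplies per-variant LRs,
$\mathrm{LR} = \prod_k \mathrm{lik}_k(A)/\mathrm{lik}_k(B)$, and reports
posterior odds as prior odds (default 1:1) times the combined LR. Variants
sharing a chromosome are still multiplied — no joint model is available —
but a prominent warning is attached. Variants *not* seen in the
germline-derived sample are non-informative under the default model and are
excluded; setting `use_absence = TRUE` instead includes their complement
likelihoods $1 - \mathrm{lik}_k(X)$. The default reproduces standard
casework reporting; the complement treatment is a principled extension that
should be enabled knowingly, which is why it is opt-in.

```{r case}
obs <- list(
  variant_observation("snv1", "chr7", vA = 25, wA = 50, vB = 0, wB = 65,
                      germline_detected = TRUE),
  variant_observation("snv2", "chr2", vA = 50, wA = 50, vB = 1, wB = 65,
                      germline_detected = TRUE))
combine_case(obs, scenario_config("sperm"))
```

Likelihoods are displayed at reporting precision (scientific below $10^{-2}$,
four decimals otherwise, LRs additionally as nearest integers); full
precision is kept internally and written alongside in reports
(`write_report()`).

### A note on one degenerate quantity

For a carrier twin with strong counts the tail probability saturates: with
$v:w$ around 1:2 and depth a few hundred, $P(p \ge 0.05)$ is
indistinguishable from 1 in double precision. Reports print such values as
`1.0000`; the bound "> 0.9999" is what is scientifically defensible, and the
tests assert the bound rather than equality. Relatedly, because likelihoods
are derived from updated beta laws alone, the LR grows without limit as
coverage increases; at realistic coverage (75–125×) the beta-derived
likelihoods dominate any correction for recurrent germline mutation
(rate ~$10^{-8}$), which is why recurrence is not modelled.

## The forward simulator

`simulate_twin_case()` generates synthetic cases from the same generative
story the closed-form model assumes, and doubles as its end-to-end check:

1. a mutation cycle is drawn uniformly over nascent-chromosome targets
   (`m_pre = 5` cycles by default), tagging $2^{m_{pre}-k}$ of the
   $2^{m_{pre}}$ cells as heterozygous carriers;
2. the twinning split assigns exactly half the cells to each embryo by
   sampling without replacement (`stats::rhyper`);
3. each embryo grows `m_post` synchronous divisions with carriers breeding
   true; with no post-twinning mutations this leaves carrier fractions
   unchanged, and the parameter exists to make that assumption explicit;
4. reads are binomial at fixed depth (default 100×, the middle of the
   75–125× casework range; a Poisson-depth option exists, default off) with
   success probability half the carrier-cell fraction — a heterozygous
   autosomal variant sits on one of two homologous chromosomes, consistent
   with observed carrier-twin read ratios between 3:1 and 1:1
   (wild-type : variant);
5. the variant is `germline_detected` when the donor twin's
   variant-chromosome fraction reaches the 5% Sanger limit, and flagged
   `discriminating` when additionally at most one variant read appears in
   the other twin's soma — the ascertainment under which casework reports a
   variant at all.

Default sequencing error is zero, matching the conservative stance that even
single stray reads are treated as real; a symmetric per-read error rate is
available for robustness studies.

Two behaviours of the simulator deserve emphasis. Marginally across variants
the twin frequencies are *positively* correlated, because both inherit the
variability of the mutation cycle (early mutations are common in both twins,
late ones rare in both); the anti-correlation induced by sampling without
replacement appears *conditionally* on the mutation cycle, and that is how
the tests assert it. And donor recovery must be read conditionally on
ascertainment: among all simulated germline-detected variants the combined
LR favours the true donor only about two-thirds of the time (symmetric
splits produce coin-flip LRs), whereas among cases with at least one
*discriminating* variant — the only cases a laboratory would ever report —
recovery exceeds 95%, as the acceptance-level test verifies on 1000 seeded
cases at 100× with two candidate variants each.

### What the simulator does not emulate

The germline and the somatic read-out are a single post-split lineage: the
primordial germ-cell bottleneck (some 15 divisions and an intermediate
population contraction separate the split from germline commitment) is not
modelled, nor is spatial clustering of carrier cells in the embryo, nor
post-twinning mutation, nor any sequencing-error structure beyond the
optional symmetric rate. Passing tests therefore show internal consistency
of model and generator under shared assumptions — not that real germline
frequencies follow the updated beta law exactly.

## Problem sizes and numerical choices

The test suite enumerates the pmf exactly up to $m = 15$; Monte-Carlo checks
use $2\times10^5$ replicates for the frequency distribution (total-variation
tolerance 0.01), $10^4$ urns of 2000 draws for the Polya limit
(Kolmogorov–Smirnov distance below 0.02), and 1000 simulated cases for the
end-to-end donor-recovery property; the whole suite runs in well under a
minute. Tail probabilities use `stats::pbeta` (continued-fraction
implementation of the regularized incomplete beta, far exceeding the
$10^{-6}$ contract); no bespoke numerics are involved. All simulation entry
points take explicit integer seeds and are bit-reproducible;
`simulate_twin_cases()` seeds case $i$ with `seed + i - 1` so any single
case can be regenerated alone.

## Known limitations

* The two-hypothesis setting is assumed exhaustive; mixtures and third
  donors are out of scope (handled upstream by STR evidence).
* Recurrent mutation is not modelled (see above); the reported LR is
  conservative at current coverage but would formally diverge with coverage.
* The TSV case format is the native interface; VCF import is deliberately
  not provided, as the case data (two read-count pairs plus an external
  Sanger flag per variant) do not map naturally onto VCF.
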