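# twinlr

Likelihood ratios for deciding which of two monozygotic (MZ) twins is the
source of germline-derived cells — a sperm sample in a criminal case, or the
paternal alleles of a child in a paternity dispute — from NGS read counts of
discriminating somatic variants. Intended for forensic geneticists and
statisticians who must report the probative value of twin-discrimination
sequencing results, and for methodologists studying the underlying model.

## The model

MZ twins are identical at every routine forensic marker, but de novo
mutations arising during early embryonic development are present at
different cell fractions in the two twins. For the *k*-th discriminating
variant, the unknown germline frequency *p*<sub>X,k</sub> in twin *X* is
given a beta prior derived from the branching process of the pre-twinning
embryo: a mutation in division cycle *k* of *m* has frequency 1/2^(k+1)
with probability 2^(k−1)/(2^m − 1), whence

- E(p) = m / (2^(m+2) − 4),
- Var(p) = [ (2^m − 1)/2^(m−1) − m²/(2^m − 1) ] / (16 (2^m − 1)).

At the conventional m = 5.5 pre-twinning divisions, moment matching gives
α = 0.4895, β ≈ 15.27, rounded for casework to **Beta(0.5, 15)**. Somatic
read counts (v variant, w wild-type) update this conjugately to
Beta(0.5 + v, 15 + w) per twin. The per-variant likelihood of "twin X is
the donor" is

- **sperm scenario**: P(p<sub>X,k</sub> ≥ 0.05), the posterior probability
  of exceeding the Sanger detection limit;
- **paternity scenario**: E(p<sub>X,k</sub>) = α<sub>X,k</sub>/(α<sub>X,k</sub>+β<sub>X,k</sub>),
  the transmission probability.

Independent variants multiply: LR = Π<sub>k</sub> lik<sub>k</sub>(A)/lik<sub>k</sub>(B),
and posterior odds = prior odds × LR (equal priors by default). A forward
simulator of pre-twinning mutation, the without-replacement twinning split
and sequencing generates synthetic cases and validates the closed forms.
See the vignette (`vignettes/twin-germline-lr.Rmd`) for the full account.

## Worked example

A sperm-sample case with two discriminating variants, both confirmed in the
sperm sample by Sanger sequencing; twin A's saliva shows strong variant
signal, twin B's at most one stray read:

```r
library(twinlr)
obs <- list(
  variant_observation("snv1", "chr7", vA = 25, wA = 50, vB = 0, wB = 65,
                      germline_detected = TRUE),
  variant_observation("snv2", "chr2", vA = 50, wA = 50, vB = 1, wB = 100,
                      germline_detected = TRUE))
combine_case(obs, scenario_config("sperm"))
```

```
MZ-twin germline case (sperm scenario, prior Beta(0.5, 15))
 variant chrom     Beta_A     Beta_B  lik_A    lik_B       LR
    snv1  chr7 (25.5, 65)  (0.5, 80) 1.0000 4.23e-03 236.2872
    snv2  chr2 (50.5, 65) (1.5, 115) 1.0000 8.01e-03 124.7670
combined LR (A vs B): 29480.8423  (nearest integer: 29481)
posterior odds (prior odds 1): 29480.8423
```

Each variant's prior is updated with each twin's read counts (`Beta_A`,
`Beta_B`); under hypothesis A the probability that the germline frequency
clears the 5% Sanger limit is near 1, under hypothesis B it is a few per
mille, and the data are about 29,000 times more likely if twin A is the
donor. The same case under `scenario_config("paternity")` uses posterior
means instead and yields a combined LR of 1540.

The same analysis from the shell, via the installed `twinlr` script:

```sh
twinlr simulate --n-cases 1 --seed 7 --out cases/     # synthetic case TSVs
twinlr lr --scenario sperm --input cases/case0001.tsv # report to stdout
twinlr prior --m 5.5 --json                           # the prior itself
```

Case TSVs have the header
`variant_id chrom vA wA vB wB germline_detected` (tab-separated,
`germline_detected` ∈ {0,1}); reports are TSV or JSON (`--json`).

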