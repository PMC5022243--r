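---
title: "Genomic prediction with dominance and imprinting effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with dominance and imprinting effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintgp)
```

## The problem

In livestock genetic evaluation, most genomic prediction models treat the two
alleles an animal carries as exchangeable and additive. Two biologically
well-documented departures are **dominance** (an interaction between the two
alleles at a locus) and **genomic imprinting** (parent-of-origin-dependent
expression: the paternally and maternally inherited copies contribute
differently). Both have been reported to contribute a few percent of the
phenotypic variance of pig production traits such as average daily gain and
backfat thickness. `imprintgp` implements a complete analysis around this
question: it decomposes genetic variance into additive, dominance and
imprinting components from phased SNP genotypes, compares models with and
without the non-additive terms, and measures what the extra terms buy (or
cost) in hold-out prediction of breeding values.

## The model

For corrected phenotypes $\mathbf{y}_c$ (records pre-adjusted for
herd/sex/pen-type effects, so that only birth year remains as a fixed effect)
the full model is

$$\mathbf{y}_c = \mathbf{X}\mathbf{b} + \mathbf{M}_a \mathbf{q}_a +
\mathbf{M}_d \mathbf{q}_d + \mathbf{M}_i \mathbf{q}_i +
\mathbf{Z}_l \mathbf{l} + \mathbf{e},$$

with birth-year fixed effects $\mathbf{b}$ (flat prior; there is no separate
intercept, which is absorbed by the year effects), random litter effects
$\mathbf{l} \sim N(0, \mathbf{I}\sigma^2_l)$, residuals
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$, and per-SNP effect vectors
$\mathbf{q}_a, \mathbf{q}_d, \mathbf{q}_i$. Reduced models drop dominance
and/or imprinting: the model names A, AD, AI and ADI name the effect sets.

For a biallelic SNP with alleles $A_1$, $A_2$ at frequency $p$ of $A_2$, the
three codings for an individual's genotype (paternal allele written first)
are

| genotype | $M_a$ | $M_d$ | $M_i$ |
|----------|--------|--------|--------|
| $A_1A_1$ | $-2p$ | $-2p^2$ | $0$ |
| $A_1A_2$ | $1-2p$ | $2p(1-p)$ | $+1$ |
| $A_2A_1$ | $1-2p$ | $2p(1-p)$ | $-1$ |
| $A_2A_2$ | $2-2p$ | $-2(1-p)^2$ | $0$ |

$M_a$ is the centred allele count; $M_d$ a centred heterozygosity contrast;
$M_i$ a signed contrast of the reciprocal heterozygotes, which requires
phased genotypes with known parental origin. Package-wide convention: **the
paternal allele is the first allele of the phased VCF genotype pair.**
Under Hardy–Weinberg genotype frequencies all three codings have mean zero
and variances $2p(1-p)$, $(2p(1-p))^2$ and $2p(1-p)$ respectively (the
imprinting case additionally requires random mating so that the reciprocal
heterozygotes are equally frequent); these are exactly the per-SNP weights
used in the variance formulas below, and the package's tests verify them by
enumeration over the genotype classes.

### Prior on SNP effects

Each effect vector has the four-component normal mixture prior

$$q \sim \pi_1 N(0,\sigma^2_{\pi 1}) + \pi_2 N(0,\sigma^2_{\pi 2}) +
\pi_3 N(0,\sigma^2_{\pi 3}) + \pi_4 N(0,\sigma^2_{\pi 4}),$$

with known mixing proportions, by default
$\pi = (0.889, 0.1, 0.01, 0.001)$: most SNPs have a small variance and a few
a large one. The class variances are model parameters with flat priors under
the ordering constraint
$\sigma^2_{\pi 1} < \sigma^2_{\pi 2} < \sigma^2_{\pi 3} < \sigma^2_{\pi 4}$
(one ordered ladder per effect type). $\sigma^2_l$ and $\sigma^2_e$ also get
flat priors.

## The Gibbs sampler

`fit_genomic_mixture()` runs a single-site Gibbs chain (RcppArmadillo core).
One full scan updates, in order:

1. each birth-year effect from its normal conditional;
2. each litter effect from its normal conditional given $\sigma^2_l$;
3. for each effect type and each SNP, the mixture-class indicator from the
   categorical posterior proportional to $\pi_c \times$ the marginal
   likelihood with the effect integrated out (the numerically stable choice
   for mixture-prior samplers), then the effect from its normal full
   conditional under the selected class variance; residuals are updated
   incrementally after every change and re-synchronised against a
   from-scratch recomputation every 1000 iterations (the maximum discrepancy
   is reported and tested to stay below $10^{-6}$);
4. each class variance from its flat-prior conditional
   $S_c / \chi^2_{k_c-2}$ ($k_c$ = effects in the class, $S_c$ = their sum of
   squares), enforcing the ordering by rejection (up to 100 redraws, else the
   previous value is kept);
5. $\sigma^2_l$ and $\sigma^2_e$ from their scaled inverse-chi-square
   conditionals.

Defaults mirror the published protocol: chain length 50,000, burn-in 20,000;
the package adds thinning (default 10) purely to bound storage — posterior
means are insensitive to it. Posterior means of the saved samples are the
parameter estimates. Mixing is summarised by a batch-means time-series SE per
variance parameter; a parameter is flagged as well mixed when the SE is below
5 % of the absolute posterior mean (read as a relative criterion; when the
mean is numerically zero the posterior SD is used as the reference and the
output says so). All randomness flows through R's RNG, so a seed fixes the
chain exactly.

### Sparsely populated mixture classes

The flat prior makes the class-variance conditional $S_c/\chi^2_{k_c-2}$,
which is improper for $k_c \le 2$ — and, less obviously, *badly behaved* well
above that: its mean is infinite for $k_c \le 4$ and its variance infinite
for $k_c \le 6$. The genetic variance components (next section) are linear in
the class variances, so a class holding a handful of SNPs injects
heavy-tailed spikes straight into their posterior means. At the data scale
this model is built for (tens of thousands of SNPs, expected class counts in
the tens to thousands) the issue never arises; in small simulated data it
dominates.

The package therefore treats a class with fewer than 7 assigned effects as
*near-empty* and redraws its variance uniformly between its neighbours,
bounded within one octave ($\times 2$) of the nearest populated side: the top
class draws from $U(\sigma^2_{\pi 3}, 2\sigma^2_{\pi 3})$, the bottom from
$U(\sigma^2_{\pi 2}/2, \sigma^2_{\pi 2})$, an interior class from
$U(\text{lower}, \min(\text{upper}, 2\cdot\text{lower}))$, everything floored
at $10^{-12} \times$ the phenotypic variance. The octave bound is the result
of explicit experimentation, not taste: bounds that track the chain's own
state let chained redraws of several empty classes ratchet the ladder upwards
without limit (or, with the opposite rule, contract it irreversibly until the
genetic signal collapses), and generous fixed headroom parks empty classes
far above the data-supported ladder, biasing the variance decomposition
upward through the $\pi_3, \pi_4$ terms. One octave keeps an empty class
distinguishable from its neighbour — the indicator step can still move SNPs
into it, after which the proper conditional carries it wherever the data
demand — while perturbing the decomposition minimally. This rule is a
numerical safeguard of this implementation; at the data scale the model is
designed for it never activates, because every class holds many SNPs.

Initialisation: year effects at within-year means, litter and SNP effects at
zero, $\sigma^2_e$ at half the phenotypic variance, $\sigma^2_l$ at 5 % of
it, and each class-variance ladder geometric ($10^{i-2}$, $i = 1..4$) scaled
so its $\pi$-weighted mean matches the genetic effects jointly starting at
half the phenotypic variance. A ladder initialised far below the plausible
per-SNP scale can strand the chain in a collapsed state (everything shrunk to
zero and the residual absorbing the genetic variance), which is a mode of the
flat-prior posterior at small SNP numbers; the data-scale initialisation
avoids it.

## Variance components and heritabilities

Genetic variances are computed from the mixture parameters:

$$\hat\sigma^2_a = \sum_{j=1}^{m} 2p_j(1-p_j) \sum_{i=1}^{4}
\pi_i \sigma^2_{a\pi_i},$$

and analogously with weight $(2p_j(1-p_j))^2$ for dominance and $2p_j(1-p_j)$
for imprinting. The additive weight is the standard one in the genomic
prediction literature; only the additive case is conventionally written out,
so the dominance and imprinting weights are **derived** here: each equals the
variance of the corresponding coding column
under Hardy–Weinberg/random-mating frequencies, verified in the tests both by
enumeration over genotype classes and by Monte-Carlo simulation. Components
are evaluated **per saved MCMC sample** and then averaged — exact for these
linear-in-$\sigma^2$ formulas and consistent with using posterior means as
estimates.

`variance_decomposition()` reports each component, its posterior SD, its
proportion of the phenotypic variance (the sum of the components in the
model, computed per sample and averaged) and the proportion's SD.
Narrow-sense heritability $h^2_a$ is the additive share (the
parent-of-origin-independent definition); broad-sense $H^2$ is the share of
the total genetic variance.

## Model comparison and validation

**Pseudo Bayes factors.** Per-observation conditional predictive ordinates
(CPO) are accumulated during sampling by the harmonic-mean estimator,
$\widehat{CPO}_i = T / \sum_t 1/N(y_i;\, \hat y_i^{(t)}, \sigma_e^{2(t)})$,
over the training observations (the standard choice). Twice the log ratio of pseudo-marginal likelihoods, $2\ln K$, compares
a model against the additive baseline, with evidence bands $2$–$6$
"positive" and $6$–$10$ "very strong"; the package labels values below 0
"negative", 0–2 "weak" and above 10 "decisive" for completeness.

**Hold-out validation.** `split_by_date()` cuts the population at a birth
date (training before, validation on/after — the study design this emulates
used 2013-04-01, leaving roughly 77 % / 23 %). Design matrices are always
centred with **training-set** allele frequencies — several reference
populations for $p_j$ would be defensible, and using training frequencies
keeps the validation honest. Reliability is
$r^2 = \mathrm{cor}^2(\text{prediction}, y_c) / h^2_{y_c}$ with
$h^2_{y_c} = \sigma^2_a/(\sigma^2_a+\sigma^2_l+\sigma^2_e)$ computed once
from the additive-only model A on training data and reused for every model,
so it scales but never reorders comparisons. GBV is the additive prediction
$M_a\hat q_a$; GTV sums all genetic terms in the model. Reliability
differences against model A are tested with the Hotelling–Williams t test for
dependent correlations sharing $y_c$ (applied to correlations, not squared
correlations; two-sided p-values, df $= n-3$), and bias is the OLS regression
of $y_c$ on the prediction (slope 1, intercept 0 = unbiased).

## The synthetic-data generator

No real dataset ships with the package, so `simulate_population()` generates
the study conditions it targets: litters of full sibs (sizes $1 + \text{Poisson}(\bar s - 1)$
— the one-parameter family reproducing the reported mean full-sib family size
of 2.44; the size distribution itself is not reported), each litter from its
own founder sire and dam whose gametes are Bernoulli($p_j$) draws, offspring
phased by construction (paternal gamete first). Defaults emulate the backfat
analysis: 8113 individuals, 33004 SNPs, variance targets
(0.341, 0.045, 0.015) for additive/dominance/imprinting, litter 0.059,
residual 0.657 (mm²), $\pi = (0.889, 0.1, 0.01, 0.001)$, 17 birth years,
23 % validation fraction. SNP effects are drawn from the mixture (relative
class variances 0.1/1/10/100, the package's choice) and **rescaled so the
analytic genetic variance hits its target exactly**, which makes recovery
tests sharp. Allele frequencies are uniform on a configurable range
(default 0.05–0.95).

What the generator deliberately does *not* emulate: linkage disequilibrium
beyond family structure (the real SNPs are genome-wide), half-sib structure
(each litter has its own parents), sex chromosomes, selection, missing
genotypes, or pre-correction error in $y_c$. Passing recovery tests on these
simulations therefore demonstrates the correctness of the machinery under the
model's own assumptions, not robustness to LD, pedigree depth or
ascertainment in real data.

## Quality control

`qc_filter()` applies the standard chip-QC thresholds with strict
inequalities, in a fixed order (fixed for reproducibility; the filters
themselves do not impose one): samples with
call rate < 0.8 are excluded first, then SNPs with call rate ≤ 0.9, minor
allele frequency ≤ 0.01, or Hardy–Weinberg chi-square p ≤ 10⁻⁷ (1 df,
reciprocal heterozygotes pooled — the test concerns genotype, not parental
origin; fixed SNPs get p = 1). Residual missing genotypes are set to the
coding-column expectation, which is 0 for all three centred/signed codings
and leaves column means unchanged; upstream imputation is out of scope.

## Problem sizes used by the tests

The test-suite and acceptance-script simulations are deliberately far smaller
than the defaults, chosen as the smallest sizes at which each property is
informative: coding identities and QC run on hundreds of individuals;
closed-form sampler oracles at $n = 200$, $m = 50$; the full ADI
parameter-recovery check at $n = 2000$, $m = 2000$ with 10,000 iterations
(4,000 burn-in); model-comparison properties at $n \approx 800$,
$m \approx 300$ with strong simulated dominance. At these sizes the upper
mixture classes hold few SNPs, which is exactly the regime where the
near-empty-class rule above matters; results quoted anywhere by the package
are produced by these runs, not transcribed from elsewhere.

## Known limitations

* Variance components from the $\pi$-weighted formula are only as good as the
  class-variance estimates; with few SNPs the upper classes are weakly
  identified and the decomposition inherits flat-prior upward bias even with
  the stabilising rules above. This is a property of the model at small $m$,
  not of the implementation, and disappears as class counts grow.
* The sampler is single-chain by design (matching the published protocol);
  convergence is assessed by time-series SE, not multi-chain diagnostics.
* Imprinting requires correctly phased heterozygotes; phase error directly
  attenuates $M_i$ and is not modelled.
* $h^2_{y_c}$ from model A is a pragmatic stand-in for the pedigree-based
  heritability the original analysis used; reliabilities scale accordingly
  (comparisons between models are unaffected).
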