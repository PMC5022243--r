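# imprintgp

Bayesian genomic prediction for livestock traits when the textbook additive
model is not enough: `imprintgp` fits mixture-prior ("BayesR-style") models
that decompose SNP effects into **additive**, **dominance** (intra-locus
allele interaction) and **genomic imprinting** (parent-of-origin-dependent
expression) components from phased genotypes, estimates how much phenotypic
variance each contributes, compares the models by pseudo Bayes factors, and
measures what the extra components buy in hold-out prediction of breeding
values. It is aimed at animal breeders and quantitative geneticists working
with phased SNP chip data on populations with family structure (the motivating
setting is Duroc pig production traits: average daily gain and backfat
thickness).

## The model

Corrected phenotypes are modelled as

```
y_c = X b + M_a q_a (+ M_d q_d) (+ M_i q_i) + Z l + e
```

with birth-year fixed effects `b`, random litter effects
`l ~ N(0, I sigma2_l)`, residuals `e ~ N(0, I sigma2_e)`, and per-SNP effect
vectors under a four-component normal mixture prior

```
q ~ 0.889 N(0, s1) + 0.1 N(0, s2) + 0.01 N(0, s3) + 0.001 N(0, s4),
s1 < s2 < s3 < s4  (flat priors on the ordered class variances)
```

The genotype codings at a SNP with allele frequency `p` (paternal allele
first) are `M_a`: −2p / 1−2p / 2−2p for A1A1 / heterozygote / A2A2;
`M_d`: −2p² / 2p(1−p) / −2(1−p)²; `M_i`: 0 / +1 (A1A2) / −1 (A2A1) / 0.
Effect sets define the four models **A**, **AD**, **AI**, **ADI**. Genetic
variances come from the mixture parameters, e.g.

```
sigma2_a = sum_j 2 p_j (1-p_j) * sum_i pi_i * s_i(additive)
```

(dominance uses weight `(2p(1-p))²`, imprinting `2p(1-p)`). Models are fitted
by a single-chain Gibbs sampler (RcppArmadillo core); model comparison uses
`2lnK` built from conditional predictive ordinates; validation reports
reliability `r² = cor²(prediction, y_c) / h²_yc`, Hotelling–Williams tests
against the additive baseline, and bias regressions. See the methods vignette
(`vignettes/imprintgp-methods.Rmd`) for the full account, including the
numerical choices.

Because no real dataset ships with the package, `simulate_population()`
generates phased populations with full-sib litters and a *known* architecture
(exact target variances), so every stage is testable end to end.

## Worked example

Simulate a small backfat-like population (variance proportions: litter 0.053,
additive 0.305, dominance 0.040, imprinting 0.013, residual 0.588) and fit
the full model:

```r
library(imprintgp)

cfg <- sim_config(n_individuals = 600, n_snps = 300, seed = 7)
pop <- simulate_population(cfg)
pop
#> <sim_population> 600 individuals, 300 SNPs, 252 litters
#>   realized variances: additive=0.339, dominance=0.0418, imprinting=0.015,
#>   litter=0.0561, residual=0.663, phenotypic=1.13

design <- design_matrices(pop$genotypes, freqs = pop$freqs)
fit <- fit_genomic_mixture(
  pop$phenotypes, design,
  model_spec("ADI", chain_length = 4000, burn_in = 1000, thinning = 5,
             seed = 1))
fit
#> <genomic_fit> model ADI: 600 individuals, 300 SNPs, 600 saved samples
#>   LPML -832.813; 2/14 variance parameters with time-series SE < 5%

variance_decomposition(fit)
#> Variance decomposition (model ADI)
#> # A tibble: 5 x 5
#>   component  estimate       sd proportion proportion_sd
#> 1 litter     0.0679   0.0419     0.0633        0.0382
#> 2 additive   0.271    0.0708     0.252         0.0567
#> 3 dominance  0.0174   0.0259     0.0162        0.0237
#> 4 imprinting 0.000501 0.000811   0.000478      0.000784
#> 5 residual   0.712    0.0624     0.668         0.0587
#> narrow-sense h2 = 0.252 (sd 0.057); broad-sense H2 = 0.269 (sd 0.062)
```

Reading this: the additive share (narrow-sense heritability) is estimated at
0.25 ± 0.06 against a simulated truth of 0.305; at only 600 individuals and
300 SNPs the small dominance and imprinting components (true shares 0.040 and
0.013) are barely identifiable and the short 4000-iteration chain leaves most
variance parameters above the 5 % time-series-SE mixing criterion — the
printed header says so. The study-scale protocol (50,000 iterations, tens of
thousands of SNPs) is the package default.

`tidy(fit)` gives the variance parameters with time-series SEs, `glance(fit)` a one-row model
summary (including the log pseudo-marginal likelihood used by
`pseudo_bayes_factor()`), and `autoplot()` works on fits, decompositions and
validation reports.

The whole analysis — simulation or file input, quality control, all four
models, Table-style TSV outputs, model comparison, hold-out validation — runs
as one reproducible pipeline:

```r
run_pipeline(list(simulate = list(n_individuals = 300, n_snps = 120),
                  models = c("A", "AD"), chain_length = 800, burn_in = 300,
                  seed = 3),
             out_dir = "run1")
```

or from the shell via `inst/scripts/imprintgp-pipeline.R --config run.yaml
--out run1`. Real data enter as a phased VCF (GT with `|`, paternal allele
first) plus a phenotype TSV (`sample_id`, `y_c`, `litter_id`, `birth_year`,
`birth_date`).

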