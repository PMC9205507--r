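# reidrisk

Re-identification risk estimation for shared microdata, using
copula-synthesized populations.

## The problem

Before a microdata sample (one row per individual) is shared, a data
custodian must show that the risk of matching its records back to real
people is acceptably low. With a set of quasi-identifiers (age band, sex,
region, ...) declared, records sharing identical values form *equivalence
classes*; the class size of record *k* is *f<sub>k</sub>* in the sample
and *F<sub>k</sub>* in the population of size *N*. Two attack match rates
follow:

- **population-to-sample**: A = (1/N) Σ<sub>k=1..n</sub> 1/f<sub>k</sub> —
  computable exactly from the sample and N;
- **sample-to-population**: B = (1/n) Σ<sub>k=1..n</sub> 1/F<sub>k</sub> —
  the quantity a custodian usually must bound, but the F<sub>k</sub> are
  unknown.

`reidrisk` estimates B by *replaying the attack on synthetic data*: it
fits a Gaussian copula and a d-vine copula (empirical-CDF marginals,
mutual-information-matched dependence) to the sample's quasi-identifiers,
synthesizes a population of size N from each, draws a synthetic sample of
size n by simple random sampling, computes B exactly on each synthetic
pair, and averages the two estimates. The package also implements three
literature baselines (entropy/independence, zero-truncated-Poisson
hypothesis test, Benedetti–Franconi Bayesian), a simulation harness that
measures estimator error against generator-known populations, a
sensitivity analysis for a misspecified N, and a JSON risk report with
threshold verdicts (default threshold 0.09).

Audience: statistical disclosure control practitioners, health-data
custodians, and methodologists evaluating risk estimators.

## Worked example

```r
library(reidrisk)

## a generator-known study population: 50,000 people, five hospital-style
## quasi-identifiers with skewed marginals and AR(1) latent dependence
pop <- generateSyntheticPopulation(studyPopulationSpec(N = 50000, seed = 77))

## the custodian's sample: 5,000 records, three QIs declared
idx <- withr::with_seed(4, sample.int(50000, 5000))
smp <- pop[idx, ]
qi  <- c("region", "ageband", "diagnosis")

report <- buildRiskReport(smp, qi, N = 50000,
                          methods = c("average", "entropy"), seed = 42)
print(report)
#> RiskReport: n = 5000, N = 50000, QIs: region, ageband, diagnosis
#>   A (population-to-sample, exact) = 0.043420 [below threshold 0.09]
#>   B_hat (average) = 0.116729 [above threshold 0.09]
#>   B_hat (entropy) = 0.164705 [above threshold 0.09]
```

Because this population is generator-known, the true risk is computable:
`sampleToPopulationRisk()` against the real population's equivalence
classes gives B = 0.1181. The average-copula estimate (0.1167) misses by
about 0.001; the entropy baseline (0.1647) overestimates by 0.047, which
would trigger unnecessary data perturbation. The verdicts say this sample
is *not* shareable at the 0.09 threshold on these three QIs — the
custodian would generalize categories and re-estimate.

How much does an uncertain N matter?

```r
sensitivityToN(smp, qi, 50000, deltas = c(-0.3, 0, 0.3), seed = 42)
#>   delta N_used      value  method
#> 1  -0.3  35000 0.14763204 average
#> 2   0.0  50000 0.11299213 average
#> 3   0.3  65000 0.09524326 average
```

Understating N overestimates risk (conservative); overstating N
underestimates it. If N is uncertain, err low.

The command-line front end wraps the same functions:

```sh
Rscript inst/exec/reidrisk estimate --input sample.csv \
    --qi region,ageband,diagnosis --population-size 50000 \
    --method average --seed 42 --report risk.json
```

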