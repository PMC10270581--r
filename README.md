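# sigcovar

Mutation-level covariate topic models for mutational-signature refitting.

## The problem

Somatic mutation catalogs are conventionally summarized per tumour as counts
over the 96 pyrimidine-centred trinucleotide substitution categories and
*refitted* against a known signature matrix to estimate each tumour's
signature exposures.  That treats a tumour's mutations as exchangeable — but
several mutational processes prefer one replication strand, so each
mutation's lagging/leading annotation carries information that standard
refitting throws away.  `sigcovar` is for analysts who have a **stranded
catalog** (per-sample counts split by a binary mutation-level feature) and a
signature matrix, and who want to (i) refit exposures while using the
covariate, (ii) test whether covariate-aware models actually generalize
better, and (iii) rank signatures by the strength and held-out-likelihood
impact of their strand bias.

## The models

With `I_{t,m}` / `J_{t,m}` the lagging/leading counts of category `m` in
sample `t`, all four models share the topic-model core
`theta ~ Dir(.)`, `z ~ Multi(theta)`, `m ~ Multi(gamma_z)`:

| model | Dirichlet prior(s) | covariate-aware | uses inherent exposures |
|-------|--------------------|-----------------|-------------------------|
| LDA   | `Dir(a)`           | no              | no  |
| MCSM  | `Dir(a)`, `Dir(b)` | yes             | no  |
| gLDA  | `Dir(e_t * a)`     | no              | yes |
| JMCSM | `Dir(e_t * a)`, `Dir(e_t * b)` | yes | yes |

`e_t` is the tumour's inherent exposure vector, estimated strand-agnostically
by a per-sample multinomial mixture model (`mmmFit()`).  Marginalizing the
exposures gives Dirichlet-multinomial likelihoods in `a = exp(a')`,
`b = exp(b')` with a `Normal(0, sigma^2)` prior on the log-scale parameters.
Learning is stochastic EM: collapsed Gibbs sampling of signature assignments
alternating with L-BFGS-B maximization of the marginal likelihood
(`semFit()`).  Models are compared by held-out *empirical likelihood* —
the test-half log-likelihood averaged over exposure draws from the fitted
priors — under per-sample 2-fold cross-validation (`compareModels()`), and
per-signature strand bias is quantified by `logRatioBias()`
(`|log (a_k/sum a)/(b_k/sum b)|`) and by single-signature flattening
contributions to the held-out likelihood (`signatureContributions()`).

## Worked example

Simulate a stranded catalog from JMCSM with known per-signature strand
biases (signature 1 three-fold lagging-biased, signature 3 three-fold
leading-biased), then ask whether the covariate-aware model earns its keep
on held-out data:

```r
library(sigcovar)

sim <- generateCatalog(generatorConfig("JMCSM", T = 40, K = 4, M = 96,
                                       nPerStrand = 300,
                                       a = c(800, 400, 200, 600),
                                       b = c(800, 400, 200, 600) * c(3, 1, 1/3, 1),
                                       seed = 9))
sim$catalog
#> StrandedCatalog: 40 samples x 96 categories; feature 'replication_strand' (lagging/leading)
#>   total counts: 12000 / 12000; dropped (no annotation): 0

compareModels(sim$catalog, sim$sigs, pairs = list(c("JMCSM", "gLDA")),
              config = semConfig("fast", semIters = 30, elDraws = 200),
              seed = 9, folds = 1)
#> EvaluationReport (negative diff_pct: covariate-aware model better)
#>  model fold  el_mean el_mc_se paired_model  diff_pct
#>  JMCSM    1 -40791.9 0.510008         gLDA -0.917718
#>   gLDA    1 -41169.8 0.220664        JMCSM -0.917718
```

JMCSM's held-out empirical log-likelihood beats its strand-oblivious
analogue by about 0.9% (`diff_pct` is negative when the covariate-aware
model is better, matching the usual reporting convention).  The fitted
log-ratio diagnostic then points at the truly biased signatures:

```r
fit <- semFit(sim$catalog, sim$sigs, "JMCSM",
              config = semConfig("fast", semIters = 20), seed = 9)
round(logRatioBias(finalParams(fit)), 3)
#>    S1    S2    S3    S4
#> 1.052 0.071 1.097 0.072
```

Signatures 1 and 3 (the two with a genuine 3-fold bias; `log 3 = 1.1`)
stand far above the unbiased ones.

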