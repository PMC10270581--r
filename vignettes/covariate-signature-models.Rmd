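---
title: "Covariate-aware topic models for mutational signature refitting"
author: "sigcovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-aware topic models for mutational signature refitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mutational processes leave characteristic *signatures*: probability
distributions $\gamma_k$ over the $M = 96$ pyrimidine-centred trinucleotide
substitution categories.  In the *refitting* setting the signature matrix is
known (e.g. a COSMIC subset) and only the per-tumour *exposures* — the
mixing weights over signatures — are inferred.  Standard refitting treats a
tumour's mutations as exchangeable.  But some processes are not uniform
across the genome: several signatures are known to prefer the lagging or
leading replication strand.  `sigcovar` models such *mutation-level
covariates* directly, so that each individual mutation's strand annotation
informs which process generated it, and so that the strand preference of
each signature can itself be estimated and tested.

## The model family

Let $I_{t,m}$ and $J_{t,m}$ be the counts of mutations of category $m$ in
sample $t$ on the two covariate values (lagging / leading), $T$ the number
of samples and $K$ the number of signatures.  All four models share the
topic-model skeleton: an exposure vector is drawn from a Dirichlet prior,
each mutation draws a signature $z$ from it and a category
$m \sim \mathrm{Multi}(\gamma_z)$.

* **LDA** — one shared prior $\theta \sim \mathrm{Dir}(a)$; strand-oblivious.
* **MCSM** — two priors: $\theta^I \sim \mathrm{Dir}(a)$ for lagging
  mutations, $\theta^J \sim \mathrm{Dir}(b)$ for leading ones.  The
  normalized difference between $a$ and $b$ is a signature's strand bias.
* **gLDA** — like LDA but *guided*: each sample's prior is
  $\mathrm{Dir}(e_t \odot a)$, where $e_t$ is the tumour's *inherent
  exposure* vector, a tumour-level covariate estimated strand-agnostically.
* **JMCSM** — both ideas jointly: $\mathrm{Dir}(e_t \odot a)$ and
  $\mathrm{Dir}(e_t \odot b)$.  The inherent exposures tie the two strands
  together, so $a$ and $b$ only encode per-signature strand *modification*
  rather than absolute exposure levels.

Marginalizing the exposures gives a product of Dirichlet-multinomial terms
per sample (the category emissions are handled separately by the sampler):

$$\mathcal{L}(a) = \prod_t \frac{\Gamma(A_t)}{\Gamma(A_t + N_t)}
  \prod_k \frac{\Gamma(\alpha_{t,k} + N_{t,k})}{\Gamma(\alpha_{t,k})}
  \;\cdot\; \prod_k \mathcal{N}(a'_k; 0, \sigma^2),$$

with $\alpha_{t,k} = a_k$ or $e_{t,k} a_k$, $A_t = \sum_k \alpha_{t,k}$ and
$a_k = e^{a'_k}$.  Everything is computed with `lgamma`/`digamma`, so
counts up to $10^7$ and parameters up to $10^5$ stay finite.

## Parameters that matter

* `sigma` (default **10**): scale of the Normal prior on the log-scale
  parameters $a'$, $b'$.  Fitted modification parameters on real catalogs
  are very large (roughly $10^3$–$10^4$, i.e. $a' \approx 7$–$9$), so the
  prior must be weak enough not to shrink them; 10 achieves that while
  still regularizing empty signatures toward $a' = 0$.  The additive
  constant $-\log(\sigma\sqrt{2\pi})$ per parameter is included in reported
  log-likelihoods; it cancels in every comparison at fixed `sigma`, but
  log-likelihoods computed under different `sigma` values are not directly
  comparable.
* `gibbsSweeps` (default **3000** in the `"full"` preset, **50** in
  `"fast"`): full collapsed-Gibbs sweeps per stochastic-EM iteration.  The
  large budget suits real catalogs with $10^5$–$10^6$ mutations; the fast
  preset is appropriate for simulation studies, where the far smaller
  chains mix in tens of sweeps (the package's own recovery tests pass with
  it).
* `semIters` (default **50**): stochastic-EM iterations.  Held-out
  summaries average the trailing 25 iterations of 50; shorter runs average
  the trailing half.  On generated data the held-out likelihood reaches its
  plateau well before iteration 25.
* exposure floor `floorEps = 1e-6`: inherent exposures are floored and
  renormalized on load and after estimation, because $e_{t,k} = 0$ would
  make a Dirichlet parameter zero and the guided likelihoods undefined.
* `S` (`elDraws`): Monte-Carlo draws for the held-out empirical likelihood
  (10,000 for report-quality numbers; a few hundred inside iteration
  traces).

## Learning

`semFit()` alternates:

1. **S-step** — collapsed Gibbs sampling of every mutation's signature
   assignment from $p(z = k \mid m) \propto (n_{t,k}^{\setminus} +
   \alpha_{t,k})\,\gamma_{k,m}$, where $n^{\setminus}$ excludes the token
   being resampled.  The tallies are kept exactly in sync with the token
   assignments (checked by a validity method).  The chain persists across
   SEM iterations; no extra burn-in is used beyond the sweeps themselves,
   since SEM needs one draw per iteration and the final sweep's state is
   that draw.
2. **M-step** — L-BFGS-B maximization of the exact marginal log-likelihood
   of the sampled counts over $a'$ (and $b'$), warm-started at the previous
   iterate, with the analytic digamma gradient (projected-gradient
   tolerance `1e-6`, at most 200 optimizer iterations).  Warm starting
   guarantees the M-step never decreases the current objective.

Initialization: $a' = b' = \log K$ (a symmetric, weakly informative
Dirichlet) and token assignments drawn proportional to
$e_{t,k}\gamma_{k,m}$ ($\gamma$ alone for the unguided models).  Signatures
that receive no sampled counts keep contributing their prior terms and are
never pruned.  For JMCSM and gLDA the inherent exposures are estimated
first with `mmmFit()` — per-sample EM for the multinomial mixture model on
the strand-merged catalog, uniform initialization, relative log-likelihood
tolerance $10^{-8}$ — exactly the covariate-oblivious baseline.

All randomness flows through R's RNG from a single integer seed; fits,
splits and simulations are bit-reproducible.  Multi-stage workflows derive
a separate stream per stage from the master seed, so adding a stage leaves
earlier draws unchanged.

## Evaluation

Since the held-out likelihood of these models is not directly computable,
`empiricalLogLik()` draws $S$ exposure realizations from the fitted
prior(s) and averages the held-out log-likelihood over draws.  The mean of
log-likelihoods (not the log of the mean likelihood) is the reported
quantity; the alternative is available via `logMeanExp = TRUE` for
sensitivity analysis.  For the guided models the draws are per-sample, from
$\mathrm{Dir}(e_t \odot \hat a)$, with the train-half exposure estimates.
`cvSplit()` implements per-sample two-fold cross-validation: each
(sample, strand) cell's tokens are split into halves differing by at most
one token, so train and test reconstitute the input exactly.
`compareModels()` pairs each covariate-aware model with its oblivious
analogue (MCSM vs LDA, JMCSM vs gLDA); the oblivious member is trained and
evaluated on the strand-merged catalog so both see identical mutations.
The reported `diff_pct` is $100(\ell_{\mathrm{obl}} -
\ell_{\mathrm{aware}})/|\ell_{\mathrm{obl}}|$ — negative when the
covariate-aware model generalizes better.

## Strand-bias diagnostics

Two complementary per-signature diagnostics:

* `logRatioBias()` — $|\log\,(a_k/\sum_i a_i) / (b_k/\sum_i b_i)|$, the
  intensity of the bias.  Scale-invariant, but blind to how often the
  signature is actually active.
* `signatureContributions()` — the held-out likelihood gain of letting a
  single signature keep its fitted bias while all others are flattened to
  their mean (sum-preserving), relative to a fully flattened no-bias
  baseline.  Because fitted concentrations are large, a Dirichlet draw sits
  close to its parameters, so flattening neutralizes strand asymmetry while
  the inherent exposures still set each signature's overall activity.  All
  $K + 1$ evaluations share one random-number seed, which removes most
  Monte-Carlo variance from the contrasts and makes a no-op flatten
  contribute exactly zero.  Contributions may legitimately be negative
  (an overfitted bias hurts held-out data); the mean inherent exposure is
  reported alongside because a rare signature can only move the held-out
  likelihood a little.

Two open design points are resolved as follows.  The no-bias baseline
flattens $a$ and $b$ each to its own mean rather than to a common value:
this preserves each strand's total concentration, and the strand asymmetry
that remains (the ratio of the two means) is exactly the catalog-wide
asymmetry that inherent exposures cannot express per signature.  And the
flattening-contribution sign is oriented so that positive means "this
signature's bias helps held-out likelihood".

## The synthetic-data generator

`generateCatalog()` samples from the exact generative processes of the four
models, and is the package's calibration instrument.  Defaults: fixed
mutation numbers per sample per strand (an optional negative-binomial mode
adds over-dispersion); synthetic signatures drawn from a sparse Dirichlet
(concentration 0.1 per category) to mimic the peakedness of real
signatures; inherent exposures from $\mathrm{Dir}(2, \ldots, 2)$ — strictly
positive, moderately variable.  Presets mirror the shapes of the catalogs
the models are aimed at (560, 100 and 100 samples with 12, 6 and 5
signatures, per-sample strand totals in the ratios of the corresponding
stranded catalogs) plus a `tiny` preset for unit tests.

What the generator does *not* emulate: sequencing noise and variant-calling
artefacts, signature misspecification (the refit uses the true $\gamma$),
correlation between mutation burden and exposure profile, and regional
covariates beyond the single binary feature.  Passing recovery tests
therefore demonstrate correctness of the inference machinery under the
model, not robustness to model violation on real catalogs.

## Study sizes used by the test-suite

The package's statistical checks run at sizes chosen to exercise the
estimators well past their noise floor: parameter recovery at $T = 200$
samples with 1000 mutations per sample per strand and $K = 4$ (true
concentrations in the low thousands, matching the magnitude fitted on real
data); bias-rank recovery at $T = 60$ with a single 3-fold biased
signature; model comparison at $T = 40$ with 300 mutations per sample per
strand, 5 independent seeds each.  Likelihood values are validated against
brute-force Monte-Carlo Dirichlet integration on tiny instances
($T \le 3$, $K \le 3$, counts $\le 10$, $10^6$ draws), and the Gibbs
sampler against exhaustive enumeration of all assignment vectors of a
3-mutation instance.

## Numerical choices and edge cases

* Counts are integers; fractional input is rejected, never rounded —
  silent rounding would corrupt likelihoods.
* Catalog categories matching the 96 SBS labels (bracket or
  trinucleotide-pair spelling) are canonicalized into the standard
  substitution-major order; other label sets are accepted as-is for
  reduced-alphabet simulations.
* Mutations whose covariate annotation is missing are dropped at catalog
  construction and counted in `droppedCount()` — before *all* analyses, so
  every model sees the same mutation set.
* Zero-count samples get uniform exposures with a warning; samples whose
  counts sit entirely on categories with zero signature support are an
  error.
* A held-out category with positive count but zero probability under every
  signature makes the empirical likelihood $-\infty$ and is reported as an
  error rather than silently propagated.
* Signature rows are renormalized on load; a row summing to zero is an
  error, as is a requested signature id that is absent.

## Known limitations

* MCSM learns the two priors independently; on covariate-balanced data it
  pays a small held-out penalty relative to LDA for its extra parameters —
  visible in the package's own null-comparison checks and consistent with
  its role as the basic (unguided) covariate model.
* The Dirichlet-multinomial marginal is exchangeable within
  (sample, strand); covariates with more than two values would need one
  prior per value (a mechanical extension, not implemented).
* The empirical likelihood is a Monte-Carlo estimate; comparisons between
  models should always be read against its reported standard error.
* De-novo signature discovery is out of scope: $\gamma$ is always an input.
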