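## Held-out evaluation: per-sample 2-fold catalog splitting, empirical
## likelihood, and paired model comparison.

.stageSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483647)
}

#' Split every sample of a catalog into two halves
#'
#' Per-sample 2-fold cross-validation split: within each (sample, covariate
#' value) cell the mutation tokens are randomly partitioned into two halves
#' whose sizes differ by at most one; the two returned catalogs reconstitute
#' the input exactly, cell by cell.
#'
#' @param cat a \linkS4class{StrandedCatalog}.
#' @param seed integer; equal seeds give identical splits.
#' @return \code{list(train = , test = )} of \linkS4class{StrandedCatalog}.
#' @export
cvSplit <- function(cat, seed = 1L) {
  set.seed(.stageSeed(seed, "cvsplit"))
  halves <- lapply(1:2, function(s) {
    m <- strandCounts(cat, s)                       # T x M
    tr <- m * 0L
    for (t in seq_len(nrow(m))) {
      row <- m[t, ]
      n <- sum(row)
      if (n == 0L) next
      tokens <- rep.int(seq_along(row), row)
      pick <- sample(n, ceiling(n / 2))
      tr[t, ] <- tabulate(tokens[pick], nbins = length(row))
    }
    list(train = tr, test = m - tr)
  })
  mk <- function(which)
    StrandedCatalog(t(halves[[1L]][[which]]), t(halves[[2L]][[which]]),
                    featureName = featureName(cat),
                    featureValueLabels = featureValueLabels(cat),
                    dropped = droppedCount(cat))
  list(train = mk("train"), test = mk("test"))
}

.rdirichlet <- function(S, shape) {
  K <- length(shape)
  x <- matrix(rgamma(S * K, shape = rep(shape, each = S)), S, K)
  rs <- rowSums(x)
  zero <- rs == 0
  if (any(zero)) {
    x[zero, ] <- matrix(shape / sum(shape), sum(zero), K, byrow = TRUE)
    rs[zero] <- 1
  }
  x / rs
}

#' Held-out empirical log-likelihood
#'
#' Monte-Carlo estimate of the held-out log-likelihood of a fitted model:
#' draw S exposure realizations from the model's Dirichlet prior(s) --
#' Dir(a) and Dir(b) for LDA / MCSM, the per-sample Dir(e_t * a) and
#' Dir(e_t * b) for gLDA / JMCSM -- and average the test-set log-likelihood
#' over draws:
#' \deqn{\frac1S \sum_s \sum_{t,m} I_{t,m} \log \sum_k \theta^{(s)}_k
#'   \gamma_{k,m} + J_{t,m} \log \sum_k \phi^{(s)}_k \gamma_{k,m}.}
#' The default is the mean of log-likelihoods over draws (a conservative
#' lower-bound-style summary); \code{logMeanExp = TRUE} instead returns the
#' log of the averaged likelihood for sensitivity analysis.
#'
#' @param params fitted \linkS4class{ModelParams}.
#' @param test held-out \linkS4class{StrandedCatalog}.  For LDA / gLDA its
#'   strands are merged internally.
#' @param sigs a \linkS4class{SignatureMatrix}.
#' @param e \linkS4class{InherentExposures} estimated on the training half
#'   (guided models only).
#' @param S number of exposure draws (default 10000).
#' @param seed optional integer; when given, draws are seeded locally so
#'   repeated calls share random numbers (used for variance-reduced
#'   flattening contrasts).
#' @param logMeanExp average on the likelihood instead of log-likelihood
#'   scale.
#' @return Scalar estimate with attribute \code{"mcse"}, the Monte-Carlo
#'   standard error over draws.  An empty test catalog gives 0.
#' @export
empiricalLogLik <- function(params, test, sigs, e = NULL, S = 10000L,
                            seed = NULL, logMeanExp = FALSE) {
  stopifnot(S >= 1L)
  if (!is.null(seed)) set.seed(.stageSeed(seed, "el"))
  kind <- modelKind(params)
  g <- gammaMatrix(sigs)
  guided <- kind %in% .GUIDED_KINDS
  stranded <- kind %in% .STRANDED_KINDS
  if (!stranded) test <- mergeStrands(test)
  I <- strandCounts(test, 1L)
  J <- strandCounts(test, 2L)
  if (sum(I) + sum(J) == 0) {
    out <- 0
    attr(out, "mcse") <- 0
    return(out)
  }
  dead <- colSums(g) == 0
  if (any((colSums(I) + colSums(J))[dead] > 0))
    stop("held-out counts in categories with zero probability under every ",
         "signature: empirical likelihood is -Inf")
  a <- aParams(params)
  b <- bParams(params)

  perDraw <- numeric(S)
  if (!guided) {
    theta <- .rdirichlet(S, a)
    perDraw <- drop(log(theta %*% g) %*% colSums(I))
    if (stranded) {
      phi <- .rdirichlet(S, b)
      perDraw <- perDraw + drop(log(phi %*% g) %*% colSums(J))
    }
  } else {
    em <- if (is(e, "InherentExposures")) exposureMatrix(e) else as.matrix(e)
    if (is.null(em)) stop("guided models need inherent exposures for EL")
    for (t in seq_len(nrow(I))) {
      it <- I[t, ]; jt <- J[t, ]
      if (sum(it) + sum(jt) == 0) next
      if (sum(it)) {
        theta <- .rdirichlet(S, em[t, ] * a)
        perDraw <- perDraw + drop(log(theta %*% g) %*% it)
      }
      if (stranded && sum(jt)) {
        phi <- .rdirichlet(S, em[t, ] * b)
        perDraw <- perDraw + drop(log(phi %*% g) %*% jt)
      }
    }
  }
  if (logMeanExp) {
    mx <- max(perDraw)
    out <- mx + log(mean(exp(perDraw - mx)))
    attr(out, "mcse") <- stats::sd(exp(perDraw - mx)) /
      (sqrt(S) * mean(exp(perDraw - mx)))
  } else {
    out <- mean(perDraw)
    attr(out, "mcse") <- stats::sd(perDraw) / sqrt(S)
  }
  out
}

#' Cross-validated held-out comparison of covariate-aware vs oblivious models
#'
#' For each cross-validation fold: split every sample's mutations in half
#' (\code{\link{cvSplit}}), estimate inherent exposures on the strand-merged
#' training half by \code{\link{mmmFit}}, fit each model of each pair by
#' \code{\link{semFit}} with the test half as held-out data, and summarize
#' the held-out empirical log-likelihood as its mean over the trailing SEM
#' iterations (the last 25 under the default 50, scaled proportionally for
#' shorter runs).  Covariate-oblivious models are trained and evaluated on
#' the strand-merged catalog so both members of a pair see identical
#' mutations.
#'
#' @param cat a \linkS4class{StrandedCatalog}.
#' @param sigs a \linkS4class{SignatureMatrix}.
#' @param pairs list of length-2 character vectors,
#'   c(covariate-aware, oblivious); default: both canonical pairings.
#' @param config a \code{\link{semConfig}}.
#' @param seed integer master seed; fold splits, exposure estimation and
#'   each fit derive their own stream from it.
#' @param folds 1 or 2 cross-validation folds.
#' @return An \linkS4class{EvaluationReport}.  \code{diff_pct} is
#'   100 (el_oblivious - el_aware) / |el_oblivious|; negative means the
#'   covariate-aware model fits held-out data better.
#' @export
compareModels <- function(cat, sigs,
                          pairs = list(c("MCSM", "LDA"), c("JMCSM", "gLDA")),
                          config = semConfig("fast"), seed = 1L,
                          folds = 2L) {
  stopifnot(folds %in% 1:2)
  split <- cvSplit(cat, seed = seed)
  aggIters <- min(25L, max(1L, config$semIters %/% 2L))
  rows <- list()
  traces <- list()
  for (f in seq_len(folds)) {
    train <- if (f == 1L) split$train else split$test
    test <- if (f == 1L) split$test else split$train
    needGuided <- any(vapply(pairs, function(p)
      any(p %in% .GUIDED_KINDS), logical(1)))
    eTrain <- if (needGuided)
      exposures(mmmFit(mergeStrands(train), sigs)) else NULL
    for (p in pairs) {
      els <- lapply(p, function(kind) {
        fit <- semFit(train, sigs, kind,
                      e = if (kind %in% .GUIDED_KINDS) eTrain else NULL,
                      config = config,
                      seed = .stageSeed(seed, paste0("fit-", kind, "-", f)),
                      heldOut = test)
        tr <- elTrace(fit)
        traces[[paste(kind, f, sep = ".")]] <<- tr
        tail25 <- utils::tail(tr, aggIters)
        list(mean = mean(tail25),
             se = if (length(tail25) > 1L)
               stats::sd(tail25) / sqrt(length(tail25)) else 0)
      })
      ## negative when the covariate-aware member fits held-out data better
      diffPct <- 100 * (els[[2L]]$mean - els[[1L]]$mean) / abs(els[[2L]]$mean)
      for (i in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(
          model = p[i], fold = f, el_mean = els[[i]]$mean,
          el_mc_se = els[[i]]$se, paired_model = p[3L - i],
          diff_pct = diffPct, stringsAsFactors = FALSE)
    }
  }
  new("EvaluationReport", results = do.call(rbind, rows), traces = traces)
}
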