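## Independent oracles used across the suite.  These deliberately avoid the
## package's own likelihood code paths: Monte-Carlo Dirichlet integration
## for the marginal likelihoods, and exhaustive enumeration for the Gibbs
## posterior.

## Monte-Carlo estimate of log integral Dir(theta; alpha) * prod_k theta_k^N_k
## for ONE sample (the Dirichlet-multinomial marginal without the multinomial
## coefficient).  Returns the log estimate and the standard error of the log.
mcMarginalOne <- function(alpha, N, S = 1e6) {
  K <- length(alpha)
  th <- matrix(rgamma(S * K, shape = rep(alpha, each = S)), S, K)
  th <- th / rowSums(th)
  nz <- which(N > 0)
  logw <- if (length(nz)) drop(log(th[, nz, drop = FALSE]) %*% N[nz])
          else numeric(S)
  m <- max(logw)
  w <- exp(logw - m)
  list(value = m + log(mean(w)),
       se = stats::sd(w) / (mean(w) * sqrt(S)))
}

## MC estimate of the DATA term of any of the four models (no prior):
## sum over samples and strands of the per-sample marginal above.
## alphas0 / alphas1: functions t -> Dirichlet parameter vector (alphas1
## NULL for single-prior models).
mcDataTerm <- function(n0, n1 = NULL, alpha0, alpha1 = NULL, S = 1e6) {
  val <- 0
  var <- 0
  for (t in seq_len(nrow(n0))) {
    est <- mcMarginalOne(alpha0(t), n0[t, ], S)
    val <- val + est$value
    var <- var + est$se^2
    if (!is.null(n1)) {
      est1 <- mcMarginalOne(alpha1(t), n1[t, ], S)
      val <- val + est1$value
      var <- var + est1$se^2
    }
  }
  list(value = val, se = sqrt(var))
}

## log Normal(0, sigma^2) prior density summed over a parameter vector
logPriorOracle <- function(plog, sigma) sum(dnorm(plog, 0, sigma, log = TRUE))

## data term of a fitted/constructed ModelParams object via the package,
## with the prior subtracted (so it is comparable to mcDataTerm)
pkgDataTerm <- function(params, n, e = NULL) {
  prior <- logPriorOracle(log(aParams(params)), sigmaPrior(params)) +
    if (!is.null(bParams(params)))
      logPriorOracle(log(bParams(params)), sigmaPrior(params)) else 0
  modelLogLik(params, n, e) - prior
}

## Exhaustive posterior over all K^n assignment vectors of a tiny instance:
## one sample, tokens given by categories `cats` and strands `strands`,
## model parameters alpha (strand 0) and beta (strand 1), emissions g (K x M).
## p(z) is proportional to DM(counts0 | alpha) DM(counts1 | beta) prod_i g[z_i, m_i].
enumeratePosterior <- function(cats, strands, alpha, beta, g) {
  K <- nrow(g)
  n <- length(cats)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  dmLog <- function(par, counts) {
    lgamma(sum(par)) - lgamma(sum(par) + sum(counts)) +
      sum(lgamma(par + counts) - lgamma(par))
  }
  logp <- apply(grid, 1L, function(z) {
    c0 <- tabulate(z[strands == 0L], nbins = K)
    c1 <- tabulate(z[strands == 1L], nbins = K)
    dmLog(alpha, c0) + dmLog(beta, c1) +
      sum(log(g[cbind(z, cats)]))
  })
  p <- exp(logp - max(logp))
  list(grid = grid, prob = p / sum(p))
}

## deterministic tiny stranded catalog used by several files
tinyCatalog <- function() {
  ## categories in rows for the constructor
  c0 <- t(matrix(c(3L, 1L, 0L,
                   2L, 2L, 1L), 2, 3, byrow = TRUE))
  c1 <- t(matrix(c(1L, 0L, 2L,
                   0L, 3L, 1L), 2, 3, byrow = TRUE))
  rownames(c0) <- rownames(c1) <- c("m1", "m2", "m3")
  colnames(c0) <- colnames(c1) <- c("s1", "s2")
  StrandedCatalog(c0, c1)
}

## random small ModelParams + AssignmentCounts instance for gradient and
## oracle tests
randomInstance <- function(kind, T = 2L, K = 2L, maxCount = 10L,
                           sigma = 10) {
  aLog <- rnorm(K, 0, 1)
  bLog <- if (kind %in% c("MCSM", "JMCSM")) rnorm(K, 0, 1) else numeric(0)
  n0 <- matrix(sample(0:maxCount, T * K, replace = TRUE), T, K)
  n1 <- if (kind %in% c("MCSM", "JMCSM"))
    matrix(sample(0:maxCount, T * K, replace = TRUE), T, K)
  else matrix(0L, T, K)
  e <- if (kind %in% c("gLDA", "JMCSM")) {
    m <- matrix(rgamma(T * K, 2) + 0.05, T, K)
    m / rowSums(m)
  } else NULL
  list(params = ModelParams(kind, aLog, bLog, sigma = sigma),
       n = AssignmentCounts(n0, n1), e = e)
}
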