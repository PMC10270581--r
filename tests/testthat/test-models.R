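priorOnly <- function(params) {
  logPriorOracle(log(aParams(params)), sigmaPrior(params)) +
    if (!is.null(bParams(params)))
      logPriorOracle(log(bParams(params)), sigmaPrior(params)) else 0
}

test_that("single-signature data terms telescope to zero", {
  p <- ModelParams("LDA", aLog = log(3.7))
  for (N in c(0L, 1L, 17L))
    expect_equal(logLikLDA(p, AssignmentCounts(matrix(N, 1, 1))),
                 priorOnly(p), tolerance = 1e-12)
})

test_that("all-zero counts leave only the Gaussian prior density", {
  set.seed(21)
  for (kind in c("LDA", "MCSM", "gLDA", "JMCSM")) {
    inst <- randomInstance(kind, T = 3L, K = 3L, maxCount = 0L)
    inst$n <- AssignmentCounts(matrix(0L, 3, 3))
    expect_equal(modelLogLik(inst$params, inst$n, inst$e),
                 priorOnly(inst$params), tolerance = 1e-12)
  }
})

test_that("the Dir(1,1) data term of counts (2,1) is -log 12", {
  p <- ModelParams("LDA", aLog = log(c(1, 1)))
  dataTerm <- logLikLDA(p, AssignmentCounts(matrix(c(2L, 1L), 1))) -
    priorOnly(p)
  expect_equal(dataTerm, -log(12), tolerance = 1e-12)
})

test_that("reduction identities hold exactly", {
  set.seed(22)
  for (rep in 1:5) {
    K <- sample(2:3, 1)
    T <- sample(1:3, 1)
    aLog <- rnorm(K); bLog <- rnorm(K)
    n0 <- matrix(sample(0:10, T * K, TRUE), T, K)
    n1 <- matrix(sample(0:10, T * K, TRUE), T, K)
    n <- AssignmentCounts(n0, n1)
    ones <- matrix(1, T, K)

    jm <- ModelParams("JMCSM", aLog, bLog)
    mc <- ModelParams("MCSM", aLog, bLog)
    expect_equal(logLikJMCSM(jm, ones, n), logLikMCSM(mc, n),
                 tolerance = 1e-10)

    gl <- ModelParams("gLDA", aLog)
    ld <- ModelParams("LDA", aLog)
    nSingle <- AssignmentCounts(n0 + n1)
    expect_equal(logLikGLDA(gl, ones, nSingle), logLikLDA(ld, nSingle),
                 tolerance = 1e-10)

    ## covariate-1 empty: second bracket telescopes to the b-prior alone
    nI <- AssignmentCounts(n0)
    expect_equal(logLikMCSM(mc, nI),
                 logLikLDA(ld, nI) + logPriorOracle(bLog, 10),
                 tolerance = 1e-10)

    ## gLDA is the a-half of JMCSM when the J counts vanish
    e <- matrix(rgamma(T * K, 2) + 0.05, T, K)
    e <- e / rowSums(e)
    expect_equal(logLikJMCSM(jm, e, nI),
                 logLikGLDA(gl, e, nI) + logPriorOracle(bLog, 10),
                 tolerance = 1e-10)
  }
})

test_that("a = b with mirrored counts gives equal strand data terms", {
  aLog <- log(c(2, 5))
  p <- ModelParams("MCSM", aLog, aLog)
  n0 <- matrix(c(4L, 1L), 1)
  sym <- logLikMCSM(p, AssignmentCounts(n0, n0))
  half <- logLikMCSM(p, AssignmentCounts(n0, 0L * n0))
  ## doubling the identical strand doubles the data term
  expect_equal(sym - priorOnly(p), 2 * (half - priorOnly(p)),
               tolerance = 1e-10)
})

test_that("likelihoods are sample-order invariant and signature-equivariant", {
  set.seed(23)
  for (kind in c("LDA", "MCSM", "gLDA", "JMCSM")) {
    inst <- randomInstance(kind, T = 3L, K = 3L)
    n0 <- assignCounts(inst$n, 1L); n1 <- assignCounts(inst$n, 2L)
    base <- modelLogLik(inst$params, inst$n, inst$e)
    ts <- sample(3L)
    nPerm <- AssignmentCounts(n0[ts, ], n1[ts, ])
    ePerm <- if (!is.null(inst$e)) inst$e[ts, ] else NULL
    expect_equal(modelLogLik(inst$params, nPerm, ePerm), base,
                 tolerance = 1e-12)
    ks <- sample(3L)
    pK <- ModelParams(kind, inst$params@aLog[ks],
                      if (length(inst$params@bLog)) inst$params@bLog[ks]
                      else numeric(0))
    nK <- AssignmentCounts(n0[, ks], n1[, ks])
    eK <- if (!is.null(inst$e)) inst$e[, ks] else NULL
    expect_equal(modelLogLik(pK, nK, eK), base, tolerance = 1e-12)
    g <- gradLogLik(pK, nK, eK)
    gBase <- gradLogLik(inst$params, inst$n, inst$e)
    K <- 3L
    expect_equal(unname(g[seq_len(K)]), unname(gBase[ks]), tolerance = 1e-10)
  }
})

test_that("log-domain evaluation stays finite at extreme counts", {
  p <- ModelParams("MCSM", aLog = log(c(1e5, 1)), bLog = log(c(1, 1e5)))
  n <- AssignmentCounts(matrix(c(1e7, 3), 1), matrix(c(0, 1e7), 1))
  v <- logLikMCSM(p, n)
  expect_true(is.finite(v))
  expect_true(all(is.finite(gradLogLik(p, n))))
})

test_that("gradients match central finite differences", {
  set.seed(24)
  h <- 1e-5
  for (rep in 1:8) {
    kind <- sample(c("LDA", "MCSM", "gLDA", "JMCSM"), 1)
    inst <- randomInstance(kind, T = 2L, K = 3L)
    par0 <- c(inst$params@aLog, inst$params@bLog)
    f <- function(par) {
      K <- 3L
      p <- ModelParams(kind, par[seq_len(K)],
                       if (length(par) > K) par[K + seq_len(K)] else numeric(0))
      modelLogLik(p, inst$n, inst$e)
    }
    num <- vapply(seq_along(par0), function(i) {
      ei <- replace(numeric(length(par0)), i, h)
      (f(par0 + ei) - f(par0 - ei)) / (2 * h)
    }, numeric(1))
    ana <- unname(gradLogLik(inst$params, inst$n, inst$e))
    expect_lt(sqrt(sum((num - ana)^2)) / max(sqrt(sum(ana^2)), 1), 1e-4)
  }
})

test_that("zero counts leave only the prior gradient", {
  p <- ModelParams("MCSM", aLog = c(0.3, -0.2), bLog = c(1, 0), sigma = 5)
  g <- gradLogLik(p, AssignmentCounts(matrix(0L, 2, 2)))
  expect_equal(unname(g), c(-c(0.3, -0.2) / 25, -c(1, 0) / 25),
               tolerance = 1e-10)
})

test_that("invalid parameters and exposures are rejected", {
  expect_error(ModelParams("LDA", aLog = c(0, Inf)), "finite")
  expect_error(ModelParams("LDA", aLog = 0, bLog = 0), "absent")
  p <- ModelParams("JMCSM", aLog = c(0, 0), bLog = c(0, 0))
  n <- AssignmentCounts(matrix(1L, 1, 2))
  expect_error(logLikJMCSM(p, matrix(c(1, 0), 1), n), "zero")
})
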