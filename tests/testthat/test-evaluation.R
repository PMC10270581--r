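test_that("cvSplit halves every cell evenly and conserves counts exactly", {
  set.seed(41)
  c0 <- matrix(rpois(96 * 8, 4), 96, 8,
               dimnames = list(canonicalCategories(), paste0("s", 1:8)))
  c1 <- matrix(rpois(96 * 8, 2), 96, 8, dimnames = dimnames(c0))
  storage.mode(c0) <- storage.mode(c1) <- "integer"
  cat <- StrandedCatalog(c0, c1)
  sp <- cvSplit(cat, seed = 3)
  expect_identical(strandCounts(sp$train, 1L) + strandCounts(sp$test, 1L),
                   strandCounts(cat, 1L))
  expect_identical(strandCounts(sp$train, 2L) + strandCounts(sp$test, 2L),
                   strandCounts(cat, 2L))
  ## per-(sample, strand) halves differ by at most one token
  for (s in 1:2) {
    d <- abs(rowSums(strandCounts(sp$train, s)) -
             rowSums(strandCounts(sp$test, s)))
    expect_true(all(d <= 1))
  }
  ## a cell of 4 splits 2/2
  one <- StrandedCatalog(matrix(4L, 1, 1, dimnames = list("m", "s")))
  spOne <- cvSplit(one, seed = 1)
  expect_identical(strandCounts(spOne$train, 1L)[1, 1], 2L)

  sp2 <- cvSplit(cat, seed = 3)
  expect_identical(strandCounts(sp2$train, 1L), strandCounts(sp$train, 1L))
  sp3 <- cvSplit(cat, seed = 4)
  expect_false(identical(strandCounts(sp3$train, 1L),
                         strandCounts(sp$train, 1L)))
})

test_that("K = 1 empirical likelihood equals the multinomial closed form", {
  g <- matrix(c(0.5, 0.3, 0.2), 1, 3, dimnames = list("S1", NULL))
  sigs <- SignatureMatrix(g)
  c0 <- matrix(c(4L, 1L, 0L), 3, 1); c1 <- matrix(c(0L, 2L, 3L), 3, 1)
  cat <- StrandedCatalog(c0, c1)
  closed <- sum((c0 + c1)[, 1] * log(g[1, ]))
  pM <- ModelParams("MCSM", aLog = log(17), bLog = log(0.3))
  for (S in c(1L, 7L, 50L))
    expect_equal(as.numeric(empiricalLogLik(pM, cat, sigs, S = S, seed = 1)),
                 closed, tolerance = 1e-12)
  pL <- ModelParams("LDA", aLog = log(2))
  expect_equal(as.numeric(empiricalLogLik(pL, cat, sigs, S = 3L, seed = 1)),
               closed, tolerance = 1e-12)
})

test_that("an empty held-out catalog has empirical likelihood zero", {
  cat <- StrandedCatalog(matrix(0L, 3, 2))
  sigs <- SignatureMatrix(matrix(rep(1 / 3, 6), 2, 3))
  p <- ModelParams("MCSM", aLog = c(0, 0), bLog = c(0, 0))
  expect_identical(as.numeric(empiricalLogLik(p, cat, sigs, S = 5L, seed = 1)), 0)
})

test_that("huge concentrations reduce the EL to the plug-in log-likelihood", {
  set.seed(42)
  g <- matrix(rgamma(3 * 10, 1), 3, 10)
  g <- g / rowSums(g)
  sigs <- SignatureMatrix(g)
  pSimplex <- c(0.5, 0.3, 0.2)
  a <- 1e8 * pSimplex
  c0 <- matrix(rpois(10 * 2, 2), 2, 10)
  cat <- StrandedCatalog(t(c0))
  p <- ModelParams("LDA", aLog = log(a))
  plugin <- sum(c0 * log(matrix(pSimplex, 1) %*% g)[rep(1, 2), ])
  el <- empiricalLogLik(p, cat, sigs, S = 2000L, seed = 9)
  expect_lt(abs(as.numeric(el) - plugin), 1e-3)
})

test_that("merged LDA and J-empty MCSM agree exactly under shared draws", {
  set.seed(43)
  g <- matrix(rgamma(2 * 8, 0.6), 2, 8)
  sigs <- SignatureMatrix(g / rowSums(g))
  c0 <- matrix(rpois(8 * 3, 3), 8, 3)
  storage.mode(c0) <- "integer"
  catI <- StrandedCatalog(c0)                   # J = 0
  aLog <- c(0.4, -0.3)
  elL <- empiricalLogLik(ModelParams("LDA", aLog), catI, sigs,
                         S = 400L, seed = 5)
  elM <- empiricalLogLik(ModelParams("MCSM", aLog, bLog = aLog), catI, sigs,
                         S = 400L, seed = 5)
  expect_equal(as.numeric(elM), as.numeric(elL), tolerance = 1e-12)
})

test_that("the Monte-Carlo standard error shrinks like 1/sqrt(S)", {
  set.seed(44)
  g <- matrix(rgamma(2 * 8, 0.6), 2, 8)
  sigs <- SignatureMatrix(g / rowSums(g))
  cat <- StrandedCatalog(matrix(rpois(8 * 2, 5L), 8, 2))
  p <- ModelParams("LDA", aLog = c(1, 1))
  se1 <- attr(empiricalLogLik(p, cat, sigs, S = 200L, seed = 1), "mcse")
  se2 <- attr(empiricalLogLik(p, cat, sigs, S = 3200L, seed = 1), "mcse")
  expect_lt(se2, se1)
})

test_that("compareModels reports one row per model, fold and pair", {
  sim <- generateCatalog(generatorConfig("MCSM", T = 6L, K = 2L, M = 10L,
                                         nPerStrand = 60L, a = c(8, 2),
                                         b = c(2, 8), seed = 12))
  rep <- compareModels(sim$catalog, sim$sigs,
                       pairs = list(c("MCSM", "LDA")),
                       config = semConfig("fast", semIters = 4L,
                                          elDraws = 50L),
                       seed = 2, folds = 2L)
  tab <- resultsTable(rep)
  expect_identical(nrow(tab), 4L)              # 1 pair x 2 folds x 2 models
  expect_setequal(tab$model, c("MCSM", "LDA"))
  ## the pair shares one diff_pct per fold, sign convention: negative means
  ## the covariate-aware member fits held-out data better
  for (f in 1:2) {
    sub <- tab[tab$fold == f, ]
    expect_equal(sub$diff_pct[1], sub$diff_pct[2], tolerance = 1e-12)
    mc <- sub[sub$model == "MCSM", ]
    ld <- sub[sub$model == "LDA", ]
    expect_equal(mc$diff_pct, 100 * (ld$el_mean - mc$el_mean) / abs(ld$el_mean),
                 tolerance = 1e-9)
  }
})
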