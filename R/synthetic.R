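## Generative simulation from the four models, for calibration, recovery and
## regression studies.  The samplers follow the models' plate notation
## exactly: per sample draw theta^I ~ Dir(e_t * a) (unit e for the unguided
## models), theta^J ~ Dir(e_t * b) when the model is covariate-aware, then
## per mutation a signature z ~ Multi(theta) and a category m ~
## Multi(gamma_z).

#' Configuration for the generative simulator
#'
#' @param modelKind which generative model to sample from.
#' @param T,K,M samples, signatures, categories.
#' @param nPerStrand mutations per sample per covariate value: a single
#'   number, a length-2 vector (covariate 0 / 1), or a T x 2 matrix.  For
#'   LDA / gLDA only the first column is used and the catalog's second
#'   strand stays empty.
#' @param a,b true modification parameters (natural scale); \code{b} is
#'   ignored for LDA / gLDA.  Defaults: a concentration of 50 spread evenly,
#'   a realistic mid-range between a diffuse prior and the very high fitted
#'   values seen on real catalogs.
#' @param e true inherent exposures (T x K matrix or
#'   \linkS4class{InherentExposures}) for gLDA / JMCSM; if \code{NULL} they
#'   are drawn from Dir(2, ..., 2) -- strictly positive and moderately
#'   variable across samples.
#' @param gamma signature matrix (\linkS4class{SignatureMatrix} or K x M
#'   matrix); if \code{NULL}, rows are drawn from a sparse Dirichlet with
#'   concentration \code{gammaConcentration} to mimic peaked real
#'   signatures.
#' @param gammaConcentration sparsity of synthetic signatures (default 0.1).
#' @param nbSize if non-NULL, per-sample mutation numbers are drawn
#'   NegBin(mu = nPerStrand, size = nbSize) instead of being fixed.
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return A \code{generatorConfig} list.
#' @export
generatorConfig <- function(modelKind = c("JMCSM", "MCSM", "LDA", "gLDA"),
                            T = 10L, K = 2L, M = 96L, nPerStrand = 100L,
                            a = NULL, b = NULL, e = NULL, gamma = NULL,
                            gammaConcentration = 0.1, nbSize = NULL,
                            seed = 1L) {
  modelKind <- match.arg(modelKind)
  if (is.null(a)) a <- rep(50 / K, K)
  if (is.null(b)) b <- a
  stopifnot(all(a > 0), all(b > 0), T >= 0, K >= 1, M >= 1)
  structure(list(modelKind = modelKind, T = as.integer(T), K = as.integer(K),
                 M = as.integer(M), nPerStrand = nPerStrand, a = a, b = b,
                 e = e, gamma = gamma,
                 gammaConcentration = gammaConcentration, nbSize = nbSize,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Preset simulator configurations
#'
#' Shapes mirroring the catalogs the models are typically applied to, at
#' per-sample mutation numbers matching the stranded totals of those
#' catalogs: \code{"brca-like"} (T = 560, K = 12, 559/374 mutations per
#' sample on the lagging/leading strand), \code{"maly-like"} (T = 100,
#' K = 6, 962/684), \code{"clle-like"} (T = 100, K = 5, 133/125) and
#' \code{"tiny"} (T = 5, K = 2, M = 6) for unit tests.
#'
#' @param name preset name.
#' @param modelKind,seed passed through to \code{\link{generatorConfig}}.
#' @return A \code{generatorConfig}.
#' @export
makePreset <- function(name = c("tiny", "brca-like", "maly-like", "clle-like"),
                       modelKind = "JMCSM", seed = 1L) {
  name <- match.arg(name)
  spec <- switch(name,
    "brca-like" = list(T = 560L, K = 12L, M = 96L, n = c(559L, 374L)),
    "maly-like" = list(T = 100L, K = 6L, M = 96L, n = c(962L, 684L)),
    "clle-like" = list(T = 100L, K = 5L, M = 96L, n = c(133L, 125L)),
    "tiny" = list(T = 5L, K = 2L, M = 6L, n = c(20L, 20L)))
  generatorConfig(modelKind = modelKind, T = spec$T, K = spec$K, M = spec$M,
                  nPerStrand = spec$n, seed = seed)
}

.rdirMat <- function(n, shape) {
  if (is.matrix(shape)) {
    x <- matrix(rgamma(length(shape), shape = t(shape)), n, ncol(shape),
                byrow = TRUE)
  } else {
    x <- matrix(rgamma(n * length(shape), shape = rep(shape, each = n)),
                n, length(shape))
  }
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  x / rs
}

#' Sample a synthetic stranded catalog from a generative model
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return A list with elements \code{catalog}
#'   (\linkS4class{StrandedCatalog}), \code{sigs}
#'   (\linkS4class{SignatureMatrix}), \code{truth}: a list holding the true
#'   \code{params} (\linkS4class{ModelParams}), \code{e}
#'   (\linkS4class{InherentExposures} or NULL), \code{assignments}
#'   (\linkS4class{AssignmentCounts} of true per-signature counts), and
#'   \code{theta0}/\code{theta1}, the realized per-sample exposure vectors.
#' @export
#' @examples
#' sim <- generateCatalog(makePreset("tiny", seed = 7))
#' sim$catalog
generateCatalog <- function(cfg) {
  stopifnot(inherits(cfg, "generatorConfig"))
  set.seed(cfg$seed)
  T <- cfg$T; K <- cfg$K; M <- cfg$M
  kind <- cfg$modelKind
  stranded <- kind %in% .STRANDED_KINDS
  guided <- kind %in% .GUIDED_KINDS

  g <- cfg$gamma
  if (is.null(g)) {
    g <- .rdirMat(K, rep(cfg$gammaConcentration, M))
    rownames(g) <- paste0("S", seq_len(K))
    colnames(g) <- if (M == 96L) canonicalCategories()
                   else paste0("cat", seq_len(M))
  } else if (is(g, "SignatureMatrix")) g <- gammaMatrix(g)
  sigs <- SignatureMatrix(g)
  g <- gammaMatrix(sigs)

  em <- NULL
  if (guided) {
    em <- cfg$e
    if (is.null(em)) em <- .rdirMat(T, rep(2, K))
    else if (is(em, "InherentExposures")) em <- exposureMatrix(em)
    colnames(em) <- rownames(g)
    rownames(em) <- paste0("sample", seq_len(T))
  }

  np <- cfg$nPerStrand
  nMat <- if (is.matrix(np)) np
          else if (length(np) == 2L) matrix(rep(as.numeric(np), each = T), T, 2L)
          else matrix(as.numeric(np), T, 2L)
  if (!stranded) nMat[, 2L] <- 0
  if (!is.null(cfg$nbSize))
    nMat[] <- rnbinom(length(nMat), mu = nMat, size = cfg$nbSize)
  storage.mode(nMat) <- "integer"

  counts0 <- matrix(0L, T, M)
  counts1 <- matrix(0L, T, M)
  n0 <- matrix(0L, T, K)
  n1 <- matrix(0L, T, K)
  theta0 <- matrix(NA_real_, T, K)
  theta1 <- if (stranded) matrix(NA_real_, T, K) else NULL

  drawStrand <- function(n, shape) {
    theta <- drop(.rdirMat(1L, shape))
    zc <- if (n > 0) drop(rmultinom(1L, n, theta)) else rep(0L, K)
    catc <- rep(0L, M)
    for (k in which(zc > 0))
      catc <- catc + drop(rmultinom(1L, zc[k], g[k, ]))
    list(theta = theta, z = as.integer(zc), cats = as.integer(catc))
  }

  for (t in seq_len(T)) {
    et <- if (guided) em[t, ] else rep(1, K)
    d0 <- drawStrand(nMat[t, 1L], et * cfg$a)
    theta0[t, ] <- d0$theta
    n0[t, ] <- d0$z
    counts0[t, ] <- d0$cats
    if (stranded) {
      d1 <- drawStrand(nMat[t, 2L], et * cfg$b)
      theta1[t, ] <- d1$theta
      n1[t, ] <- d1$z
      counts1[t, ] <- d1$cats
    }
  }

  sampleNames <- paste0("sample", seq_len(T))
  dimnames(counts0) <- dimnames(counts1) <-
    list(sampleNames, colnames(g))
  dimnames(n0) <- dimnames(n1) <- list(sampleNames, rownames(g))
  params <- ModelParams(kind, log(cfg$a),
                        if (stranded) log(cfg$b) else numeric(0),
                        sigma = 10)
  names(params@aLog) <- rownames(g)
  if (length(params@bLog)) names(params@bLog) <- rownames(g)

  list(catalog = StrandedCatalog(t(counts0), t(counts1)),
       sigs = sigs,
       truth = list(params = params,
                    e = if (guided) InherentExposures(em) else NULL,
                    assignments = AssignmentCounts(n0, n1),
                    theta0 = theta0, theta1 = theta1))
}
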