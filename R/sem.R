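#' Stochastic-EM configuration
#'
#' Bundles the knobs of \code{\link{semFit}}.  The \code{"full"} preset uses
#' 3000 Gibbs sweeps per S-step, which is the budget appropriate for
#' real-catalog analyses; the \code{"fast"} preset (50 sweeps) is suited to
#' simulation studies and tests, where chains over far fewer tokens mix
#' quickly.
#'
#' @param preset \code{"full"} or \code{"fast"}.
#' @param semIters number of SEM iterations (default 50; summaries are
#'   conventionally taken over the last half, see \code{\link{compareModels}}).
#' @param gibbsSweeps full Gibbs sweeps per S-step.
#' @param sigma scale of the Normal(0, sigma^2) prior on a', b'.  The
#'   default 10 is weak enough that fitted concentration parameters in the
#'   thousands (a' around 7-9) are essentially unshrunk.
#' @param pgtol,maxOptIter L-BFGS-B projected-gradient tolerance and
#'   iteration cap for each M-step.
#' @param elDraws Monte-Carlo draws for the per-iteration held-out
#'   empirical likelihood when a held-out catalog is supplied.
#' @return A named list of class \code{"semConfig"}.
#' @export
semConfig <- function(preset = c("full", "fast"), semIters = 50L,
                      gibbsSweeps = NULL, sigma = 10, pgtol = 1e-6,
                      maxOptIter = 200L, elDraws = 1000L) {
  preset <- match.arg(preset)
  if (is.null(gibbsSweeps))
    gibbsSweeps <- if (preset == "full") 3000L else 50L
  structure(list(preset = preset, semIters = as.integer(semIters),
                 gibbsSweeps = as.integer(gibbsSweeps), sigma = sigma,
                 pgtol = pgtol, maxOptIter = as.integer(maxOptIter),
                 elDraws = as.integer(elDraws)),
            class = "semConfig")
}

## M-step: maximize the marginal log-likelihood on the sampled assignment
## counts over a' (and b') by L-BFGS-B, warm-started at the previous iterate.
.mStep <- function(params, counts, e, config) {
  kind <- modelKind(params)
  K <- length(params@aLog)
  twoBlocks <- kind %in% .STRANDED_KINDS
  par0 <- if (twoBlocks) c(params@aLog, params@bLog) else params@aLog
  rebuild <- function(par)
    ModelParams(kind, par[seq_len(K)],
                if (twoBlocks) par[K + seq_len(K)] else numeric(0),
                sigma = params@sigma)
  fn <- function(par) -modelLogLik(rebuild(par), counts, e)
  gr <- function(par) -unname(gradLogLik(rebuild(par), counts, e))
  opt <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = config$maxOptIter,
                              pgtol = config$pgtol))
  if (!is.finite(opt$value)) stop("non-finite objective in M-step")
  if (opt$convergence != 0)
    warning("M-step optimizer did not fully converge (code ",
            opt$convergence, "); iterate retained")
  rebuild(opt$par)
}

#' Fit a covariate topic model by stochastic EM
#'
#' Alternates an S-step -- collapsed-Gibbs resampling of every mutation's
#' signature assignment under the current parameters (see
#' \code{\link{gibbsSweep}}) -- with an M-step that maximizes the exact
#' marginal log-likelihood of the sampled assignment counts over the
#' log-scale Dirichlet parameters by L-BFGS-B with the analytic gradient.
#' For the guided models (gLDA, JMCSM) the inherent exposures are taken as
#' given, or estimated first by \code{\link{mmmFit}} on the strand-merged
#' catalog when absent.  The unguided-prior models trained without the
#' covariate (LDA, gLDA) see the strand-merged catalog, so that every model
#' of a comparison pair is trained on the same mutations.
#'
#' @param cat a \linkS4class{StrandedCatalog}; MCSM / JMCSM require both
#'   covariate values to be populated.
#' @param sigs a \linkS4class{SignatureMatrix}.
#' @param modelKind one of \code{"LDA"}, \code{"MCSM"}, \code{"gLDA"},
#'   \code{"JMCSM"}.
#' @param e optional \linkS4class{InherentExposures} for gLDA / JMCSM.
#' @param config a \code{\link{semConfig}}.
#' @param seed integer seed; the whole fit is bit-reproducible given it.
#' @param heldOut optional \linkS4class{StrandedCatalog}: when supplied,
#'   the held-out empirical log-likelihood (\code{\link{empiricalLogLik}})
#'   of the current parameters is recorded after every SEM iteration.
#' @param verbose log per-iteration objective to \code{message()}.
#' @return An \linkS4class{SEMResult}.
#' @details Initialization: a' = b' = log(K) (a symmetric, weakly
#'   informative Dirichlet), assignments drawn token-wise proportional to
#'   e_tk * gamma_k,m.  Signatures that receive no sampled counts still
#'   contribute their prior terms and are never pruned.
#' @export
semFit <- function(cat, sigs, modelKind = c("JMCSM", "MCSM", "LDA", "gLDA"),
                   e = NULL, config = semConfig(), seed = 1L,
                   heldOut = NULL, verbose = FALSE) {
  modelKind <- match.arg(modelKind)
  stopifnot(is(cat, "StrandedCatalog"), is(sigs, "SignatureMatrix"))
  K <- nrow(gammaMatrix(sigs))
  seed <- as.integer(seed)
  set.seed(seed)

  tot <- sampleTotals(cat)
  if (modelKind %in% .STRANDED_KINDS && sum(tot[, 2L]) == 0L)
    warning("fitting a covariate-aware model (", modelKind,
            ") on a catalog whose second covariate value is empty")
  guided <- modelKind %in% .GUIDED_KINDS
  if (guided && is.null(e))
    e <- exposures(mmmFit(cat, sigs))
  fitCat <- if (modelKind %in% c("LDA", "gLDA")) mergeStrands(cat) else cat

  params <- ModelParams(modelKind, aLog = rep(log(K), K),
                        bLog = if (modelKind %in% .STRANDED_KINDS)
                          rep(log(K), K) else numeric(0),
                        sigma = config$sigma)
  names(params@aLog) <- signatureIds(sigs)
  if (length(params@bLog)) names(params@bLog) <- signatureIds(sigs)

  state <- gibbsInit(fitCat, sigs, e = if (guided) e else NULL)
  trace <- vector("list", config$semIters)
  el <- numeric(0)
  for (it in seq_len(config$semIters)) {
    state <- gibbsSweep(state, params, sigs, e = if (guided) e else NULL,
                        nSweeps = config$gibbsSweeps)
    params <- .mStep(params, state@counts, if (guided) e else NULL, config)
    trace[[it]] <- params
    if (!is.null(heldOut)) {
      elIt <- empiricalLogLik(params, heldOut, sigs,
                              e = if (guided) e else NULL,
                              S = config$elDraws)
      el <- c(el, as.numeric(elIt))
    }
    if (verbose)
      message(sprintf("SEM iter %3d: loglik %.4f%s", it,
                      modelLogLik(params, state@counts,
                                  if (guided) e else NULL),
                      if (!is.null(heldOut))
                        sprintf(", held-out EL %.4f", el[it]) else ""))
  }
  new("SEMResult", modelKind = modelKind, paramsTrace = trace,
      elTrace = el, finalParams = params, seed = seed,
      config = unclass(config))
}
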