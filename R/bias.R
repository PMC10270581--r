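## Per-signature replication-strand bias diagnostics for a fitted
## covariate-aware model: (i) the magnitude of the log-ratio of normalized
## modification parameters, and (ii) the held-out likelihood contribution of
## letting a single signature keep its bias while all others are flattened.

#' Normalized-parameter log-ratio strand bias
#'
#' For a covariate-aware model (MCSM, JMCSM) with strand parameters a and b,
#' returns per signature the magnitude
#' \deqn{\left| \log \frac{a_k / \sum_i a_i}{b_k / \sum_i b_i} \right|,}
#' the intensity of the signature's strand bias.  Invariant to separate
#' rescaling of a and of b; zero when a and b are proportional.
#'
#' @param params a \linkS4class{ModelParams} of kind MCSM or JMCSM.
#' @return Named non-negative numeric vector of length K.
#' @export
#' @examples
#' p <- ModelParams("MCSM", aLog = log(c(0.5, 0.5)), bLog = log(c(0.8, 0.2)))
#' logRatioBias(p)   # |log 0.625|, |log 2.5|
logRatioBias <- function(params) {
  if (!modelKind(params) %in% .STRANDED_KINDS)
    stop("log-ratio bias needs both strand parameter vectors (MCSM or JMCSM)")
  a <- aParams(params)
  b <- bParams(params)
  if (any(a == 0) || any(b == 0)) stop("zero modification parameter")
  abs(log((a / sum(a)) / (b / sum(b))))
}

#' Flatten all but one signature's modification parameters
#'
#' Keeps signature \code{keep} unchanged and replaces every other a_k by the
#' mean of the remaining mass, (sum(a) - a_keep) / (K - 1), and likewise for
#' b; the parameter sums are preserved exactly.  With the high
#' concentrations typical of fitted models, the Dirichlet draws then sit
#' close to their parameters, so only the kept signature retains a strand
#' asymmetry beyond what the inherent exposures dictate.
#'
#' @param params a \linkS4class{ModelParams} with K >= 2.
#' @param keep signature index (or name) whose parameters are retained.
#' @return A \linkS4class{ModelParams} of the same kind.
#' @export
flattenParams <- function(params, keep) {
  a <- aParams(params)
  K <- length(a)
  if (K < 2L) stop("flattening needs at least two signatures")
  if (is.character(keep)) keep <- match(keep, names(a))
  stopifnot(keep %in% seq_len(K))
  flat <- function(v) {
    out <- rep((sum(v) - v[keep]) / (K - 1), K)
    out[keep] <- v[keep]
    names(out) <- names(v)
    out
  }
  ModelParams(modelKind(params), log(flat(a)),
              if (length(params@bLog)) log(flat(bParams(params)))
              else numeric(0),
              sigma = sigmaPrior(params))
}

#' Fully flattened (no-bias) parameters
#'
#' Replaces every a_k by mean(a) and every b_k by mean(b): the sum-preserving
#' baseline in which no signature has any strand-specific modification.
#'
#' @param params a \linkS4class{ModelParams}.
#' @return A \linkS4class{ModelParams} of the same kind.
#' @export
noBiasParams <- function(params) {
  a <- aParams(params)
  flat <- function(v) setNames(rep(mean(v), length(v)), names(v))
  ModelParams(modelKind(params), log(flat(a)),
              if (length(params@bLog)) log(flat(bParams(params)))
              else numeric(0),
              sigma = sigmaPrior(params))
}

#' Per-signature held-out likelihood contribution of strand bias
#'
#' For each signature q, the difference between the held-out empirical
#' log-likelihood when only q keeps its fitted strand bias
#' (\code{\link{flattenParams}}) and when no signature does
#' (\code{\link{noBiasParams}}).  All K + 1 evaluations share the same
#' random-number seed, so a flattening that changes nothing contributes
#' exactly zero and Monte-Carlo variance largely cancels in the contrast.
#' Contributions can be negative: a signature whose fitted bias is
#' overfitted hurts held-out likelihood.  The mean inherent exposure of
#' each signature is reported alongside, because a rare signature can only
#' ever move the held-out likelihood a little.
#'
#' @param params fitted covariate-aware \linkS4class{ModelParams}
#'   (typically JMCSM).
#' @param test held-out \linkS4class{StrandedCatalog}.
#' @param sigs a \linkS4class{SignatureMatrix}.
#' @param e \linkS4class{InherentExposures} (train-half estimates) for
#'   guided models; also the source of the mean-exposure column.
#' @param S Monte-Carlo draws per evaluation.
#' @param seed shared seed for all evaluations.
#' @return data.frame with columns \code{signature}, \code{log_ratio},
#'   \code{contribution}, \code{mean_exposure}.
#' @export
signatureContributions <- function(params, test, sigs, e = NULL,
                                   S = 1000L, seed = 1L) {
  lr <- logRatioBias(params)
  base <- empiricalLogLik(noBiasParams(params), test, sigs, e = e, S = S,
                          seed = seed)
  contrib <- vapply(seq_along(lr), function(q) {
    el <- empiricalLogLik(flattenParams(params, q), test, sigs, e = e,
                          S = S, seed = seed)
    as.numeric(el) - as.numeric(base)
  }, numeric(1))
  meanExp <- if (!is.null(e)) colMeans(exposureMatrix(e)) else
    rep(NA_real_, length(lr))
  data.frame(signature = names(lr), log_ratio = as.numeric(lr),
             contribution = contrib,
             mean_exposure = as.numeric(meanExp),
             stringsAsFactors = FALSE)
}
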