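## Collapsed Gibbs sampling of signature assignments.
##
## The sampler state expands the catalog into mutation tokens (one entry per
## mutation with its sample, category and covariate value) plus the running
## T x K assignment tallies, kept exactly in sync with the tokens.

#' GibbsState: token-level signature assignments
#'
#' @slot sampleIdx,catIdx,strandIdx,z parallel integer vectors over mutation
#'   tokens: 1-based sample index, 1-based category index, covariate value
#'   (0/1) and current 1-based signature assignment.
#' @slot counts the running \linkS4class{AssignmentCounts} tallies, always
#'   equal to the tokenwise tally of \code{z}.
#' @export
setClass("GibbsState",
         representation(sampleIdx = "integer", catIdx = "integer",
                        strandIdx = "integer", z = "integer",
                        counts = "AssignmentCounts"))

setValidity("GibbsState", function(object) {
  if (!all(lengths(list(object@catIdx, object@strandIdx, object@z)) ==
           length(object@sampleIdx)))
    return("token vectors must have equal length")
  tal <- .tallyAssignments(object@sampleIdx, object@strandIdx, object@z,
                           nrow(assignCounts(object@counts, 1L)),
                           ncol(assignCounts(object@counts, 1L)))
  if (!identical(tal$n0, unname(assignCounts(object@counts, 1L))) ||
      !identical(tal$n1, unname(assignCounts(object@counts, 2L))))
    return("assignment tallies out of sync with tokens")
  TRUE
})

setMethod("show", "GibbsState", function(object) {
  cat(sprintf("GibbsState: %d tokens, %d samples, %d signatures\n",
              length(object@z), nrow(assignCounts(object@counts, 1L)),
              ncol(assignCounts(object@counts, 1L))))
})

.tallyAssignments <- function(ti, xi, z, T, K) {
  tally <- function(sel) {
    m <- matrix(0L, T, K)
    if (any(sel)) {
      tab <- table(factor(ti[sel], levels = seq_len(T)),
                   factor(z[sel], levels = seq_len(K)))
      m[] <- as.integer(tab)
    }
    m
  }
  list(n0 = tally(xi == 0L), n1 = tally(xi == 1L))
}

## per-sample Dirichlet parameter matrices for the S-step
.gibbsAlphaBeta <- function(params, e, T) {
  K <- length(params@aLog)
  em <- if (is.null(e)) matrix(1, T, K)
        else if (is(e, "InherentExposures")) exposureMatrix(e)
        else as.matrix(e)
  alpha <- em * matrix(aParams(params), T, K, byrow = TRUE)
  beta <- if (length(params@bLog))
    em * matrix(bParams(params), T, K, byrow = TRUE) else alpha
  list(alpha = alpha, beta = beta)
}

#' Initialize a Gibbs sampler state from a catalog
#'
#' Expands the catalog into mutation tokens and draws an initial assignment
#' for each token with probability proportional to e_tk * gamma_k,m (gamma
#' alone for the unguided models).  Uses R's global RNG; call
#' \code{set.seed()} first for reproducibility.
#'
#' @param cat a \linkS4class{StrandedCatalog}.
#' @param sigs a \linkS4class{SignatureMatrix}.
#' @param e optional \linkS4class{InherentExposures} (guided models).
#' @return A \linkS4class{GibbsState}.
#' @export
gibbsInit <- function(cat, sigs, e = NULL) {
  g <- gammaMatrix(sigs)
  K <- nrow(g)
  I <- strandCounts(cat, 1L)      # T x M
  J <- strandCounts(cat, 2L)
  T <- nrow(I)
  if (ncol(I) != ncol(g))
    stop("catalog and signatures disagree on categories")
  expand <- function(mat, x) {
    nz <- which(mat > 0, arr.ind = TRUE)
    if (!nrow(nz)) return(list(ti = integer(0), mi = integer(0),
                               xi = integer(0)))
    reps <- mat[nz]
    list(ti = rep(nz[, 1L], reps), mi = rep(nz[, 2L], reps),
         xi = rep.int(x, sum(reps)))
  }
  e0 <- expand(I, 0L); e1 <- expand(J, 1L)
  ti <- as.integer(c(e0$ti, e1$ti))
  mi <- as.integer(c(e0$mi, e1$mi))
  xi <- as.integer(c(e0$xi, e1$xi))

  em <- if (is.null(e)) matrix(1, T, K) else exposureMatrix(e)
  z <- integer(length(ti))
  if (length(ti)) {
    w <- em[ti, , drop = FALSE] * t(g)[mi, , drop = FALSE]   # tokens x K
    bad <- rowSums(w) <= 0
    if (any(bad))
      stop("token(s) in categories with zero emission under every signature")
    cum <- w / rowSums(w)
    if (K > 1L) for (k in 2:K) cum[, k] <- cum[, k] + cum[, k - 1L]
    u <- runif(length(ti))
    z <- as.integer(1L + rowSums(cum < u))
  }
  tal <- .tallyAssignments(ti, xi, z, T, K)
  n0 <- tal$n0; n1 <- tal$n1
  dimnames(n0) <- dimnames(n1) <- list(rownames(I), signatureIds(sigs))
  new("GibbsState", sampleIdx = ti, catIdx = mi, strandIdx = xi, z = z,
      counts = AssignmentCounts(n0, n1))
}

#' Collapsed-Gibbs conditional assignment distribution
#'
#' The exact conditional probability over signatures for one mutation token
#' whose own assignment has been removed from the tallies:
#' p(z = k | w = m) proportional to (n_k + alpha_k) * gamma_k,m, where n_k
#' are the remaining same-sample same-covariate assignment counts and
#' alpha_k the sample's Dirichlet parameters (e_tk * a_k, or a_k with unit
#' exposures).
#'
#' @param countsMinus numeric K vector of assignment counts excluding the
#'   current token.
#' @param alpha numeric K vector of Dirichlet parameters for this sample
#'   and covariate value.
#' @param gammaCol numeric K vector gamma[, m] of emission probabilities of
#'   the token's category.
#' @return Normalized K-simplex vector.
#' @export
#' @examples
#' gibbsConditional(c(3, 1), c(1, 1), c(0.5, 0.25))  # (0.8, 0.2)
gibbsConditional <- function(countsMinus, alpha, gammaCol) {
  w <- (countsMinus + alpha) * gammaCol
  tot <- sum(w)
  if (tot <= 0)
    stop("zero emission probability under every signature for this category")
  w / tot
}

#' Run collapsed-Gibbs sweeps over all tokens
#'
#' Each sweep resamples every mutation token once in decrement-sample-
#' increment order from its exact conditional (see
#' \code{\link{gibbsConditional}}).  Tallies stay synchronized with the
#' tokens; runs are bit-identical under equal seeds.
#'
#' @param state a \linkS4class{GibbsState}.
#' @param params a \linkS4class{ModelParams}.
#' @param sigs a \linkS4class{SignatureMatrix}.
#' @param e optional exposures (guided models).
#' @param nSweeps number of full sweeps.
#' @return The updated \linkS4class{GibbsState}.
#' @export
gibbsSweep <- function(state, params, sigs, e = NULL, nSweeps = 1L) {
  if (!length(state@z) || nSweeps < 1L) return(state)
  n0 <- assignCounts(state@counts, 1L)
  ab <- .gibbsAlphaBeta(params, e, nrow(n0))
  res <- gibbs_sweep_cpp(state@sampleIdx, state@catIdx, state@strandIdx,
                         state@z, unname(n0),
                         unname(assignCounts(state@counts, 2L)),
                         ab$alpha, ab$beta, gammaMatrix(sigs),
                         as.integer(nSweeps))
  dimnames(res$n0) <- dimnames(res$n1) <- dimnames(n0)
  new("GibbsState", sampleIdx = state@sampleIdx, catIdx = state@catIdx,
      strandIdx = state@strandIdx, z = res$z,
      counts = AssignmentCounts(res$n0, res$n1))
}
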