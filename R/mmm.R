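#' Multinomial mixture refitting of signature exposures by EM
#'
#' Fits, independently for every sample, the exposure vector theta_t that
#' maximizes the multinomial mixture log-likelihood
#' \deqn{\sum_m c_{t,m} \log \sum_k \theta_{t,k} \gamma_{k,m}}
#' over the K-simplex.  The E-step computes responsibilities
#' r_{t,m,k} proportional to theta_{t,k} gamma_{k,m}; the M-step sets
#' theta_{t,k} proportional to the responsibility-weighted counts.  Used
#' both as the covariate-oblivious baseline and to extract the inherent
#' exposures that guide gLDA and JMCSM (in that case the catalog is
#' strand-merged first).
#'
#' @param counts a \linkS4class{StrandedCatalog} (strands are merged) or a
#'   T x M count matrix with categories in columns.
#' @param sigs a \linkS4class{SignatureMatrix}; categories must match.
#' @param tol convergence tolerance on the relative change of the total
#'   log-likelihood (default 1e-8).
#' @param maxIter maximum EM iterations (default 1000).
#' @param floorEps exposure floor applied to the returned exposures.
#' @return An \linkS4class{MMMFit}.  Zero-count samples get uniform
#'   exposures with a warning.
#' @details Initialization is uniform theta = (1/K, ..., 1/K), which makes
#'   the fit deterministic.  The per-iteration total log-likelihood trace is
#'   non-decreasing (EM monotonicity); all samples are iterated jointly,
#'   which leaves each sample's independent EM path unchanged.
#' @export
#' @examples
#' g <- SignatureMatrix(rbind(c(1, 0), c(0, 1)))
#' f <- mmmFit(matrix(c(30, 70), 1), g)
#' exposureMatrix(exposures(f))   # 0.3 / 0.7
mmmFit <- function(counts, sigs, tol = 1e-8, maxIter = 1000L,
                   floorEps = 1e-6) {
  if (is(counts, "StrandedCatalog"))
    counts <- strandCounts(mergeStrands(counts), 1L)
  counts <- as.matrix(counts)
  g <- gammaMatrix(sigs)
  if (ncol(counts) != ncol(g))
    stop("counts has ", ncol(counts), " categories but signatures have ",
         ncol(g))
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), colnames(g))) {
    idx <- match(colnames(g), colnames(counts))
    if (anyNA(idx)) stop("counts and signature categories do not match")
    counts <- counts[, idx, drop = FALSE]
  }
  T <- nrow(counts); K <- nrow(g)
  support <- colSums(g) > 0
  unexplained <- which(rowSums(counts[, !support, drop = FALSE]) > 0)
  if (length(unexplained))
    stop("sample(s) with counts in categories of zero signature support: ",
         paste(rownames(counts)[unexplained] %||% unexplained, collapse = ", "))
  empty <- rowSums(counts) == 0
  if (any(empty))
    warning(sum(empty), " zero-count sample(s) assigned uniform exposures")

  theta <- matrix(1 / K, T, K)
  total <- rowSums(counts)
  ll <- function(th) {
    mix <- th %*% g
    sum(counts[counts > 0] * log(mix[counts > 0]))
  }
  trace <- ll(theta)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mix <- theta %*% g                       # T x M
    mix[mix == 0] <- 1                       # only where counts are 0
    w <- (counts / mix) %*% t(g)             # T x K
    thetaNew <- theta * w
    rs <- rowSums(thetaNew)
    rs[rs == 0] <- 1
    thetaNew <- thetaNew / rs
    thetaNew[empty, ] <- 1 / K
    theta <- thetaNew
    trace <- c(trace, ll(theta))
    n <- length(trace)
    if (iter >= maxIter ||
        abs(trace[n] - trace[n - 1L]) <= tol * (abs(trace[n - 1L]) + 1e-12))
      break
  }
  e <- theta
  rownames(e) <- rownames(counts) %||% paste0("sample", seq_len(T))
  colnames(e) <- signatureIds(sigs)
  new("MMMFit",
      exposures = InherentExposures(e, floorEps = floorEps),
      loglikTrace = trace, nIter = rep(iter, T))
}
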