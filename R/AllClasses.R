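#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#' @importFrom S4Vectors metadata metadata<- SimpleList
NULL

.checkCountMatrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m))
    return(sprintf("%s must be a numeric matrix", what))
  bad <- which(!is.finite(m) | m < 0 | m != round(m))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    return(sprintf(
      "%s has a negative, non-finite or non-integer entry at row '%s', column '%s'",
      what,
      if (is.null(rownames(m))) rc[1L] else rownames(m)[rc[1L]],
      if (is.null(colnames(m))) rc[2L] else colnames(m)[rc[2L]]))
  }
  NULL
}

## ---------------------------------------------------------------- catalog --

#' StrandedCatalog: per-sample mutation counts split by a binary covariate
#'
#' A \linkS4class{SummarizedExperiment} with two assays, \code{counts0} and
#' \code{counts1}, holding per-sample mutation-category counts for the two
#' values of a mutation-level covariate (by convention the lagging and
#' leading replication strand).  Rows are mutation categories (typically the
#' 96 trinucleotide substitution contexts), columns are samples.
#'
#' @param counts0,counts1 integer matrices, categories x samples, for
#'   covariate values 0 and 1.  \code{counts1 = NULL} yields an all-zero
#'   second strand (a feature-merged catalog).
#' @param featureName name of the mutation-level covariate.
#' @param featureValueLabels length-2 character: labels of covariate values
#'   0 and 1 (value 0 first; lagging before leading by convention).
#' @param dropped number of input mutations dropped for missing covariate
#'   annotation (bookkeeping only).
#' @return A \code{StrandedCatalog} object.
#' @export
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("s1", "s2")))
#' StrandedCatalog(m, m, featureName = "replication_strand")
setClass("StrandedCatalog", contains = "SummarizedExperiment")

setValidity("StrandedCatalog", function(object) {
  an <- assayNames(object)
  if (!all(c("counts0", "counts1") %in% an))
    return("assays must contain 'counts0' and 'counts1'")
  msg <- .checkCountMatrix(assay(object, "counts0"), "counts0")
  if (!is.null(msg)) return(msg)
  msg <- .checkCountMatrix(assay(object, "counts1"), "counts1")
  if (!is.null(msg)) return(msg)
  if (!identical(dim(assay(object, "counts0")), dim(assay(object, "counts1"))))
    return("counts0 and counts1 must have identical dimensions")
  md <- metadata(object)
  if (is.null(md$featureName)) return("metadata featureName missing")
  if (length(md$featureValueLabels) != 2L)
    return("featureValueLabels must have length 2")
  TRUE
})

#' @rdname StrandedCatalog-class
#' @export
StrandedCatalog <- function(counts0, counts1 = NULL,
                            featureName = "replication_strand",
                            featureValueLabels = c("lagging", "leading"),
                            dropped = 0L) {
  counts0 <- as.matrix(counts0)
  if (is.null(counts1)) {
    counts1 <- counts0
    counts1[] <- 0
  }
  counts1 <- as.matrix(counts1)
  if (is.null(rownames(counts0)) && nrow(counts0))
    rownames(counts0) <- paste0("cat", seq_len(nrow(counts0)))
  if (is.null(colnames(counts0)) && ncol(counts0))
    colnames(counts0) <- paste0("sample", seq_len(ncol(counts0)))
  if (nrow(counts0)) {
    ord <- .orderCategories(rownames(counts0))
    counts0 <- counts0[ord$index, , drop = FALSE]
    counts1 <- counts1[ord$index, , drop = FALSE]
    rownames(counts0) <- rownames(counts1) <- ord$labels
    colnames(counts1) <- colnames(counts0)
  }
  storage.mode(counts0) <- "integer"
  storage.mode(counts1) <- "integer"
  se <- SummarizedExperiment(
    assays = SimpleList(counts0 = counts0, counts1 = counts1),
    metadata = list(featureName = featureName,
                    featureValueLabels = as.character(featureValueLabels),
                    dropped = as.integer(dropped)))
  new("StrandedCatalog", se)
}

#' @rdname sigcovar-generics
setMethod("sampleIds", "StrandedCatalog", function(x, ...) colnames(x))

#' @rdname sigcovar-generics
setMethod("categoryLabels", "StrandedCatalog", function(x, ...) rownames(x))

#' @describeIn StrandedCatalog-class counts for one covariate value, samples
#'   in rows (T x M), \code{strand} being 1/2 or a feature-value label.
#' @param x,strand,... see generic.
#' @export
setMethod("strandCounts", "StrandedCatalog", function(x, strand = 1L, ...) {
  if (is.character(strand))
    strand <- match(strand, metadata(x)$featureValueLabels)
  stopifnot(strand %in% 1:2)
  t(assay(x, if (strand == 1L) "counts0" else "counts1"))
})

#' @rdname sigcovar-generics
setMethod("featureName", "StrandedCatalog", function(x, ...) metadata(x)$featureName)

#' @rdname sigcovar-generics
setMethod("featureValueLabels", "StrandedCatalog",
          function(x, ...) metadata(x)$featureValueLabels)

#' @rdname sigcovar-generics
setMethod("droppedCount", "StrandedCatalog", function(x, ...) metadata(x)$dropped)

#' @describeIn StrandedCatalog-class per-sample totals; a T x 2 matrix with
#'   one column per covariate value.
#' @export
setMethod("sampleTotals", "StrandedCatalog", function(x, ...) {
  cbind(colSums(assay(x, "counts0")), colSums(assay(x, "counts1")))
})

#' @describeIn StrandedCatalog-class collapse the covariate: counts0 becomes
#'   the elementwise sum, counts1 all zeros, featureName \code{"merged"}.
#' @export
setMethod("mergeStrands", "StrandedCatalog", function(x, ...) {
  StrandedCatalog(assay(x, "counts0") + assay(x, "counts1"),
                  featureName = "merged",
                  featureValueLabels = c("merged", "unused"),
                  dropped = droppedCount(x))
})

setMethod("show", "StrandedCatalog", function(object) {
  tot <- sampleTotals(object)
  cat(sprintf(
    "StrandedCatalog: %d samples x %d categories; feature '%s' (%s)\n",
    ncol(object), nrow(object), featureName(object),
    paste(featureValueLabels(object), collapse = "/")))
  cat(sprintf("  total counts: %d / %d; dropped (no annotation): %d\n",
              sum(tot[, 1L]), sum(tot[, 2L]), droppedCount(object)))
})

## --------------------------------------------------------------- signatures

#' SignatureMatrix: known signatures as category distributions
#'
#' K mutational signatures as rows of a K x M probability matrix; row k,
#' entry m is the probability that a mutation from signature k falls in
#' category m.  Rows are renormalized to the simplex at construction.
#'
#' @slot gamma K x M matrix, rownames signature ids, colnames categories.
#' @param gamma K x M non-negative matrix; rows are renormalized.
#' @return A \code{SignatureMatrix}.
#' @export
#' @examples
#' SignatureMatrix(matrix(1, 2, 4, dimnames = list(c("S1", "S2"), NULL)))
setClass("SignatureMatrix", representation(gamma = "matrix"))

setValidity("SignatureMatrix", function(object) {
  g <- object@gamma
  if (nrow(g) < 1L) return("need at least one signature")
  if (any(!is.finite(g)) || any(g < 0)) return("gamma must be finite and >= 0")
  if (any(abs(rowSums(g) - 1) > 1e-8))
    return("signature rows must sum to 1 (tolerance 1e-8)")
  TRUE
})

#' @rdname SignatureMatrix-class
#' @export
SignatureMatrix <- function(gamma) {
  gamma <- as.matrix(gamma)
  if (is.null(rownames(gamma)))
    rownames(gamma) <- paste0("S", seq_len(nrow(gamma)))
  if (is.null(colnames(gamma)))
    colnames(gamma) <- paste0("cat", seq_len(ncol(gamma)))
  rs <- rowSums(gamma)
  if (any(rs <= 0))
    stop("signature row(s) sum to zero: ",
         paste(rownames(gamma)[rs <= 0], collapse = ", "))
  new("SignatureMatrix", gamma = gamma / rs)
}

#' @rdname sigcovar-generics
setMethod("signatureIds", "SignatureMatrix", function(x, ...) rownames(x@gamma))

#' @rdname sigcovar-generics
setMethod("gammaMatrix", "SignatureMatrix", function(x, ...) x@gamma)

#' @rdname sigcovar-generics
setMethod("categoryLabels", "SignatureMatrix", function(x, ...) colnames(x@gamma))

setMethod("show", "SignatureMatrix", function(object) {
  cat(sprintf("SignatureMatrix: %d signatures x %d categories\n",
              nrow(object@gamma), ncol(object@gamma)))
  cat("  ", paste(utils::head(signatureIds(object), 12L), collapse = ", "),
      if (nrow(object@gamma) > 12L) ", ..." else "", "\n", sep = "")
})

## ---------------------------------------------------------------- exposures

#' InherentExposures: tumour-level signature exposure vectors
#'
#' Per-sample simplex vectors e_t over the K signatures, used as the
#' tumour-level covariate that modulates the Dirichlet priors of gLDA and
#' JMCSM.  Entries are floored at \code{floorEps} and rows renormalized, so
#' every Dirichlet parameter e_tk * a_k stays strictly positive.
#'
#' @slot e T x K matrix of exposures, rows on the simplex.
#' @param e T x K non-negative matrix; rows renormalized after flooring.
#' @param floorEps exposure floor (default 1e-6).
#' @return An \code{InherentExposures}.
#' @export
setClass("InherentExposures", representation(e = "matrix"))

setValidity("InherentExposures", function(object) {
  e <- object@e
  if (any(!is.finite(e)) || any(e < 0)) return("exposures must be finite, >= 0")
  if (any(abs(rowSums(e) - 1) > 1e-8)) return("exposure rows must sum to 1")
  TRUE
})

#' @rdname InherentExposures-class
#' @export
InherentExposures <- function(e, floorEps = 1e-6) {
  e <- as.matrix(e)
  if (is.null(rownames(e))) rownames(e) <- paste0("sample", seq_len(nrow(e)))
  if (is.null(colnames(e))) colnames(e) <- paste0("S", seq_len(ncol(e)))
  if (any(!is.finite(e)) || any(e < 0))
    stop("exposures must be finite and non-negative")
  rs <- rowSums(e)
  if (any(rs <= 0)) stop("exposure row(s) sum to zero")
  e <- e / rs
  e <- pmax(e, floorEps)
  e <- e / rowSums(e)
  new("InherentExposures", e = e)
}

#' @rdname sigcovar-generics
setMethod("exposureMatrix", "InherentExposures", function(x, ...) x@e)

#' @rdname sigcovar-generics
setMethod("sampleIds", "InherentExposures", function(x, ...) rownames(x@e))

#' @rdname sigcovar-generics
setMethod("signatureIds", "InherentExposures", function(x, ...) colnames(x@e))

setMethod("show", "InherentExposures", function(object) {
  cat(sprintf("InherentExposures: %d samples x %d signatures\n",
              nrow(object@e), ncol(object@e)))
  cat("  mean exposure:",
      paste(sprintf("%s=%.3f", colnames(object@e), colMeans(object@e)),
            collapse = ", "), "\n")
})

## ------------------------------------------------------------- model params

.MODEL_KINDS <- c("LDA", "MCSM", "gLDA", "JMCSM")
.STRANDED_KINDS <- c("MCSM", "JMCSM")
.GUIDED_KINDS <- c("gLDA", "JMCSM")

#' ModelParams: Dirichlet modification parameters on the log scale
#'
#' Holds the per-signature Dirichlet concentration ("modification")
#' parameters of one of the four models, stored as a' = log a (and b' =
#' log b for the covariate-aware models MCSM and JMCSM), together with the
#' scale sigma of the Normal(0, sigma^2) prior on a' and b'.  Working on the
#' log scale keeps a, b strictly positive and makes the M-step optimisation
#' unconstrained.
#'
#' @slot modelKind one of "LDA", "MCSM", "gLDA", "JMCSM".
#' @slot aLog numeric K vector a'.
#' @slot bLog numeric K vector b' (length 0 for LDA / gLDA).
#' @slot sigma positive prior scale.
#' @param modelKind,aLog,bLog,sigma see slots; \code{bLog} must be supplied
#'   exactly for MCSM and JMCSM.
#' @return A \code{ModelParams}.
#' @export
#' @examples
#' ModelParams("MCSM", aLog = log(c(2, 1)), bLog = log(c(1, 2)))
setClass("ModelParams",
         representation(modelKind = "character", aLog = "numeric",
                        bLog = "numeric", sigma = "numeric"))

setValidity("ModelParams", function(object) {
  if (!object@modelKind %in% .MODEL_KINDS)
    return(paste("modelKind must be one of", paste(.MODEL_KINDS, collapse = ", ")))
  if (any(!is.finite(object@aLog))) return("aLog must be finite")
  stranded <- object@modelKind %in% .STRANDED_KINDS
  if (stranded && length(object@bLog) != length(object@aLog))
    return("bLog must match aLog for MCSM/JMCSM")
  if (!stranded && length(object@bLog) != 0L)
    return("bLog must be absent for LDA/gLDA")
  if (length(object@bLog) && any(!is.finite(object@bLog)))
    return("bLog must be finite")
  if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be a single positive number")
  TRUE
})

#' @rdname ModelParams-class
#' @export
ModelParams <- function(modelKind, aLog, bLog = numeric(0), sigma = 10) {
  modelKind <- match.arg(modelKind, .MODEL_KINDS)
  nm <- if (is.null(names(aLog))) paste0("S", seq_along(aLog)) else names(aLog)
  aLog <- setNames(as.numeric(aLog), nm)
  bLog <- if (length(bLog)) setNames(as.numeric(bLog), nm) else numeric(0)
  new("ModelParams", modelKind = modelKind, aLog = aLog, bLog = bLog,
      sigma = sigma)
}

#' @rdname sigcovar-generics
setMethod("modelKind", "ModelParams", function(x, ...) x@modelKind)

#' @describeIn ModelParams-class Dirichlet parameters a = exp(a') on the
#'   natural scale, named by signature.
#' @param x,... see generic.
#' @export
setMethod("aParams", "ModelParams", function(x, ...) exp(x@aLog))

#' @describeIn ModelParams-class b = exp(b'), or NULL for LDA/gLDA.
#' @export
setMethod("bParams", "ModelParams", function(x, ...)
  if (length(x@bLog)) exp(x@bLog) else NULL)

#' @rdname sigcovar-generics
setMethod("sigmaPrior", "ModelParams", function(x, ...) x@sigma)

#' @rdname sigcovar-generics
setMethod("signatureIds", "ModelParams", function(x, ...) names(x@aLog))

setMethod("show", "ModelParams", function(object) {
  cat(sprintf("ModelParams [%s], K = %d, sigma = %g\n",
              object@modelKind, length(object@aLog), object@sigma))
  cat("  a:", paste(sprintf("%.3g", exp(object@aLog)), collapse = " "), "\n")
  if (length(object@bLog))
    cat("  b:", paste(sprintf("%.3g", exp(object@bLog)), collapse = " "), "\n")
})

## -------------------------------------------------------- assignment counts

#' AssignmentCounts: signature-assignment tallies per sample and strand
#'
#' T x K integer matrices of how many mutations in each sample are currently
#' assigned to each signature, split by covariate value: \code{n0} holds
#' I_tk (covariate 0), \code{n1} holds J_tk.  For the single-prior models
#' (LDA, gLDA) \code{n1} is all zeros and \code{n0} carries N_tk.
#'
#' @slot n0,n1 T x K integer matrices.
#' @param n0,n1 matrices; \code{n1 = NULL} gives all zeros.
#' @return An \code{AssignmentCounts}.
#' @export
setClass("AssignmentCounts", representation(n0 = "matrix", n1 = "matrix"))

setValidity("AssignmentCounts", function(object) {
  msg <- .checkCountMatrix(object@n0, "n0")
  if (!is.null(msg)) return(msg)
  msg <- .checkCountMatrix(object@n1, "n1")
  if (!is.null(msg)) return(msg)
  if (!identical(dim(object@n0), dim(object@n1)))
    return("n0 and n1 must have identical dimensions")
  TRUE
})

#' @rdname AssignmentCounts-class
#' @export
AssignmentCounts <- function(n0, n1 = NULL) {
  n0 <- as.matrix(n0)
  if (is.null(n1)) {
    n1 <- n0
    n1[] <- 0
  }
  n1 <- as.matrix(n1)
  storage.mode(n0) <- "integer"
  storage.mode(n1) <- "integer"
  dimnames(n1) <- dimnames(n0)
  new("AssignmentCounts", n0 = n0, n1 = n1)
}

#' @describeIn AssignmentCounts-class tally matrix for one covariate value
#'   (\code{strand} 1 or 2).
#' @param x,strand,... see generic.
#' @export
setMethod("assignCounts", "AssignmentCounts", function(x, strand = 1L, ...) {
  stopifnot(strand %in% 1:2)
  if (strand == 1L) x@n0 else x@n1
})

setMethod("show", "AssignmentCounts", function(object) {
  cat(sprintf("AssignmentCounts: %d samples x %d signatures (totals %d / %d)\n",
              nrow(object@n0), ncol(object@n0), sum(object@n0), sum(object@n1)))
})

## ------------------------------------------------------------------ results

#' MMMFit: multinomial-mixture refitting result
#'
#' @slot exposures fitted \linkS4class{InherentExposures}.
#' @slot loglikTrace per-EM-iteration total observed-data log-likelihood
#'   (non-decreasing).
#' @slot nIter iterations run per sample.
#' @export
setClass("MMMFit",
         representation(exposures = "InherentExposures",
                        loglikTrace = "numeric", nIter = "integer"))

#' @rdname sigcovar-generics
setMethod("exposures", "MMMFit", function(x, ...) x@exposures)

#' @rdname sigcovar-generics
setMethod("loglikTrace", "MMMFit", function(x, ...) x@loglikTrace)

setMethod("show", "MMMFit", function(object) {
  cat(sprintf("MMMFit: %d samples, %d EM iterations, final loglik %.4f\n",
              nrow(exposureMatrix(object@exposures)),
              length(object@loglikTrace),
              object@loglikTrace[length(object@loglikTrace)]))
})

#' SEMResult: stochastic-EM fit of one model
#'
#' @slot modelKind fitted model.
#' @slot paramsTrace list of \linkS4class{ModelParams}, one per SEM iteration.
#' @slot elTrace held-out empirical log-likelihood per SEM iteration (length
#'   0 when no held-out catalog was supplied).
#' @slot finalParams parameters after the last iteration.
#' @slot seed integer seed the fit was run under.
#' @slot config the configuration list used (see \code{\link{semConfig}}).
#' @export
setClass("SEMResult",
         representation(modelKind = "character", paramsTrace = "list",
                        elTrace = "numeric", finalParams = "ModelParams",
                        seed = "integer", config = "list"))

#' @rdname sigcovar-generics
setMethod("modelKind", "SEMResult", function(x, ...) x@modelKind)

#' @rdname sigcovar-generics
setMethod("paramsTrace", "SEMResult", function(x, ...) x@paramsTrace)

#' @rdname sigcovar-generics
setMethod("elTrace", "SEMResult", function(x, ...) x@elTrace)

#' @rdname sigcovar-generics
setMethod("finalParams", "SEMResult", function(x, ...) x@finalParams)

setMethod("show", "SEMResult", function(object) {
  cat(sprintf("SEMResult [%s]: %d SEM iterations (seed %d)\n",
              object@modelKind, length(object@paramsTrace), object@seed))
  show(object@finalParams)
  if (length(object@elTrace))
    cat(sprintf("  final held-out EL: %.4f\n",
                object@elTrace[length(object@elTrace)]))
})

#' EvaluationReport: held-out model comparison
#'
#' @slot results data.frame with one row per (model, fold): columns
#'   \code{model}, \code{fold}, \code{el_mean}, \code{el_mc_se},
#'   \code{paired_model}, \code{diff_pct}.  \code{diff_pct} is
#'   100 * (el_oblivious - el_sensitive) / |el_oblivious| and is negative
#'   when the covariate-aware model of the pair is better.
#' @slot traces per-(model, fold) EL traces over SEM iterations.
#' @export
setClass("EvaluationReport",
         representation(results = "data.frame", traces = "list"))

#' @rdname sigcovar-generics
setMethod("resultsTable", "EvaluationReport", function(x, ...) x@results)

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (negative diff_pct: covariate-aware model better)\n")
  print(object@results, row.names = FALSE, digits = 6)
})
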