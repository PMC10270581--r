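## Readers and writers for stranded catalogs, signature matrices, exposures
## and model-parameter tables.  All formats are plain TSV.
##
## Wide catalog: a "#feature_name=<name>" header line, then one block per
## covariate value introduced by "#feature=<label>", each block being a
## header row (sample + category labels) and one row per sample.
##
## Long catalog: columns sample, category, feature, count.  Rows whose
## feature is not one of the two declared labels are dropped and counted.

#' Read a stranded mutation catalog
#'
#' @param path TSV file.
#' @param format \code{"auto"} (default; sniffs the header), \code{"wide"}
#'   or \code{"long"}.
#' @param featureValueLabels length-2 character giving the two covariate
#'   values (value 0 first).  For long input, \code{NULL} means: use
#'   \code{c("lagging", "leading")} if present, else the first two distinct
#'   feature values in file order.  Rows with any other feature value are
#'   dropped and tallied in \code{\link{droppedCount}}.
#' @param strict error on an empty catalog (header only).
#' @return A \linkS4class{StrandedCatalog}.
#' @seealso \code{\link{writeCatalog}}
#' @export
readCatalog <- function(path, format = c("auto", "wide", "long"),
                        featureValueLabels = NULL, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "auto") {
    first <- lines[!grepl("^\\s*$", lines)][1L]
    format <- if (is.na(first)) "long"
      else if (startsWith(first, "#")) "wide"
      else {
        hdr <- strsplit(first, "\t", fixed = TRUE)[[1]]
        if (identical(tolower(hdr[seq_len(min(4, length(hdr)))]),
                      c("sample", "category", "feature", "count")[seq_len(min(4, length(hdr)))]))
          "long" else "wide"
      }
  }
  cat <- if (format == "wide") .readWide(lines, featureValueLabels)
         else .readLong(lines, featureValueLabels)
  if (strict && ncol(cat) == 0L)
    stop("catalog is empty (no samples) and strict = TRUE")
  cat
}

.parseCount <- function(x, where) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | !is.finite(v) | v < 0 | v != round(v))
  if (length(bad))
    stop(sprintf("negative or non-integer count '%s' at %s %s",
                 x[bad[1L]], where, bad[1L]))
  as.integer(v)
}

.readWide <- function(lines, featureValueLabels) {
  featName <- "replication_strand"
  m <- regmatches(lines, regexec("^#feature_name=(.*)$", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) featName <- m[[hit[1L]]][2L]

  blockStart <- grep("^#feature=", lines)
  if (!length(blockStart)) stop("wide catalog: no '#feature=' block found")
  labels <- sub("^#feature=", "", lines[blockStart])
  blockEnd <- c(blockStart[-1L] - 1L, length(lines))

  readBlock <- function(from, to) {
    body <- lines[(from + 1L):to]
    body <- body[!grepl("^#", body) & !grepl("^\\s*$", body)]
    if (!length(body)) stop("wide catalog: empty block")
    hdr <- strsplit(body[1L], "\t", fixed = TRUE)[[1]]
    cats <- hdr[-1L]
    rows <- body[-1L]
    if (!length(rows))
      return(matrix(0L, 0L, length(cats), dimnames = list(NULL, cats)))
    cells <- strsplit(rows, "\t", fixed = TRUE)
    ids <- vapply(cells, `[`, "", 1L)
    mat <- matrix(0L, length(rows), length(cats), dimnames = list(ids, cats))
    for (i in seq_along(cells)) {
      if (length(cells[[i]]) != length(cats) + 1L)
        stop("wide catalog: row for sample '", ids[i], "' has wrong width")
      mat[i, ] <- .parseCount(cells[[i]][-1L], paste0("sample ", ids[i], ", column"))
    }
    mat
  }

  blocks <- Map(readBlock, blockStart, blockEnd)
  names(blocks) <- labels
  if (is.null(featureValueLabels)) featureValueLabels <- labels[1:2]
  if (length(blocks) == 1L)
    blocks[[2L]] <- blocks[[1L]] * 0L
  b0 <- blocks[[featureValueLabels[1L]]]
  b1 <- blocks[[featureValueLabels[2L]]]
  if (is.null(b0) || is.null(b1))
    stop("wide catalog: feature blocks ",
         paste(featureValueLabels, collapse = "/"), " not both present")
  if (!identical(dimnames(b0), dimnames(b1)))
    stop("wide catalog: blocks disagree on samples or categories")
  StrandedCatalog(t(b0), t(b1), featureName = featName,
                  featureValueLabels = featureValueLabels)
}

.readLong <- function(lines, featureValueLabels) {
  lines <- lines[!grepl("^#", lines) & !grepl("^\\s*$", lines)]
  if (!length(lines)) stop("long catalog: no header row")
  hdr <- tolower(strsplit(lines[1L], "\t", fixed = TRUE)[[1]])
  need <- c("sample", "category", "feature", "count")
  if (!all(need %in% hdr))
    stop("long catalog: header must contain ", paste(need, collapse = ", "))
  col <- match(need, hdr)
  rows <- lines[-1L]
  if (!length(rows))
    return(StrandedCatalog(matrix(0L, 0L, 0L),
                           featureValueLabels = featureValueLabels %||%
                             c("lagging", "leading")))
  cells <- strsplit(rows, "\t", fixed = TRUE)
  getcol <- function(j) vapply(cells, `[`, "", col[j])
  sample <- getcol(1L); category <- getcol(2L); feature <- getcol(3L)
  count <- .parseCount(getcol(4L), "long-catalog row")

  if (is.null(featureValueLabels)) {
    uf <- unique(feature)
    featureValueLabels <- if (all(c("lagging", "leading") %in% uf))
      c("lagging", "leading") else utils::head(uf, 2L)
    if (length(featureValueLabels) < 2L)
      featureValueLabels <- c(featureValueLabels, "leading")[1:2]
  }
  keep <- feature %in% featureValueLabels
  dropped <- sum(count[!keep])
  sample <- sample[keep]; category <- category[keep]
  feature <- feature[keep]; count <- count[keep]

  sampleIds <- unique(sample)
  cats <- unique(category)
  n0 <- n1 <- matrix(0L, length(cats), length(sampleIds),
                     dimnames = list(cats, sampleIds))
  i <- cbind(match(category, cats), match(sample, sampleIds))
  is0 <- feature == featureValueLabels[1L]
  ## duplicate (sample, category, feature) rows accumulate
  for (r in which(is0)) n0[i[r, 1L], i[r, 2L]] <- n0[i[r, 1L], i[r, 2L]] + count[r]
  for (r in which(!is0)) n1[i[r, 1L], i[r, 2L]] <- n1[i[r, 1L], i[r, 2L]] + count[r]
  StrandedCatalog(n0, n1, featureValueLabels = featureValueLabels,
                  dropped = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a stranded catalog to TSV
#'
#' @param cat a \linkS4class{StrandedCatalog}.
#' @param path output file.
#' @param format \code{"wide"} (default) or \code{"long"}.
#' @return \code{path}, invisibly.  \code{readCatalog(writeCatalog(x))}
#'   reproduces the counts bit-exactly, order preserved.
#' @export
writeCatalog <- function(cat, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(is(cat, "StrandedCatalog"))
  fv <- featureValueLabels(cat)
  if (format == "wide") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#feature_name=", featureName(cat)), con)
    for (s in 1:2) {
      writeLines(paste0("#feature=", fv[s]), con)
      m <- strandCounts(cat, s)  # T x M
      writeLines(paste(c("sample", colnames(m)), collapse = "\t"), con)
      for (i in seq_len(nrow(m)))
        writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
    }
  } else {
    recs <- c("sample\tcategory\tfeature\tcount")
    for (s in 1:2) {
      m <- strandCounts(cat, s)
      nz <- which(m > 0, arr.ind = TRUE)
      nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]  # sample-major
      if (nrow(nz))
        recs <- c(recs, paste(rownames(m)[nz[, 1L]], colnames(m)[nz[, 2L]],
                              fv[s], m[nz], sep = "\t"))
    }
    writeLines(recs, path)
  }
  invisible(path)
}

#' Read a signature matrix (COSMIC v2 style TSV)
#'
#' Auto-detects orientation: either the 96 contexts are in rows (any column
#' whose values canonicalize to the 96 labels is used as the category
#' column, remaining numeric columns are signatures -- the published v2
#' layout) or contexts are in the header and signatures in rows.
#'
#' @param path TSV file.
#' @param subset optional signature selection, either exact column names or
#'   integers matched against the number embedded in each signature name
#'   (so \code{subset = c(1, 5)} picks "Signature 1" and "Signature 5").
#'   The result is in request order.
#' @return A \linkS4class{SignatureMatrix} with rows renormalized to the
#'   simplex.
#' @export
readSignatures <- function(path, subset = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  canonCol <- which(vapply(df, function(col)
    all(!is.na(canonicalizeCategory(as.character(col)))), logical(1)))
  if (length(canonCol)) {
    cats <- canonicalizeCategory(as.character(df[[canonCol[1L]]]))
    num <- vapply(df, is.numeric, logical(1))
    num[canonCol] <- FALSE
    g <- t(as.matrix(df[, num, drop = FALSE]))
    colnames(g) <- cats
  } else {
    hdrCanon <- canonicalizeCategory(colnames(df)[-1L])
    numRest <- all(vapply(df[-1L], is.numeric, logical(1)))
    if (all(!is.na(hdrCanon)) || (numRest && !is.numeric(df[[1L]]))) {
      ## signatures in rows; header either the 96 contexts or generic labels
      g <- as.matrix(df[, -1L, drop = FALSE])
      rownames(g) <- as.character(df[[1L]])
      if (all(!is.na(hdrCanon))) colnames(g) <- hdrCanon
    } else {
      stop("could not identify the category layout of ", path)
    }
  }
  ord <- .orderCategories(colnames(g))
  g <- g[, ord$index, drop = FALSE]
  colnames(g) <- ord$labels
  if (!is.null(subset)) {
    idx <- if (is.numeric(subset)) {
      nums <- suppressWarnings(as.integer(gsub("[^0-9]", "", rownames(g))))
      match(as.integer(subset), nums)
    } else match(subset, rownames(g))
    if (anyNA(idx))
      stop("requested signature(s) absent: ",
           paste(subset[is.na(idx)], collapse = ", "))
    g <- g[idx, , drop = FALSE]
  }
  SignatureMatrix(g)
}

#' Write a signature matrix as TSV (signatures in rows)
#' @param sigs a \linkS4class{SignatureMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSignatures <- function(sigs, path) {
  g <- gammaMatrix(sigs)
  df <- data.frame(signature = rownames(g), g, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write inherent exposure tables
#'
#' Sample-by-signature TSV with a leading \code{sample} column; rows are
#' floored at \code{floorEps} and renormalized to the simplex on load.
#'
#' @param path TSV file.
#' @param floorEps exposure floor applied on load.
#' @return \code{readExposures}: an \linkS4class{InherentExposures}.
#' @export
readExposures <- function(path, floorEps = 1e-6) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  e <- as.matrix(df[, -1L, drop = FALSE])
  rownames(e) <- as.character(df[[1L]])
  InherentExposures(e, floorEps = floorEps)
}

#' @rdname readExposures
#' @param exp an \linkS4class{InherentExposures}.
#' @export
writeExposures <- function(exp, path) {
  e <- exposureMatrix(exp)
  df <- data.frame(sample = rownames(e), e, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write model parameter tables
#'
#' TSV with columns \code{signature}, \code{a}, optionally \code{b}, and a
#' \code{sigma} column (constant); the model kind is stored in a header
#' comment line \code{#model=<kind>}.
#'
#' @param path TSV file.
#' @return \code{readParams}: a \linkS4class{ModelParams}.
#' @export
readParams <- function(path) {
  lines <- readLines(path)
  kindLine <- grep("^#model=", lines, value = TRUE)
  kind <- if (length(kindLine)) sub("^#model=", "", kindLine[1L]) else "MCSM"
  df <- read.delim(textConnection(lines[!startsWith(lines, "#")]),
                   stringsAsFactors = FALSE)
  aLog <- setNames(log(df$a), df$signature)
  bLog <- if ("b" %in% names(df) && !all(is.na(df$b))) log(df$b) else numeric(0)
  ModelParams(kind, aLog, bLog, sigma = df$sigma[1L])
}

#' @rdname readParams
#' @param params a \linkS4class{ModelParams}.
#' @export
writeParams <- function(params, path) {
  a <- aParams(params)
  b <- bParams(params)
  df <- data.frame(signature = names(a), a = as.numeric(a))
  if (!is.null(b)) df$b <- as.numeric(b)
  df$sigma <- sigmaPrior(params)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#model=", modelKind(params)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
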