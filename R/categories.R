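## Canonical SBS96 category handling.
##
## Order is substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank,
## then 3' flank, each A/C/G/T -- the order used by published signature
## matrices, so loaded catalogs and signature files line up by index.

.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")

#' Canonical SBS96 category labels
#'
#' The 96 pyrimidine-centred single-base-substitution categories in canonical
#' order: substitution (C>A, C>G, C>T, T>A, T>C, T>G) varying slowest, then
#' the 5' flanking base, then the 3' flanking base.
#'
#' @return Character vector of length 96, e.g. \code{"A[C>A]A"}.
#' @export
#' @examples
#' head(canonicalCategories())
canonicalCategories <- function() {
  labs <- character(96L)
  i <- 1L
  for (s in .SUBS) for (f5 in .BASES) for (f3 in .BASES) {
    labs[i] <- paste0(f5, "[", s, "]", f3)
    i <- i + 1L
  }
  labs
}

#' Canonicalize SBS category spellings
#'
#' Maps accepted spellings of the 96 trinucleotide-substitution labels to the
#' canonical bracket form.  Accepted inputs: \code{"A[C>A]A"} (any case) and
#' the trinucleotide-pair form \code{"ACA>AAA"} (flanks must agree, middle
#' base pyrimidine).  Labels that match neither pattern are returned as
#' \code{NA}.
#'
#' @param x character vector of category labels.
#' @return Character vector of canonical labels, \code{NA} where not
#'   recognised.
#' @export
#' @examples
#' canonicalizeCategory(c("a[c>a]a", "ACA>AAA", "not-a-context"))
canonicalizeCategory <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))

  bracket <- grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", x)
  out[bracket] <- x[bracket]

  trip <- grepl("^[ACGT]{3}>[ACGT]{3}$", x) & !bracket
  if (any(trip)) {
    ref <- substr(x[trip], 1L, 3L)
    alt <- substr(x[trip], 5L, 7L)
    ok <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &
      substr(ref, 3L, 3L) == substr(alt, 3L, 3L) &
      substr(ref, 2L, 2L) %in% c("C", "T") &
      substr(ref, 2L, 2L) != substr(alt, 2L, 2L)
    lab <- paste0(
      substr(ref, 1L, 1L), "[", substr(ref, 2L, 2L), ">",
      substr(alt, 2L, 2L), "]", substr(ref, 3L, 3L)
    )
    out[trip][ok] <- lab[ok]
  }

  out[!out %in% canonicalCategories()] <- NA_character_
  out
}

## Order arbitrary labels: if every label is an SBS96 spelling, put them in
## canonical order; if some but not all are, that is almost certainly a typo
## and is rejected; otherwise the labels are kept in the order given.
.orderCategories <- function(labels) {
  canon <- canonicalizeCategory(labels)
  if (all(!is.na(canon))) {
    if (anyDuplicated(canon))
      stop("duplicate mutation categories after canonicalization: ",
           paste(unique(canon[duplicated(canon)]), collapse = ", "))
    idx <- order(match(canon, canonicalCategories()))
    list(labels = canon[idx], index = idx)
  } else if (any(!is.na(canon))) {
    bad <- labels[is.na(canon)]
    stop("unknown mutation category label(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  } else {
    if (anyDuplicated(labels))
      stop("duplicate category labels: ",
           paste(unique(labels[duplicated(labels)]), collapse = ", "))
    list(labels = labels, index = seq_along(labels))
  }
}
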