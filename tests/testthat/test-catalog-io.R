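test_that("canonical category order and spellings map bijectively", {
  cc <- canonicalCategories()
  expect_length(cc, 96L)
  expect_identical(anyDuplicated(cc), 0L)
  expect_identical(cc[1L], "A[C>A]A")
  ## substitution-major order: first 16 labels all C>A
  expect_true(all(grepl("C>A", cc[1:16], fixed = TRUE)))
  ## both accepted spellings hit the same index
  trip <- paste0(substr(cc, 1, 1), substr(cc, 3, 3), substr(cc, 7, 7), ">",
                 substr(cc, 1, 1), substr(cc, 5, 5), substr(cc, 7, 7))
  expect_identical(canonicalizeCategory(trip), cc)
  expect_identical(canonicalizeCategory(tolower(cc)), cc)
  expect_true(is.na(canonicalizeCategory("A[G>A]A")))  # purine-centred
})

test_that("long TSV is transcribed directly and unknown strands are dropped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tcategory\tfeature\tcount",
               "s1\tA[C>A]A\tlagging\t3",
               "s1\tA[C>A]A\tleading\t1",
               "s2\tA[C>A]C\tlagging\t2",
               "s1\tA[C>A]A\tunknown\t5"), f)
  cat <- readCatalog(f)
  expect_identical(strandCounts(cat, "lagging")["s1", "A[C>A]A"], 3L)
  expect_identical(strandCounts(cat, "leading")["s1", "A[C>A]A"], 1L)
  expect_identical(strandCounts(cat, 1L)["s2", "A[C>A]C"], 2L)
  expect_identical(droppedCount(cat), 5L)
})

test_that("header-only long file gives an empty catalog unless strict", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tcategory\tfeature\tcount", f)
  cat <- readCatalog(f)
  expect_identical(ncol(cat), 0L)
  expect_error(readCatalog(f, strict = TRUE), "empty")
})

test_that("negative and fractional counts are rejected with location", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tcategory\tfeature\tcount",
               "s1\tA[C>A]A\tlagging\t2.5"), f)
  expect_error(readCatalog(f), "non-integer")
  writeLines(c("sample\tcategory\tfeature\tcount",
               "s1\tA[C>A]A\tlagging\t-1"), f)
  expect_error(readCatalog(f), "negative|non-integer")
})

test_that("mixed known/unknown SBS labels are rejected, listing offenders", {
  expect_error(
    StrandedCatalog(matrix(1L, 2, 1,
                           dimnames = list(c("A[C>A]A", "A[Z>A]A"), "s1"))),
    "unknown mutation category")
})

test_that("a BRCA-shaped catalog round-trips bit-identically (wide and long)", {
  set.seed(11)
  T <- 560L; M <- 96L
  tot <- c(313219L, 209488L)
  mk <- function(total) {
    cell <- as.vector(rmultinom(1L, total, rep(1, T * M)))
    matrix(as.integer(cell), M, T,
           dimnames = list(canonicalCategories(), paste0("s", seq_len(T))))
  }
  cat <- StrandedCatalog(mk(tot[1L]), mk(tot[2L]))
  expect_identical(as.integer(colSums(sampleTotals(cat))), tot)
  for (fmt in c("wide", "long")) {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCatalog(cat, f, format = fmt)
    back <- readCatalog(f)
    expect_identical(strandCounts(back, 1L), strandCounts(cat, 1L))
    expect_identical(strandCounts(back, 2L), strandCounts(cat, 2L))
    expect_identical(featureValueLabels(back), featureValueLabels(cat))
  }
})

test_that("mergeStrands sums elementwise, is idempotent and conserves totals", {
  c0 <- matrix(c(2L, 0L), 2, 1, dimnames = list(c("x", "y"), "s1"))
  c1 <- matrix(c(1L, 5L), 2, 1, dimnames = list(c("x", "y"), "s1"))
  cat <- StrandedCatalog(c0, c1)
  m <- mergeStrands(cat)
  expect_identical(unname(strandCounts(m, 1L)), matrix(c(3L, 5L), 1))
  expect_true(all(strandCounts(m, 2L) == 0L))
  expect_identical(featureName(m), "merged")
  m2 <- mergeStrands(m)
  expect_identical(strandCounts(m2, 1L), strandCounts(m, 1L))
  expect_identical(sampleTotals(m)[, 1L],
                   sampleTotals(cat)[, 1L] + sampleTotals(cat)[, 2L])
})

test_that("signature files load in either orientation, renormalized", {
  g <- matrix(rgamma(5 * 96, 1), 5, 96,
              dimnames = list(paste("Signature", c(1, 2, 5, 9, 13)),
                              canonicalCategories()))
  sigs <- SignatureMatrix(g)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSignatures(sigs, f)                       # signatures in rows
  back <- readSignatures(f)
  expect_equal(gammaMatrix(back), gammaMatrix(sigs), tolerance = 1e-12)

  ## COSMIC v2 layout: contexts in rows, one column per signature, with a
  ## 7x-scaled row that must renormalize away
  gv2 <- t(gammaMatrix(sigs))
  gv2[, 2L] <- gv2[, 2L] * 7
  df <- data.frame(`Somatic Mutation Type` = rownames(gv2), gv2,
                   check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- readSignatures(f)
  expect_equal(gammaMatrix(back2), gammaMatrix(sigs), tolerance = 1e-12)

  ## subset by embedded number, in request order
  sub <- readSignatures(f, subset = c(13, 1))
  expect_identical(signatureIds(sub), c("Signature 13", "Signature 1"))
  expect_error(readSignatures(f, subset = c(1, 99)), "absent")
})

test_that("zero signature rows error; uniform rows load unchanged", {
  expect_error(SignatureMatrix(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)),
               "zero")
  u <- matrix(1 / 96, 2, 96, dimnames = list(c("S1", "S2"),
                                             canonicalCategories()))
  expect_equal(gammaMatrix(SignatureMatrix(u)), u, tolerance = 0)
})

test_that("exposures round-trip with flooring applied on load", {
  e <- InherentExposures(matrix(c(0.4, 0.6, 1, 0), 2, 2, byrow = TRUE))
  em <- exposureMatrix(e)
  expect_true(all(em > 0))                        # floored
  expect_equal(unname(rowSums(em)), c(1, 1), tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExposures(e, f)
  expect_equal(exposureMatrix(readExposures(f)), em, tolerance = 1e-9)
})

test_that("model parameter tables round-trip", {
  p <- ModelParams("JMCSM", aLog = log(c(S1 = 1200, S2 = 340)),
                   bLog = log(c(800, 90)), sigma = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeParams(p, f)
  back <- readParams(f)
  expect_identical(modelKind(back), "JMCSM")
  expect_equal(aParams(back), aParams(p), tolerance = 1e-9)
  expect_equal(bParams(back), bParams(p), tolerance = 1e-9)
})
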