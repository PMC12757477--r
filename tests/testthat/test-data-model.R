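# Readers/writers and the validity of the shared domain types.

test_that("sample design reads, validates and reports its structure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcondition\treplicate",
               sprintf("LP_r%d\tLP\t%d", 1:3, 1:3),
               sprintf("WT_r%d\tWT\t%d", 1:4, 1:4)), f)
  d <- readSampleDesign(f, reference = "WT")
  expect_setequal(conditions(d), c("LP", "WT"))
  expect_length(samplesFor(d, "LP"), 3L)
  expect_length(samplesFor(d, "WT"), 4L)
  expect_identical(referenceCondition(d), "WT")

  # duplicated ids are rejected, naming the offender
  writeLines(c("sample_id\tcondition\treplicate",
               "s1\tLP\t1", "s1\tLP\t2"), f)
  expect_error(readSampleDesign(f), "s1")

  # empty file and missing columns are format errors
  writeLines(character(), f)
  expect_error(readSampleDesign(f), "empty")
  writeLines(c("sample_id\tcondition", "s1\tLP"), f)
  expect_error(readSampleDesign(f), "replicate")
})

test_that("abundance tables round-trip with missing-vs-zero semantics", {
  set.seed(1)
  m <- matrix(rexp(12, 1e-6), 4, 3,
              dimnames = list(paste0("P", 1:4), paste0("s", 1:3)))
  m[2, 3] <- NA
  tab <- tinyTable(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAbundanceTable(tab, f)
  back <- readAbundanceTable(f, "protein")
  expect_equal(abundances(back), m, tolerance = 1e-11)
  # the mask survives the round trip and missing is not zero
  expect_true(is.na(abundances(back)[2, 3]))
  imputed <- abundances(back)
  imputed[is.na(imputed)] <- 0
  expect_false(isTRUE(all.equal(rowMeans(imputed),
                                rowMeans(abundances(back), na.rm = TRUE))))

  # negative cells and non-numeric cells are rejected with coordinates
  writeLines(c("feature_id\ts1\ts2", "P1\t1.5\t-5.0"), f)
  expect_error(readAbundanceTable(f, "protein"), "P1.*s2")
  writeLines(c("feature_id\ts1", "P1\tabc"), f)
  expect_error(readAbundanceTable(f, "protein"), "non-numeric")
  # blank and "NA" cells are both missing
  writeLines(c("feature_id\ts1\ts2\ts3", "P1\t\tNA\t2.0"), f)
  expect_identical(is.na(abundances(readAbundanceTable(f, "protein"))[1, ]),
                   c(s1 = TRUE, s2 = TRUE, s3 = FALSE))
})

test_that("abundance table class enforces its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(tinyTable(m), "unique")
  m2 <- matrix(c(1, -1, 2, 3), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(tinyTable(m2), "negative")
  expect_error(tinyTable(matrix(1, 1, 1, dimnames = list("a", "s")),
                         kind = "metabolite"), "kind")
})

test_that("contrast results round-trip at 12 significant digits", {
  set.seed(2)
  p <- sort(runif(10))
  res <- contrastDf(sprintf("F%02d", 1:10), rnorm(10), p, bhOracle(p))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeContrastResult(res, f)
  back <- readContrastResult(f)
  expect_identical(names(back),
                   c("feature_id", "log2fc", "p_raw", "p_adj", "direction"))
  expect_equal(back$log2fc, res$log2fc, tolerance = 1e-11)
  expect_equal(back$p_adj, res$p_adj, tolerance = 1e-11)
  expect_identical(back$direction, res$direction)

  expect_error(writeContrastResult(res[0, ], f), "empty")
  bad <- res
  bad$p_adj[1] <- bad$p_raw[1] / 2
  expect_error(writeContrastResult(bad, f), "p_adj")
  bad2 <- res
  bad2$direction <- "sideways"
  expect_error(writeContrastResult(bad2, f), "direction")
})

test_that("GMT and edge-list files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(sets, f, description = c("first", "second"))
  back <- readGmt(f, source_db = "db1")
  expect_identical(back$alpha, sets$alpha)
  expect_identical(back$beta, sets$beta)
  expect_identical(attr(back, "source_db"), c("db1", "db1"))
  writeLines("only_name\tdesc", f)
  expect_error(readGmt(f), "member")

  e <- data.frame(from = c("a", "b"), to = c("b", "c"), score = c(0.9, 0.4))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(e, f2)
  back2 <- readEdgeList(f2)
  expect_identical(back2$from, e$from)
  expect_equal(back2$score, e$score, tolerance = 1e-11)
})
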