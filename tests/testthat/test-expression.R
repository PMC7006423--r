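test_that("delimited matrices parse with missing cells and round-trip losslessly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB",
               "s1\t1.5\t",
               "s2\t-0.25\t2",
               "s3\t0\t3.125"), tmp)
  m <- read_expression_matrix(tmp)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(unclass(m)["s1", "B"]))

  set.seed(42)
  vals <- matrix(rnorm(12), 3, 4)
  vals[2, 3] <- NA
  orig <- toy_matrix(vals)
  out <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(orig, out)
  back <- read_expression_matrix(out)
  expect_identical(unclass(back)[, ], unclass(orig)[, ])
  expect_identical(rownames(back), rownames(orig))
  expect_identical(colnames(back), colnames(orig))
})

test_that("both orientations are accepted and malformed input is rejected", {
  vals <- matrix(1:6 / 2, 2, 3)
  m <- toy_matrix(vals)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # write transposed by hand: proteins in rows
  tvals <- t(unclass(m))
  writeLines(c(paste(c("protein_id", rownames(m)), collapse = "\t"),
               vapply(seq_len(nrow(tvals)), function(i)
                 paste(c(rownames(tvals)[i], tvals[i, ]), collapse = "\t"),
                 character(1))), tmp)
  back <- read_expression_matrix(tmp, orientation = "proteins_in_rows")
  expect_equal(unclass(back)[, ], unclass(m)[, ])

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "s1\t1\t2", "s2\t3"), bad)
  expect_error(read_expression_matrix(bad), "line 3")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tA", "s1\t1\t2"), dup)
  expect_error(read_expression_matrix(dup), "duplicate")
})

test_that("response groups follow the PFS thresholds and partition known patients", {
  co <- toy_cohort(c(2.0, 13.1, 24.0, 3.0, 23.99, 30, NA))
  expect_equal(as.character(co$group),
               c("poor", "normal", "long_term", "poor", "normal",
                 "long_term", NA))
  # group counts over known-PFS patients sum to that number
  expect_equal(sum(table(co$group)), sum(!is.na(co$pfs_months)))

  # exclusive 24-month boundary demotes exactly the boundary patient
  excl <- assign_response_groups(
    data.frame(patient_id = c("a", "b"), pfs_months = c(24, 24.01)),
    group_thresholds(long_min_inclusive = FALSE))
  expect_equal(as.character(excl$group), c("normal", "long_term"))

  expect_error(toy_cohort(c(1, -2)), "non-positive")
  expect_error(assign_response_groups(
    data.frame(patient_id = "a", pfs_months = NA_real_)), "unknown")
})

test_that("detection filtering keeps completeness >= the threshold and is monotone", {
  vals <- matrix(rnorm(40), 10, 4)
  vals[, 1] <- NA                 # never detected
  vals[1:3, 2] <- NA              # 70% complete
  m <- toy_matrix(vals)
  kept <- filter_detected(m, 0.8)
  expect_equal(colnames(kept), c("PR03", "PR04"))
  expect_equal(attr(kept, "meta")$detection$dropped, 2L)
  # complete protein survives any threshold; monotone in min_fraction
  for (f in c(0.1, 0.5, 0.9, 1)) {
    expect_true("PR04" %in% colnames(filter_detected(m, f)))
  }
  fr <- seq(0.05, 1, by = 0.05)
  counts <- vapply(fr, function(f) ncol(filter_detected(m, f)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("z-scoring gives exact mean 0 / sd 1 per protein and is idempotent", {
  expect_equal(unclass(zscore_normalize(toy_matrix(matrix(c(1, 2, 3)))))[, 1],
               c(S01 = -1, S02 = 0, S03 = 1))
  set.seed(7)
  vals <- matrix(rnorm(60, sd = 3), 12, 5)
  vals[c(2, 15, 33)] <- NA
  z <- zscore_normalize(toy_matrix(vals))
  expect_equal(unname(colMeans(z, na.rm = TRUE)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd, na.rm = TRUE)), rep(1, 5),
               tolerance = 1e-12)
  z2 <- zscore_normalize(z)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  expect_true(all(is.na(z) == is.na(vals)))

  const <- toy_matrix(cbind(rnorm(5), rep(2, 5)))
  expect_error(zscore_normalize(const), "PR02")
})

test_that("imputation fills per-protein median or half-minimum and nothing else", {
  vals <- matrix(c(1, 2, 3, NA,
                   4, NA, 8, 12), 4, 2)
  m <- toy_matrix(vals)
  med <- impute_missing(m, "median")
  expect_equal(unname(unclass(med)[4, 1]), 2)
  expect_equal(unname(unclass(med)[2, 2]), 8)
  hm <- impute_missing(m, "half_minimum")
  expect_equal(unname(unclass(hm)[4, 1]), 0.5)
  expect_equal(unname(unclass(hm)[2, 2]), 2)
  expect_equal(unclass(impute_missing(m, "none"))[, ], vals,
               ignore_attr = TRUE)
  expect_equal(unclass(med)[1:3, 1], unclass(m)[1:3, 1])
})
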