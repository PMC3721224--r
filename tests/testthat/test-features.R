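make_peaks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], rt_min = as.numeric(r[[2]]),
               height = as.numeric(r[[3]]),
               base_mass = if (length(r) > 3) as.numeric(r[[4]]) else NA_real_,
               envelope = NA_character_, stringsAsFactors = FALSE)))
}

test_that("base-peak normalization maps the tallest peak to exactly 100", {
  expect_equal(normalize_heights(c(1000, 500, 50)), c(100, 50, 5))
  expect_equal(normalize_heights(7), 100)
  expect_equal(normalize_heights(c(200, 200)), c(100, 100))
  expect_error(normalize_heights(numeric(0)), "empty")
  expect_error(normalize_heights(c(10, -1)), "positive")
})

test_that("peak filtering is strict on threshold and closed on the window", {
  pk <- data.frame(rt_min = c(12, 15, 20), rel_height = c(100, 50, 5))
  expect_identical(nrow(filter_peaks(pk)), 2L)
  pk <- data.frame(rt_min = 35, rel_height = 100)
  expect_identical(nrow(filter_peaks(pk)), 0L)
  pk <- data.frame(rt_min = c(12, 13), rel_height = c(100, 10.0))
  expect_identical(filter_peaks(pk)$rel_height, 100)    # 10.0 is dropped
  pk <- data.frame(rt_min = c(10, 30), rel_height = c(100, 50))
  expect_identical(nrow(filter_peaks(pk)), 2L)          # closed window
})

test_that("filtering happens per sample before matching", {
  pk <- make_peaks(list("s1", 12, 1000), list("s1", 13, 50),
                   list("s2", 13, 900))
  # rt 13 is 5% in s1 (dropped) but 100% in s2 (kept)
  ft <- match_features(preprocess_peaks(pk))
  expect_identical(dim(ft$values), c(2L, 2L))
  expect_equal(unname(ft$values["s1", 2]), 0)
  expect_equal(unname(ft$values["s2", 2]), 100)
})

test_that("rt binning joins within tolerance and splits outside it", {
  pk <- make_peaks(list("s1", 12.00, 100), list("s2", 12.05, 100))
  ft <- match_features(preprocess_peaks(pk))
  expect_identical(ncol(ft$values), 1L)
  expect_true(all(ft$values > 0))

  pk <- make_peaks(list("s1", 12.00, 100), list("s2", 12.50, 100))
  ft <- match_features(preprocess_peaks(pk))
  expect_identical(ncol(ft$values), 2L)
})

test_that("mass tolerance separates co-eluting ions of different mass", {
  pk <- make_peaks(list("s1", 12.00, 100, 317), list("s2", 12.03, 100, 466))
  ft <- match_features(preprocess_peaks(pk))
  expect_identical(ncol(ft$values), 2L)
})

test_that("one peak per sample per bin; the closer rt wins", {
  pk <- make_peaks(list("s1", 12.00, 100), list("s2", 12.00, 100),
                   list("s2", 12.06, 90))
  ft <- match_features(preprocess_peaks(pk))
  expect_identical(ncol(ft$values), 2L)
  # s2's 12.00 peak holds the shared bin; 12.06 seeded its own
  expect_equal(sort(unname(ft$values["s2", ])), c(90, 100))
  expect_equal(unname(ft$values["s1", ]), c(100, 0))
})

test_that("matching is stable under input row permutation", {
  set.seed(42)
  cfg <- synth_config(seed = 42)
  pk <- simulate_peak_tables(cfg, simulate_profiles(cfg))
  pre <- preprocess_peaks(pk)
  ft1 <- match_features(pre)
  ft2 <- match_features(pre[sample(nrow(pre)), ])
  expect_identical(dim(ft1$values), dim(ft2$values))
  expect_equal(ft1$values, ft2$values)
})

test_that("feature count is monotone non-increasing in rt tolerance", {
  set.seed(11)
  pk <- make_peaks(list("s1", 12.00, 100), list("s2", 12.08, 100),
                   list("s1", 12.30, 80), list("s2", 12.55, 70),
                   list("s3", 12.62, 60))
  pre <- preprocess_peaks(pk, threshold = 10)
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
                   function(tol) ncol(match_features(pre, rt_tol = tol)$values),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the default synthetic study yields exactly 43 recurring features", {
  cfg <- synth_config(seed = 5)
  ft <- match_features(preprocess_peaks(
    simulate_peak_tables(cfg, simulate_profiles(cfg))))
  expect_identical(ncol(ft$values), 43L)
  expect_identical(nrow(ft$values), 21L)
  # row maxima are 100 before filtering wipes nothing above threshold
  expect_true(all(abs(apply(ft$values, 1, max) - 100) < 1e-9))
  nz <- ft$values[ft$values > 0]
  expect_true(all(nz > 10 & nz <= 100))
})

test_that("feature tables round-trip losslessly through CSV", {
  cfg <- synth_config(seed = 3)
  ft <- match_features(preprocess_peaks(
    simulate_peak_tables(cfg, simulate_profiles(cfg))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(back$values, ft$values)
  expect_equal(back$features$rt, ft$features$rt)
  expect_equal(back$features$base_mass, ft$features$base_mass)

  empty <- feature_table(matrix(numeric(0), 0, 0),
                         data.frame(rt = numeric(0), base_mass = numeric(0),
                                    envelope = character(0)))
  write_feature_table(empty, path)
  expect_identical(ncol(read_feature_table(path)$values), 0L)
})

test_that("peak table reader validates structure and values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,rt_min,height", "s1,12.0,100", "s1,oops,50"), path)
  expect_error(read_peak_table(path), "non-numeric rt_min at data line 2")
  writeLines(c("sample_id,rt_min", "s1,12.0"), path)
  expect_error(read_peak_table(path), "height")
  writeLines(c("sample_id,rt_min,height", "s1,12.0,-5"), path)
  expect_error(read_peak_table(path), "positive")
})
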