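test_that("series construction enforces the domain invariants", {
  expect_s3_class(make_test_series(rep(70, 1830)), "rso2_series")
  # saturation bound
  expect_error(make_test_series(c(rep(70, 199), 101)), "\\[0, 100\\]")
  # intraop floor of 100 points
  expect_error(make_test_series(rep(70, 50)), "at least 100")
  # baseline window must span exactly 60 samples
  expect_error(
    rso2_series(rep(70, 300), baseline_window = 1:59, intraop_window = 60:300),
    "exactly 60")
  # baseline must precede intraop
  expect_error(
    rso2_series(rep(70, 300), baseline_window = 100:159, intraop_window = 50:250),
    "precede")
})

test_that("compute_baseline is the mean of the 2-minute window", {
  expect_equal(compute_baseline(make_test_series(rep(70, 200), 73.4)), 73.4)
  s <- rso2_series(c(rep(70, 30), rep(74, 30), rep(60, 200)),
                   baseline_window = 1:60, intraop_window = 61:260)
  expect_equal(compute_baseline(s), 72.0)
})

test_that("summarize_series reports the study summary block", {
  sm <- summarize_series(make_test_series(rep(70, 2940)))
  expect_equal(sm$mean, 70)
  expect_equal(sm$lowest, 70)
  expect_equal(sm$highest, 70)
  expect_equal(sm$duration_min, 98)

  sm2 <- summarize_series(make_test_series(rep(c(60, 70, 80), 50)))
  expect_equal(sm2$lowest, 60)
  expect_equal(sm2$highest, 80)
  expect_equal(sm2$mean, 70)

  expect_equal(summarize_series(make_test_series(rep(70, 1830)))$duration_min, 61)
})

test_that("desaturation metrics match hand evaluation and edge cases", {
  # hand-evaluated: threshold 63, two samples strictly below
  s <- make_test_series(c(rep(70, 95), 65, 62, 61, 64, 63), baseline_level = 70)
  dm <- desaturation_metrics(s, baseline = 70, fraction = 0.9)
  expect_equal(dm$threshold_value, 63)
  expect_equal(dm$duration_min, 2 * 2 / 60)
  expect_equal(dm$area_min_pct, ((63 - 62) + (63 - 61)) * 2 / 60)

  # all samples at/above threshold: zero burden (threshold is strict <)
  s2 <- make_test_series(rep(63, 200), baseline_level = 70)
  dm2 <- desaturation_metrics(s2, baseline = 70, fraction = 0.9)
  expect_equal(dm2$duration_min, 0)
  expect_equal(dm2$area_min_pct, 0)

  # rectangle: 60 min exactly 1 unit below threshold
  s3 <- make_test_series(rep(62, 1800), baseline_level = 70)
  dm3 <- desaturation_metrics(s3, baseline = 70, fraction = 0.9)
  expect_equal(dm3$duration_min, 60)
  expect_equal(dm3$area_min_pct, 60)

  expect_warning(desaturation_metrics(s3, baseline = 70, fraction = 0.5),
                 "nonstandard")
})

test_that("thresholds nest and area is bounded on arbitrary series", {
  for (seed in 1:20) {
    set.seed(seed)
    v <- pmin(100, pmax(0, 70 + cumsum(rnorm(500, 0, 0.8))))
    s <- make_test_series(v)
    bl <- compute_baseline(s)
    d <- lapply(c(0.8, 0.9, 1.0), function(f)
      desaturation_metrics(s, baseline = bl, fraction = f))
    dur <- vapply(d, function(x) x$duration_min, numeric(1))
    ar <- vapply(d, function(x) x$area_min_pct, numeric(1))
    expect_true(all(diff(dur) >= 0))  # 0.8 <= 0.9 <= 1.0
    expect_true(all(diff(ar) >= 0))
    for (k in 1:3)
      expect_lte(ar[k], dur[k] * (d[[k]]$threshold_value - min(v)) + 1e-12)
    expect_true(all((ar == 0) == (dur == 0)))
  }
})

test_that("write_series / read_series round-trips bit-exactly", {
  set.seed(42)
  v <- round(runif(400, 55, 85), 3) + pi * 1e-8  # non-representable decimals
  s <- make_test_series(v, subject_id = "RT01", side = "right")
  path <- file.path(withr::local_tempdir(), "RT01.csv")
  write_series(s, path)
  s2 <- read_series(path)
  expect_identical(s2$values, s$values)
  expect_identical(s2$baseline_window, s$baseline_window)
  expect_identical(s2$intraop_window, s$intraop_window)
  expect_identical(s2$subject_id, "RT01")
  expect_identical(s2$side, "right")
})

test_that("read_series validates format and fills only short gaps", {
  dir <- withr::local_tempdir()
  s <- make_test_series(rep(70, 200))
  path <- file.path(dir, "g.csv")
  write_series(s, path)

  # drop 4 samples (8 s): carried forward with a warning
  lines <- readLines(path)
  short <- lines[-(100:103)]
  writeLines(short, path)
  expect_warning(s2 <- read_series(path), "carry-forward")
  expect_equal(length(s2$values), length(s$values))

  # drop 7 samples (14 s): invalid
  writeLines(lines[-(100:106)], path)
  expect_error(suppressWarnings(read_series(path)), "dropout")

  # off-grid timestamp
  bad <- lines
  bad[100] <- sub("^([0-9]+)", "197", bad[100])
  writeLines(bad, path)
  expect_error(read_series(path), "grid|increasing")

  # value outside range
  bad <- lines
  bad[100] <- sub(",.*$", ",101", bad[100])
  writeLines(bad, path)
  expect_error(read_series(path), "\\[0, 100\\]")

  # intraop too short
  s3 <- make_test_series(rep(70, 120))
  path3 <- file.path(dir, "h.csv")
  write_series(s3, path3)
  meta <- jsonlite::read_json(paste0(sub(".csv", "", path3), ".meta.json"),
                              simplifyVector = TRUE)
  meta$intraop_end_s <- meta$intraop_start_s + 100  # 50 points
  jsonlite::write_json(meta, paste0(sub(".csv", "", path3), ".meta.json"),
                       auto_unbox = TRUE)
  expect_error(read_series(path3), "at least 100")
})
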