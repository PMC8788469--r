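test_that("Cook's-distance flags match the leave-one-out refit oracle", {
  # perfectly collinear points have zero distance everywhere
  expect_length(cooks_outliers(1:10, 2 * (1:10) + 1), 0L)
  # one displaced point dominates the mean distance
  x <- 1:10
  y <- 2 * x
  y[4] <- y[4] + 8
  expect_equal(cooks_outliers(x, y), oracle_cooks_outliers(x, y))
  expect_equal(cooks_outliers(x, y), 4L)
  # an infinite threshold flags nothing
  expect_length(cooks_outliers(x, y, k = Inf), 0L)
  expect_error(cooks_outliers(rep(1, 5), 1:5), "degenerate")

  # randomized agreement with the oracle across small regressions
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- 1.5 * x + rnorm(n, sd = 0.3)
    if (runif(1) < 0.5) y[sample(n, 1)] <- y[sample(n, 1)] + 4
    expect_equal(cooks_outliers(x, y), oracle_cooks_outliers(x, y))
  }
})

test_that("identity data calibrate to slope 1, intercept 0, r2 1", {
  expected <- rep(10^(0:4), each = 5)
  std <- tibble::tibble(accession = as.character(1:25),
                        abundance = expected, expected_fmol = expected)
  m <- fit_calibration(std)
  expect_equal(m$slope, 1, tolerance = 1e-9)
  expect_equal(m$intercept, 0, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_length(m$removed_accessions, 0L)
  expect_equal(m$n_points, 25L)
  # constant multiplicative bias moves only the intercept
  m2 <- fit_calibration(dplyr::mutate(std, abundance = abundance * 100))
  expect_equal(m2$slope, 1, tolerance = 1e-9)
  expect_equal(m2$intercept, -2, tolerance = 1e-9)
  # fitting is invariant to row order
  m3 <- fit_calibration(std[sample(25), ])
  expect_equal(m3$slope, m$slope)
  expect_equal(m3$intercept, m$intercept)
})

test_that("gross planted outliers are removed once and the line refit", {
  std <- planted_outlier_standards()
  m <- fit_calibration(std)
  expect_equal(m$n_points, 25L)
  expect_setequal(m$removed_accessions,
                  std$accession[std$planted_outlier])
  expect_equal(m$slope, 1, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-9)
})

test_that("undetected standards are excluded and too few points error", {
  std <- tibble::tibble(
    accession = sprintf("U%d", 1:6),
    abundance = c(1, 10, 100, 1000, 0, NA),
    expected_fmol = c(1, 10, 100, 1000, 5, 5)
  )
  expect_message(m <- fit_calibration(std), "excluding 2")
  expect_equal(m$n_points, 4L)
  expect_error(
    suppressMessages(fit_calibration(std[c(1, 2, 5, 6), ])),
    "at least 4"
  )
})

test_that("pooling refits on the union of retained replicate points", {
  expected <- rep(10^(0:4), each = 5)
  std <- tibble::tibble(accession = as.character(1:25),
                        abundance = expected, expected_fmol = expected)
  m <- fit_calibration(std)
  # identical replicates pool to the same line
  pooled <- pool_reference(list(m, m, m))
  expect_equal(pooled$slope, m$slope, tolerance = 1e-9)
  expect_equal(pooled$intercept, m$intercept, tolerance = 1e-9)
  expect_equal(pool_reference(list(m))$slope, m$slope)

  # two noisy replicates around the same line pool between their slopes
  set.seed(42)
  reps <- lapply(1:2, function(i) {
    fit_calibration(dplyr::mutate(std, abundance = abundance * 10^rnorm(25, 0, 0.15)))
  })
  pooled <- pool_reference(reps)
  slopes <- vapply(reps, `[[`, numeric(1), "slope")
  expect_gte(pooled$slope, min(slopes) - 1e-9)
  expect_lte(pooled$slope, max(slopes) + 1e-9)
  expect_error(pool_reference(list()), "at least one")
})

test_that("calibration read-off converts relative abundance to fmol", {
  m <- structure(
    list(slope = 1, intercept = 2, r2 = 1, removed_accessions = character(0),
         n_points = 25L, space = "log10-log10", points = tibble::tibble()),
    class = "calibration"
  )
  rel <- tibble::tibble(accession = c("A", "B", "C"), sample_id = "S1",
                        abundance = c(0.5, NA, 0))
  out <- apply_calibration(rel, m)
  expect_equal(out$fmol[1], 50)
  expect_true(all(is.na(out$fmol[2:3])))

  # identity model: fmol = rel, so calibrate-then-apply recovers standards
  expected <- rep(10^(0:4), each = 5)
  std <- tibble::tibble(accession = as.character(1:25),
                        abundance = expected, expected_fmol = expected)
  ident <- fit_calibration(std)
  back <- apply_calibration(
    dplyr::mutate(std, sample_id = "S1"), ident
  )
  expect_equal(back$fmol, expected, tolerance = 1e-9)
})

test_that("calibration models round-trip through JSON", {
  std <- planted_outlier_standards()
  m <- fit_calibration(std)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path)
  back <- read_calibration(path)
  expect_equal(back$slope, m$slope)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$r2, m$r2)
  expect_setequal(back$removed_accessions, m$removed_accessions)
  expect_equal(back$points$log10_observed, m$points$log10_observed)
})

test_that("tidy, glance and autoplot expose the fitted model", {
  m <- fit_calibration(planted_outlier_standards())
  td <- tidy(m)
  expect_equal(td$estimate, c(m$intercept, m$slope))
  gl <- glance(m)
  expect_equal(gl$n_points, 25L)
  expect_equal(gl$n_removed, 3L)
  expect_s3_class(autoplot(m), "ggplot")
})
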