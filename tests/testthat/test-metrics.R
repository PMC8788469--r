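long_tbl <- function(mat) {
  tibble::as_tibble(mat, rownames = "accession") |>
    tidyr::pivot_longer(-accession, names_to = "sample_id",
                        values_to = "abundance")
}

test_that("replicate CV uses the n-1 standard deviation", {
  mat <- rbind(
    A = c(S1 = 100, S2 = 100, S3 = 100),
    B = c(90, 110, NA)
  )
  expect_message(out <- cv_among_replicates(long_tbl(mat)), NA)
  expect_equal(out$cv_pct[out$accession == "A"], 0)
  # sd(90, 110) = 14.1421; mean 100
  expect_equal(out$cv_pct[out$accession == "B"], 14.14214, tolerance = 1e-5)
  expect_equal(attr(out, "median_cv_pct"), median(out$cv_pct))

  single <- long_tbl(rbind(A = c(S1 = 1)))
  expect_error(cv_among_replicates(single), "2 replicate")
})

test_that("among-protein CV is grouped by concentration decade", {
  abund <- tibble::tibble(
    accession = c("U1", "U2", "U3", "U4"),
    sample_id = "S1",
    abundance = c(10, 30, 100, 100)
  )
  expected <- tibble::tibble(
    accession = c("U1", "U2", "U3", "U4"),
    expected_fmol = c(50, 60, 500, 600)  # decades 1 and 2
  )
  out <- cv_among_proteins(abund, expected)
  expect_equal(out$cv_pct[out$decade == 1], 70.71068, tolerance = 1e-5)
  expect_equal(out$cv_pct[out$decade == 2], 0)
  expect_equal(attr(out, "median_cv_pct"), mean(c(70.71068, 0)),
               tolerance = 1e-5)

  # a single usable decade is its own median; lone-protein decades skipped
  expected2 <- dplyr::mutate(expected, expected_fmol = c(50, 60, 500, 5000))
  expect_message(out2 <- cv_among_proteins(abund, expected2), "skipping 2")
  expect_equal(attr(out2, "median_cv_pct"), 70.71068, tolerance = 1e-5)
})

test_that("bootstrap absolute error is reproducible and correctly pooled", {
  est <- tibble::tibble(accession = c("U1", "U2"), sample_id = "S1",
                        fmol = c(50, 100))
  exp_tbl <- tibble::tibble(accession = c("U1", "U2"),
                            expected_fmol = c(50, 50))
  # errors are {0%, 100%}: resample medians can only hit 0, 50 or 100
  be <- bootstrap_absolute_error(est, exp_tbl, B = 2000, seed = 9)
  expect_equal(be$median_error_pct, 50)
  expect_true(all(be$boot_medians %in% c(0, 50, 100)))
  be2 <- bootstrap_absolute_error(est, exp_tbl, B = 2000, seed = 9)
  expect_identical(be$boot_medians, be2$boot_medians)

  # perfect estimates give an all-zero distribution
  be0 <- bootstrap_absolute_error(
    est, dplyr::mutate(exp_tbl, expected_fmol = c(50, 100)), B = 50, seed = 1
  )
  expect_equal(be0$median_error_pct, 0)
  expect_equal(be0$ci, c(0, 0))
  expect_equal(glance(be0)$n_errors, 2L)

  expect_error(
    bootstrap_absolute_error(est, dplyr::mutate(exp_tbl, expected_fmol = 0)),
    "positive"
  )
})

test_that("validation-spike error reports the median over present spikes", {
  manifest <- make_validation_spikes()
  est <- tibble::tibble(accession = manifest$accession, sample_id = "S1",
                        fmol = manifest$expected_fmol)
  out <- error_vs_known(est, manifest)
  expect_equal(attr(out, "median_error_pct"), 0)

  est2 <- dplyr::mutate(est, fmol = fmol * 1.26)
  out2 <- error_vs_known(est2, manifest)
  expect_equal(attr(out2, "median_error_pct"), 26, tolerance = 1e-9)

  expect_warning(out3 <- error_vs_known(est2[-1, ], manifest), "INS")
  expect_equal(nrow(out3), 3L)
  expect_error(error_vs_known(est, manifest[0, ]), "empty")
})

test_that("mass ratio handles subsets and empty subsets", {
  prot <- tibble::tibble(accession = c("A", "B"),
                         mw_g_per_mol = c(5e4, 1e5))
  abs_tbl <- tibble::tibble(accession = c("A", "B"), sample_id = "S1",
                            conc_mol = c(4e-11, 1e-11))
  expect_equal(mass_ratio(abs_tbl, prot, 3e-6)$mass_ratio, 1)
  half <- dplyr::mutate(abs_tbl, conc_mol = conc_mol / 2)
  expect_equal(mass_ratio(half, prot, 3e-6)$mass_ratio, 0.5)
  expect_equal(
    mass_ratio(abs_tbl, prot, 3e-6, subset = "A")$mass_ratio, 2e-6 / 3e-6
  )
  expect_equal(
    mass_ratio(abs_tbl, prot, 3e-6, subset = character(0))$mass_ratio, 0
  )
  # fmol input is accepted and converted
  fm <- tibble::tibble(accession = c("A", "B"), sample_id = "S1",
                       fmol = c(4e-11, 1e-11) * 1e15)
  expect_equal(mass_ratio(fm, prot, 3e-6)$mass_ratio, 1)
})

test_that("technique enumeration is a deterministic Cartesian product", {
  grid <- enumerate_techniques(quant_methods(), c("UPS2", "TPA"),
                               paste0("C", 1:5))
  expect_equal(nrow(grid), 70L)
  # methods vary outermost
  expect_equal(grid$method[1:10], rep("PAI", 10))
  expect_equal(nrow(enumerate_techniques("NSAF", "UPS2", "std")), 1L)
  expect_error(enumerate_techniques(character(0), "UPS2", "std"))
})

test_that("metrics are invariant to protein ordering", {
  set.seed(61)
  abund <- tibble::tibble(
    accession = rep(sprintf("P%d", 1:6), each = 3),
    sample_id = rep(c("S1", "S2", "S3"), 6),
    abundance = rlnorm(18)
  )
  perm <- abund[sample(nrow(abund)), ]
  a <- cv_among_replicates(abund)
  b <- cv_among_replicates(perm)
  expect_equal(attr(a, "median_cv_pct"), attr(b, "median_cv_pct"))
  expect_equal(dplyr::arrange(a, accession), dplyr::arrange(b, accession))
})
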