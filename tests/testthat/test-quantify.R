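sc_row <- function(sample, pep, prot, sc, xic = NA_real_) {
  tibble::tibble(sample_id = sample, peptide_seq = pep, proteins = prot,
                 spectral_count = sc, xic_area = xic,
                 rt_sd_seconds = NA_real_)
}

test_that("PAI is observed over observable distinct peptides", {
  # P1 has 3 observable peptides; 2 observed with spectra
  ev <- dplyr::bind_rows(
    sc_row("S1", "AAAAAAAK", "P1", 3L),
    sc_row("S1", "DDDDDDD", "P1", 1L),
    sc_row("S1", "AAAAAAAK", "P2", 0L, xic = 100)  # no spectra: not observed
  )
  out <- pai_index(ev, toy_proteins())
  expect_equal(out$abundance[out$accession == "P1"], 2 / 3)
  expect_equal(out$abundance[out$accession == "P2"], 0)
  expect_error(pai_index(sc_row("S1", "AAAK", "NOPE", 1L), toy_proteins()),
               "NOPE")
})

test_that("PAI reports proteins without observable peptides absent", {
  prot <- annotate_proteins(tibble::tibble(
    accession = "SHORT", sequence = "GGKGG"  # no peptide in the 7-30 window
  ))
  ev <- sc_row("S1", "GGK", "SHORT", 2L)
  expect_warning(out <- pai_index(ev, prot), "observable")
  expect_true(is.na(out$abundance))
})

test_that("emPAI is 10^PAI - 1", {
  pai <- tibble::tibble(accession = c("A", "B", "C"), sample_id = "S1",
                        abundance = c(0, 1, 0.5))
  expect_equal(empai_index(pai)$abundance,
               c(0, 9, 2.16228), tolerance = 1e-5)
})

test_that("SAF divides summed spectra by protein length", {
  ev <- dplyr::bind_rows(
    sc_row("S1", "AAAAAAAK", "P1", 7L),
    sc_row("S1", "DDDDDDD", "P1", 3L),
    sc_row("S1", "VVVVVVVK", "P3", 0L, xic = 5)
  )
  out <- saf_index(ev, toy_proteins())
  expect_equal(out$abundance[out$accession == "P1"], 10 / 23)
  expect_equal(out$abundance[out$accession == "P3"], 0)
})

test_that("NSAF normalizes SAF to unit sum excluding contaminants", {
  saf <- tibble::tibble(accession = c("A", "B"), sample_id = "S1",
                        abundance = c(0.1, 0.2))
  prot <- tibble::tibble(accession = c("A", "B"), role = "background")
  expect_equal(nsaf_index(saf, prot)$abundance, c(1, 2) / 3)

  # a single protein normalizes to exactly 1
  expect_equal(nsaf_index(saf[1, ], prot)$abundance, 1)

  # contaminants are excluded from the normalizing sum
  prot2 <- tibble::tibble(accession = c("A", "B"), role = c("background", "contaminant"))
  out <- nsaf_index(saf, prot2)
  expect_equal(out$abundance[out$accession == "A"], 1)
  expect_equal(out$abundance[out$accession == "B"], 2)

  saf0 <- dplyr::mutate(saf, abundance = 0)
  expect_error(nsaf_index(saf0, prot), "all-zero")
})

test_that("XIC preprocessing log-transforms and median-ratio normalizes", {
  ev <- dplyr::bind_rows(
    sc_row("REF", c("AAAAAAAK", "DDDDDDD"), "P1", 1L, xic = c(100, 1000)),
    sc_row("S2", c("AAAAAAAK", "DDDDDDD"), "P1", 1L, xic = c(100, 1000)),
    sc_row("S3", c("AAAAAAAK", "DDDDDDD"), "P1", 1L, xic = c(1000, 10000))
  )
  out <- preprocess_xic(ev, reference_sample = "REF")
  ref <- out[out$sample_id == "REF", ]
  expect_equal(sort(ref$log10_intensity), c(2, 3))
  # identical sample: zero shift
  expect_equal(out$log10_intensity[out$sample_id == "S2"],
               ref$log10_intensity)
  # constant 10x sample: shift of -1 brings it back onto the reference
  expect_equal(out$log10_intensity[out$sample_id == "S3"],
               ref$log10_intensity)
  # a sample sharing no peptide with the reference is an error
  ev2 <- dplyr::bind_rows(ev, sc_row("S4", "VVVVVVVK", "P3", 1L, xic = 50))
  expect_error(preprocess_xic(ev2, reference_sample = "REF"), "S4")
})

test_that("SUMnorm, TOP3 and iBAQ aggregate linear intensities correctly", {
  xic <- tibble::tibble(
    sample_id = "S1",
    peptide_seq = c("AAAAAAAK", "CCCCCCCR", "DDDDDDD", "EEEEEEEK"),
    proteins = "P1",
    log10_intensity = log10(c(10, 20, 30, 40)),
    intensity = c(10, 20, 30, 40)
  )
  prot <- toy_proteins()
  expect_equal(sumnorm_index(xic, prot)$abundance, 100 / 23)
  expect_equal(top3_index(xic, prot)$abundance, 30)
  expect_message(
    out2 <- top3_index(xic[1:2, ], prot),
    "fewer than 3"
  )
  expect_equal(out2$abundance, 15)
  expect_equal(ibaq_index(xic, prot)$abundance, 100 / 3)

  # a shared peptide contributes its full intensity to both proteins
  shared <- tibble::tibble(
    sample_id = "S1", peptide_seq = "AAAAAAAK", proteins = "P1;P3",
    log10_intensity = log10(60), intensity = 60
  )
  out <- ibaq_index(shared, prot)
  expect_equal(out$abundance[out$accession == "P1"], 60 / 3)
  expect_equal(out$abundance[out$accession == "P3"], 60 / 2)
})

test_that("quantify dispatches, with emPAI = 10^PAI - 1 elementwise", {
  sim <- simulate_dataset(sim_config(n_background = 25, n_samples = 2,
                                     seed = 31))
  pai <- quantify(sim$evidence, sim$proteins, "PAI")
  empai <- quantify(sim$evidence, sim$proteins, "emPAI")
  merged <- dplyr::inner_join(pai, empai, by = c("accession", "sample_id"))
  expect_equal(merged$abundance.y, 10^merged$abundance.x - 1)
  expect_equal(attr(empai, "method"), "emPAI")
  expect_error(quantify(sim$evidence, sim$proteins, "nope"), "must be one of")
})

test_that("NSAF sums to one per sample and ignores count scaling", {
  sim <- simulate_dataset(sim_config(n_background = 25, n_samples = 2,
                                     seed = 32))
  nsaf <- quantify(sim$evidence, sim$proteins, "NSAF")
  sums <- nsaf |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(abundance))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)

  scaled <- dplyr::mutate(sim$evidence, spectral_count = spectral_count * 5L)
  nsaf2 <- quantify(scaled, sim$proteins, "NSAF")
  expect_equal(nsaf2$abundance, nsaf$abundance)
})

test_that("intensity indices are homogeneous of degree 1", {
  sim <- simulate_dataset(sim_config(n_background = 25, n_samples = 1,
                                     rt_outlier_fraction = 0, seed = 33))
  for (m in c("SUMnorm", "TOP3", "iBAQ")) {
    base <- quantify(sim$evidence, sim$proteins, m)
    doubled <- quantify(
      dplyr::mutate(sim$evidence, xic_area = xic_area * 2),
      sim$proteins, m
    )
    merged <- dplyr::inner_join(base, doubled, by = c("accession", "sample_id"))
    expect_equal(merged$abundance.y, 2 * merged$abundance.x,
                 tolerance = 1e-9)
  }
})

test_that("every method rank-recovers truth in the noise-free limit", {
  cfg <- sim_config(
    n_background = 20, n_samples = 1, noise_sigma = 0,
    peptide_efficiency_sigma = 0, dropout_enabled = FALSE,
    shared_peptide_fraction = 0, rt_outlier_fraction = 0,
    proteins_per_level = 1,  # distinct true amounts, so ranks are unambiguous
    sc_rate_per_fmol = 5, seed = 34
  )
  sim <- simulate_dataset(cfg)
  truth <- dplyr::select(sim$proteins, accession, true_fmol)
  # iBAQ divides the summed intensity by the observable count, undoing the
  # peptide-count dependence exactly; its noise-free values are proportional
  # to the true amounts, hence perfectly rank-correlated
  ibaq <- quantify(sim$evidence, sim$proteins, "iBAQ") |>
    dplyr::inner_join(truth, by = "accession")
  expect_equal(stats::cor(ibaq$abundance, ibaq$true_fmol,
                          method = "spearman"), 1)
  # spectral counts at a high rate are exactly lambda-proportional only in
  # expectation; check strong (not necessarily perfect) rank agreement
  for (m in c("NSAF", "SUMnorm")) {
    rel <- quantify(sim$evidence, sim$proteins, m) |>
      dplyr::inner_join(truth, by = "accession")
    expect_gt(stats::cor(rel$abundance, rel$true_fmol, method = "spearman"),
              0.9)
  }
})
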