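#' Synthetic spike-in simulation configuration
#'
#' Parameters of the synthetic data generator: a background proteome at
#' log-uniform abundance plus a UPS2-like standard ladder (six levels,
#' eight proteins per level by default), observed through an explicit
#' model: logistic abundance-dependent peptide detection, Poisson spectral
#' counts (truncated at 1), and lognormal XIC intensities with a fixed
#' per-peptide ionization efficiency and per-observation noise.
#'
#' @param n_background Number of background proteins.
#' @param seq_len_range Length range (residues) for random sequences.
#' @param background_fmol_log10_range Log10 range of background true
#'   amounts (fmol); drawn log-uniformly.
#' @param standard_levels_fmol Strictly increasing standard amounts, one
#'   per level (default the UPS2 ladder 0.5-50000 fmol).
#' @param proteins_per_level Standard proteins at each level (default 8).
#' @param sc_rate_per_fmol Poisson rate of spectra per fmol per peptide.
#' @param xic_gain Linear XIC area per fmol per peptide.
#' @param peptide_efficiency_sigma SD (log10) of the fixed per-peptide
#'   ionization efficiency.
#' @param noise_sigma SD (log10) of the per-observation intensity noise.
#' @param dropout_midpoint_fmol Amount at which a peptide is detected with
#'   probability 1/2.
#' @param dropout_slope Steepness of the logistic detection curve (per
#'   log10 fmol).
#' @param dropout_enabled Disable (`FALSE`) to detect every observable
#'   peptide.
#' @param shared_peptide_fraction Fraction of peptides mapped to a second
#'   protein.
#' @param rt_outlier_fraction Fraction of peptides given a retention-time
#'   SD above 20 s (to exercise the RT filter).
#' @param n_samples Number of replicate samples to simulate.
#' @param digest [digest_params()] defining observable peptides.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background = 200,
                       seq_len_range = c(150L, 600L),
                       background_fmol_log10_range = c(1, 3),
                       standard_levels_fmol = c(0.5, 5, 50, 500, 5000, 50000),
                       proteins_per_level = 8L,
                       sc_rate_per_fmol = 0.5,
                       xic_gain = 1e4,
                       peptide_efficiency_sigma = 0.3,
                       noise_sigma = 0.2,
                       dropout_midpoint_fmol = 400,
                       dropout_slope = 3,
                       dropout_enabled = TRUE,
                       shared_peptide_fraction = 0.05,
                       rt_outlier_fraction = 0.02,
                       n_samples = 6L,
                       digest = digest_params(),
                       seed = 42L) {
  stopifnot(
    n_background >= 1, proteins_per_level >= 1,
    all(standard_levels_fmol > 0),
    all(diff(standard_levels_fmol) > 0),
    sc_rate_per_fmol > 0, xic_gain > 0,
    peptide_efficiency_sigma >= 0, noise_sigma >= 0,
    dropout_midpoint_fmol > 0, dropout_slope > 0,
    shared_peptide_fraction >= 0, shared_peptide_fraction <= 1,
    rt_outlier_fraction >= 0, rt_outlier_fraction <= 1,
    n_samples >= 1
  )
  structure(
    list(
      n_background = as.integer(n_background),
      seq_len_range = as.integer(seq_len_range),
      background_fmol_log10_range = background_fmol_log10_range,
      standard_levels_fmol = standard_levels_fmol,
      proteins_per_level = as.integer(proteins_per_level),
      sc_rate_per_fmol = sc_rate_per_fmol,
      xic_gain = xic_gain,
      peptide_efficiency_sigma = peptide_efficiency_sigma,
      noise_sigma = noise_sigma,
      dropout_midpoint_fmol = dropout_midpoint_fmol,
      dropout_slope = dropout_slope,
      dropout_enabled = isTRUE(dropout_enabled),
      shared_peptide_fraction = shared_peptide_fraction,
      rt_outlier_fraction = rt_outlier_fraction,
      n_samples = as.integer(n_samples),
      digest = digest,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Residue sampling weights: lysine + arginine at ~11% combined so tryptic
# peptides have realistic lengths; the other 18 residues uniform.
.AA_SAMPLING_PROB <- {
  p <- setNames(rep(0.89 / 18, 20), names(.AA_RESIDUE_MASS))
  p[c("K", "R")] <- 0.055
  p
}

random_sequences <- function(n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(len) {
    paste(sample(names(.AA_SAMPLING_PROB), len, replace = TRUE,
                 prob = .AA_SAMPLING_PROB), collapse = "")
  }, character(1))
}

#' Simulate a background proteome with a spiked standard ladder
#'
#' Generates random protein sequences for `n_background` background
#' proteins (true amounts log-uniform over the configured range) and
#' `proteins_per_level` standard proteins at each standard level
#' (`expected_fmol` set to the level). Deterministic for a fixed seed.
#'
#' @param config A [sim_config()] list.
#' @return Protein tibble: `accession`, `sequence`, `length_aa`, `role`
#'   (`background` / `standard`), `expected_fmol` (standards only) and
#'   `true_fmol`. Pass through [annotate_proteins()] before simulating
#'   evidence.
#' @export
simulate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_std <- length(config$standard_levels_fmol) * config$proteins_per_level
  levels <- rep(config$standard_levels_fmol, each = config$proteins_per_level)
  lo <- config$background_fmol_log10_range[1]
  hi <- config$background_fmol_log10_range[2]
  tibble::tibble(
    accession = c(
      sprintf("SYNUPS%02d", seq_len(n_std)),
      sprintf("SYNBG%04d", seq_len(config$n_background))
    ),
    sequence = random_sequences(n_std + config$n_background,
                                config$seq_len_range),
    role = rep(c("standard", "background"), c(n_std, config$n_background)),
    expected_fmol = c(levels, rep(NA_real_, config$n_background)),
    true_fmol = c(levels, 10^runif(config$n_background, lo, hi))
  ) |>
    dplyr::mutate(length_aa = nchar(.data$sequence))
}

#' Simulate peptide-level evidence
#'
#' For each protein and each of its observable tryptic peptides, in each
#' sample: the peptide is detected with probability
#' `plogis(dropout_slope * (log10(fmol) - log10(dropout_midpoint)))`
#' (1 when dropout is disabled); if detected, its spectral count is
#' Poisson(`sc_rate_per_fmol * fmol`) truncated to at least 1 and its XIC
#' area is `xic_gain * fmol * 10^(e_p + eps)`, where `e_p` is a fixed
#' per-peptide ionization efficiency (Normal in log10) and `eps` is
#' per-observation noise. Retention-time SDs are |Normal(3, 2)| seconds,
#' with `rt_outlier_fraction` of peptides forced above 20 s. A
#' `shared_peptide_fraction` of peptides is mapped to a second protein.
#'
#' @param proteome Annotated protein tibble from [simulate_proteome()] +
#'   [annotate_proteins()], with a `true_fmol` column.
#' @param config The same [sim_config()] used for the proteome.
#' @return Evidence tibble in the [read_evidence_table()] layout.
#' @export
simulate_evidence <- function(proteome, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(proteome))
  if (!all(c("n_observable", "true_fmol") %in% names(proteome))) {
    abort("`proteome` must be annotated (n_observable) and carry true_fmol")
  }
  set.seed(config$seed + 1L)

  peps <- proteome |>
    dplyr::mutate(peptide_seq = purrr::map(.data$sequence, \(s) {
      p <- unique(tryptic_digest(s, config$digest))
      len <- nchar(p)
      p[len >= config$digest$min_peptide_len &
          len <= config$digest$max_peptide_len]
    })) |>
    dplyr::select("accession", "true_fmol", "peptide_seq") |>
    tidyr::unnest("peptide_seq")
  n_pep <- nrow(peps)
  if (n_pep == 0L) abort("no observable peptides in the proteome")

  # fixed per-peptide properties
  peps$efficiency <- rnorm(n_pep, 0, config$peptide_efficiency_sigma)
  peps$rt_outlier <- runif(n_pep) < config$rt_outlier_fraction
  share <- runif(n_pep) < config$shared_peptide_fraction
  partner <- rep(NA_character_, n_pep)
  if (any(share) && nrow(proteome) > 1L) {
    partner[share] <- vapply(peps$accession[share], function(a) {
      sample(setdiff(proteome$accession, a), 1L)
    }, character(1))
  }
  peps$proteins <- ifelse(is.na(partner), peps$accession,
                          paste(peps$accession, partner, sep = ";"))

  p_detect <- if (config$dropout_enabled) {
    stats::plogis(config$dropout_slope *
                    (log10(peps$true_fmol) - log10(config$dropout_midpoint_fmol)))
  } else {
    rep(1, n_pep)
  }
  lambda <- config$sc_rate_per_fmol * peps$true_fmol

  samples <- sprintf("S%02d", seq_len(config$n_samples))
  purrr::map(samples, function(s) {
    detected <- runif(n_pep) < p_detect
    n <- sum(detected)
    if (n == 0L) return(NULL)
    lam <- lambda[detected]
    # Poisson truncated to >= 1, by inverse-CDF conditioning
    sc <- qpois(runif(n, ppois(0, lam), 1), lam)
    sc[sc < 1L] <- 1L
    xic <- config$xic_gain * peps$true_fmol[detected] *
      10^(peps$efficiency[detected] + rnorm(n, 0, config$noise_sigma))
    rt <- abs(rnorm(n, 3, 2))
    rt[peps$rt_outlier[detected]] <- runif(sum(peps$rt_outlier[detected]),
                                           21, 60)
    tibble::tibble(
      sample_id = s,
      peptide_seq = peps$peptide_seq[detected],
      proteins = peps$proteins[detected],
      spectral_count = as.integer(sc),
      xic_area = xic,
      rt_sd_seconds = rt
    )
  }) |>
    purrr::list_rbind()
}

#' Validation-spike manifest
#'
#' Four purified proteins spiked at known amounts for validating absolute
#' estimates: insulin (INS) at 51.9 fmol, alpha-lactalbumin (LALBA) at
#' 108.6 fmol, myoglobin (MYG) at 181.8 fmol and ribonuclease A (RNAS1) at
#' 342.6 fmol. The attached sequences are synthetic stand-ins (random
#' tryptic-friendly sequences, fixed across calls), not the biological
#' sequences.
#'
#' @return Tibble `accession`, `expected_fmol`, `role`, `sequence`,
#'   `length_aa`.
#' @export
#' @examples
#' make_validation_spikes()
make_validation_spikes <- function() {
  seqs <- with_local_seed(20220104L, random_sequences(4L, c(110L, 160L)))
  tibble::tibble(
    accession = c("INS", "LALBA", "MYG", "RNAS1"),
    expected_fmol = c(51.9, 108.6, 181.8, 342.6),
    role = "validation_spike",
    sequence = seqs,
    length_aa = nchar(seqs)
  )
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a complete annotated dataset
#'
#' Convenience wrapper: [simulate_proteome()], [annotate_proteins()] (with
#' the config's digest parameters) and [simulate_evidence()] in one call.
#'
#' @param config A [sim_config()] list.
#' @return List with `proteins` (annotated, with `true_fmol`), `evidence`
#'   and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  proteins <- annotate_proteins(simulate_proteome(config), config$digest)
  list(
    proteins = proteins,
    evidence = simulate_evidence(proteins, config),
    config = config
  )
}

#' Write simulated fixtures to disk
#'
#' Writes the FASTA, evidence TSV and standards-manifest TSV of a
#' simulated dataset, in the formats the package readers consume.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_fixtures <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seqs <- Biostrings::AAStringSet(setNames(dataset$proteins$sequence,
                                           dataset$proteins$accession))
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.fasta"))
  readr::write_tsv(dataset$evidence, file.path(dir, "evidence.tsv"))
  dataset$proteins |>
    dplyr::filter(.data$role == "standard") |>
    dplyr::select("accession", "expected_fmol") |>
    readr::write_tsv(file.path(dir, "standards.tsv"))
  invisible(dir)
}
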