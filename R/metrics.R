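#' Coefficient of variation among replicates
#'
#' Per-protein CV (%) of abundance across replicate samples:
#' `100 * sd / mean` with the n-1 sample standard deviation. Proteins
#' present in fewer than two replicates are skipped (a message reports how
#' many).
#'
#' @param abundances Long tibble `accession`, `sample_id` and a value
#'   column.
#' @param value Name of the value column (tidy-eval; default `abundance`).
#' @return Tibble `accession`, `cv_pct`, with attribute `median_cv_pct`
#'   (also returned by `median(out$cv_pct)`).
#' @export
cv_among_replicates <- function(abundances, value = abundance) {
  stopifnot(is.data.frame(abundances))
  if (dplyr::n_distinct(abundances$sample_id) < 2L) {
    abort("at least 2 replicate samples are required")
  }
  per <- abundances |>
    dplyr::filter(!is.na({{ value }})) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      n = dplyr::n(),
      cv_pct = 100 * sd({{ value }}) / mean({{ value }}),
      .groups = "drop"
    )
  skipped <- sum(per$n < 2L)
  if (skipped > 0L) {
    inform(sprintf(
      "skipping %d protein(s) present in fewer than 2 replicates", skipped
    ))
  }
  out <- per |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::select("accession", "cv_pct")
  attr(out, "median_cv_pct") <- median(out$cv_pct)
  out
}

#' Coefficient of variation among proteins, by concentration decade
#'
#' Groups standard proteins by the order of magnitude of their expected
#' amount (`floor(log10(expected fmol))`), computes the CV (%) across the
#' proteins of each decade within each sample, summarizes each decade by
#' its median across samples, and reports the median over decades. Decades
#' with fewer than two proteins in a sample are skipped (a message reports
#' how many sample-decade groups).
#'
#' @param abundances Long tibble `accession`, `sample_id` and a value
#'   column for the standards.
#' @param expected Tibble `accession`, `expected_fmol`.
#' @param value Name of the value column (tidy-eval; default `abundance`).
#' @return Tibble `decade`, `cv_pct` (median across samples), with
#'   attribute `median_cv_pct` = median over decades.
#' @export
cv_among_proteins <- function(abundances, expected, value = abundance) {
  stopifnot(is.data.frame(abundances), is.data.frame(expected))
  dat <- abundances |>
    dplyr::filter(!is.na({{ value }})) |>
    dplyr::inner_join(
      dplyr::select(expected, "accession", "expected_fmol"), by = "accession"
    ) |>
    dplyr::mutate(decade = floor(log10(.data$expected_fmol)))
  per_group <- dat |>
    dplyr::group_by(.data$sample_id, .data$decade) |>
    dplyr::summarise(
      n = dplyr::n(),
      cv_pct = 100 * sd({{ value }}) / mean({{ value }}),
      .groups = "drop"
    )
  skipped <- sum(per_group$n < 2L)
  if (skipped > 0L) {
    inform(sprintf(
      "skipping %d sample-decade group(s) with fewer than 2 proteins", skipped
    ))
  }
  out <- per_group |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(cv_pct = median(.data$cv_pct), .groups = "drop")
  if (nrow(out) == 0L) abort("no decade has 2 or more quantified standards")
  attr(out, "median_cv_pct") <- median(out$cv_pct)
  out
}

#' Bootstrap absolute error against the spiked standards
#'
#' The absolute error of a (protein, sample) estimate is
#' `100 * |estimated - expected| / expected` (%). The pooled errors are
#' resampled with replacement `B` times; the median of each resample forms
#' the bootstrap distribution of the median absolute error.
#'
#' @param estimates Long tibble `accession`, `sample_id`, `fmol`.
#' @param expected Tibble `accession`, `expected_fmol` (all positive).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @return A list of class `boot_error`: `errors` (per protein-sample
#'   tibble), `median_error_pct`, `ci` (2.5-97.5 percentile interval of
#'   the bootstrap medians) and `boot_medians`.
#' @export
bootstrap_absolute_error <- function(estimates, expected, B = 1000,
                                     seed = 1L) {
  stopifnot(B >= 1)
  errors <- absolute_errors(estimates, expected)
  if (nrow(errors) == 0L) abort("no standard has both an estimate and an expected value")
  set.seed(seed)
  n <- nrow(errors)
  boot_medians <- vapply(
    seq_len(B),
    \(i) median(errors$error_pct[sample.int(n, n, replace = TRUE)]),
    numeric(1)
  )
  structure(
    list(
      errors = errors,
      median_error_pct = median(errors$error_pct),
      ci = unname(quantile(boot_medians, c(0.025, 0.975))),
      boot_medians = boot_medians
    ),
    class = "boot_error"
  )
}

absolute_errors <- function(estimates, expected) {
  stopifnot(is.data.frame(estimates), is.data.frame(expected))
  if (any(expected$expected_fmol <= 0)) {
    abort("expected_fmol must be positive to compute relative errors")
  }
  estimates |>
    dplyr::inner_join(
      dplyr::select(expected, "accession", "expected_fmol"), by = "accession"
    ) |>
    dplyr::filter(!is.na(.data$fmol)) |>
    dplyr::mutate(
      error_pct = 100 * abs(.data$fmol - .data$expected_fmol) / .data$expected_fmol
    )
}

#' @export
print.boot_error <- function(x, ...) {
  cat(sprintf(
    "<bootstrap absolute error: median %.2f%% (95%% CI %.2f-%.2f%%), n = %d, B = %d>\n",
    x$median_error_pct, x$ci[1], x$ci[2], nrow(x$errors), length(x$boot_medians)
  ))
  invisible(x)
}

#' @rdname bootstrap_absolute_error
#' @param x A `boot_error` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.boot_error <- function(x, ...) {
  tibble::tibble(
    median_error_pct = x$median_error_pct,
    ci_low = x$ci[1], ci_high = x$ci[2],
    n_errors = nrow(x$errors), B = length(x$boot_medians)
  )
}

#' Total mass ratio
#'
#' Ratio of the estimated total mass of the quantified proteins to the
#' known injected mass: `sum_i conc_i * MW_i / total_mass`, per sample.
#' With a `subset` of accessions (e.g. the spiked standards),
#' `total_mass_g` should be the subset's known injected mass.
#'
#' @param absolute Long tibble `accession`, `sample_id`, `conc_mol` (or
#'   `fmol`, converted at 1 fmol = 1e-15 mol).
#' @param proteins Annotated protein tibble with `mw_g_per_mol`.
#' @param total_mass_g Known injected mass (g); single number or named by
#'   sample.
#' @param subset Optional character vector of accessions to restrict to.
#' @return Tibble `sample_id`, `mass_ratio`.
#' @export
mass_ratio <- function(absolute, proteins, total_mass_g, subset = NULL) {
  stopifnot(is.data.frame(absolute), all(total_mass_g > 0))
  dat <- absolute
  if (!"conc_mol" %in% names(dat)) {
    if (!"fmol" %in% names(dat)) {
      abort("`absolute` must have a `conc_mol` or `fmol` column")
    }
    dat <- dplyr::mutate(dat, conc_mol = .data$fmol * 1e-15)
  }
  samples <- unique(dat$sample_id)
  if (!is.null(subset)) {
    dat <- dplyr::filter(dat, .data$accession %in% subset)
  }
  dat <- dat |>
    dplyr::filter(!is.na(.data$conc_mol)) |>
    dplyr::left_join(
      dplyr::select(proteins, "accession", "mw_g_per_mol"), by = "accession"
    )
  if (any(is.na(dat$mw_g_per_mol))) {
    abort(sprintf(
      "missing molecular weight for protein(s): %s",
      paste(unique(dat$accession[is.na(dat$mw_g_per_mol)]), collapse = ", ")
    ))
  }
  mass_of <- function(sample_id) {
    if (length(total_mass_g) == 1L && is.null(names(total_mass_g))) {
      rep(total_mass_g, length(sample_id))
    } else {
      unname(total_mass_g[sample_id])
    }
  }
  out <- dat |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mass_ratio = sum(.data$conc_mol * .data$mw_g_per_mol), .groups = "drop"
    ) |>
    dplyr::mutate(mass_ratio = .data$mass_ratio / mass_of(.data$sample_id))
  # samples whose every protein fell outside the subset contribute ratio 0
  missing <- setdiff(samples, out$sample_id)
  if (length(missing) > 0L) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(sample_id = missing, mass_ratio = 0)
    )
  }
  dplyr::arrange(out, .data$sample_id)
}

#' Absolute error against proteins spiked at known amounts
#'
#' Same error formula as [bootstrap_absolute_error()] but without
#' resampling, for validation spikes of known fmol. Manifest proteins
#' missing from the estimates are reported absent with a warning; the
#' median is taken over the remaining spikes.
#'
#' @param estimates Long tibble `accession`, `sample_id`, `fmol`.
#' @param manifest Tibble `accession`, `expected_fmol` of the validation
#'   spikes.
#' @return Tibble `accession`, `sample_id`, `fmol`, `expected_fmol`,
#'   `error_pct`, with attribute `median_error_pct`.
#' @export
error_vs_known <- function(estimates, manifest) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0L) abort("the validation-spike manifest is empty")
  errors <- absolute_errors(estimates, manifest)
  absent <- setdiff(manifest$accession, errors$accession)
  if (length(absent) > 0L) {
    warn(sprintf(
      "validation spike(s) not quantified: %s", paste(absent, collapse = ", ")
    ))
  }
  if (nrow(errors) == 0L) abort("no validation spike was quantified")
  out <- dplyr::select(errors, "accession", "sample_id", "fmol",
                       "expected_fmol", "error_pct")
  attr(out, "median_error_pct") <- median(out$error_pct)
  out
}

#' Enumerate quantification techniques
#'
#' Full Cartesian product of quantification methods, transformation
#' strategies and experimental conditions, in deterministic order (methods
#' outermost, then strategies, then conditions).
#'
#' @param methods,strategies,conditions Non-empty character vectors.
#' @return Tibble `method`, `strategy`, `condition`; its row count is the
#'   number of technique-dataset combinations.
#' @export
#' @examples
#' nrow(enumerate_techniques(quant_methods(), c("UPS2", "TPA"), "standard"))
enumerate_techniques <- function(methods, strategies, conditions) {
  stopifnot(length(methods) > 0, length(strategies) > 0,
            length(conditions) > 0)
  tidyr::expand_grid(
    method = methods, strategy = strategies, condition = conditions
  )
}
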