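check_proteins_present <- function(accessions, proteins) {
  missing <- setdiff(accessions, proteins$accession)
  if (length(missing) > 0L) {
    abort(sprintf(
      "protein(s) in evidence but not in metadata: %s",
      paste(missing, collapse = ", ")
    ))
  }
}

new_rel_abundance <- function(tbl, method) {
  out <- tibble::as_tibble(tbl)
  attr(out, "method") <- method
  attr(out, "unit") <- "unitless"
  class(out) <- c("rel_abundance", class(out))
  out
}

#' @export
print.rel_abundance <- function(x, ...) {
  cat(sprintf("<rel_abundance: method=%s, unit=%s>\n",
              attr(x, "method"), attr(x, "unit")))
  NextMethod()
}

# Spectral-count evidence expanded to one row per (sample, protein, peptide);
# expects shared peptides already removed for SC methods.
expand_by_protein <- function(evidence) {
  evidence |>
    tidyr::separate_longer_delim("proteins", delim = ";") |>
    dplyr::rename(accession = "proteins")
}

#' Protein abundance index (PAI)
#'
#' Number of distinct observed peptide sequences (spectral count > 0) per
#' protein and sample, divided by the protein's observable-peptide count.
#' Proteins with no observable tryptic peptide cannot be indexed and are
#' reported absent (`NA`) with a warning.
#'
#' @param evidence Evidence tibble, filtered for a spectral-counting method
#'   (see [filter_evidence()]).
#' @param proteins Annotated protein tibble ([annotate_proteins()]).
#' @return Long tibble `accession`, `sample_id`, `abundance`.
#' @export
pai_index <- function(evidence, proteins) {
  ev <- expand_by_protein(evidence)
  check_proteins_present(ev$accession, proteins)
  out <- ev |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(
      n_obs = dplyr::n_distinct(.data$peptide_seq[.data$spectral_count > 0]),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(proteins, "accession", "n_observable"), by = "accession"
    ) |>
    dplyr::mutate(
      abundance = ifelse(.data$n_observable > 0,
                         .data$n_obs / .data$n_observable, NA_real_)
    )
  n_bad <- sum(out$n_observable == 0 & out$n_obs > 0)
  if (n_bad > 0L) {
    warn(sprintf(
      "%d protein-sample value(s) undefined: no observable peptide (PAI denominator 0)",
      n_bad
    ))
  }
  dplyr::select(out, "accession", "sample_id", "abundance")
}

#' Exponentially modified PAI (emPAI)
#'
#' `10^PAI - 1`, elementwise on a PAI table.
#'
#' @param pai Output of [pai_index()].
#' @return Long tibble with `abundance` transformed.
#' @export
empai_index <- function(pai) {
  dplyr::mutate(pai, abundance = 10^.data$abundance - 1)
}

#' Spectral abundance factor (SAF)
#'
#' Summed spectral count of a protein's peptides in a sample divided by the
#' protein's length in residues.
#'
#' @inheritParams pai_index
#' @return Long tibble `accession`, `sample_id`, `abundance`.
#' @export
saf_index <- function(evidence, proteins) {
  ev <- expand_by_protein(evidence)
  check_proteins_present(ev$accession, proteins)
  ev |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(sc = sum(.data$spectral_count), .groups = "drop") |>
    dplyr::left_join(
      dplyr::select(proteins, "accession", "length_aa"), by = "accession"
    ) |>
    dplyr::mutate(abundance = .data$sc / .data$length_aa) |>
    dplyr::select("accession", "sample_id", "abundance")
}

#' Normalized spectral abundance factor (NSAF)
#'
#' SAF values normalized to sum to 1 within each sample over all quantified
#' non-contaminant proteins:
#' `NSAF_i = (SC/L)_i / sum_j (SC/L)_j`. Contaminant-flagged proteins are
#' excluded from the normalizing sum (they still receive a value relative
#' to the sample's non-contaminant total).
#'
#' @param saf Output of [saf_index()].
#' @param proteins Protein tibble; a `role` column marks contaminants.
#' @return Long tibble `accession`, `sample_id`, `abundance` summing to 1
#'   per sample over non-contaminant proteins.
#' @export
nsaf_index <- function(saf, proteins) {
  contam <- contaminant_accessions(proteins)
  out <- saf |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      total = sum(.data$abundance[!.data$accession %in% contam], na.rm = TRUE)
    ) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    abort(sprintf(
      "sample '%s' has no spectral counts to normalize (all-zero SAF)",
      out$sample_id[which(out$total <= 0)[1]]
    ))
  }
  out |>
    dplyr::mutate(abundance = .data$abundance / .data$total) |>
    dplyr::select("accession", "sample_id", "abundance")
}

contaminant_accessions <- function(proteins) {
  if (!"role" %in% names(proteins)) return(character(0))
  proteins$accession[!is.na(proteins$role) & proteins$role == "contaminant"]
}

#' Preprocess XIC intensities
#'
#' Log10-transforms peptide XIC areas and applies median-ratio
#' normalization in log space against a reference sample: for each sample,
#' the median of (log10 intensity - reference log10 intensity) over
#' peptides shared with the reference is subtracted. Rows without an XIC
#' area are dropped (a message reports how many).
#'
#' @param evidence Evidence tibble filtered for an XIC method.
#' @param reference_sample Sample id used as normalization reference;
#'   default the first sample appearing in the evidence.
#' @return Tibble `sample_id`, `peptide_seq`, `proteins`, `log10_intensity`
#'   (normalized) and `intensity` (linear scale, `10^log10_intensity`).
#' @export
preprocess_xic <- function(evidence, reference_sample = NULL) {
  ev <- tibble::as_tibble(evidence)
  n_missing <- sum(is.na(ev$xic_area))
  if (n_missing > 0L) {
    inform(sprintf("dropping %d peptide row(s) without an XIC area", n_missing))
    ev <- ev[!is.na(ev$xic_area), , drop = FALSE]
  }
  if (nrow(ev) == 0L) abort("no XIC areas available after filtering")
  reference_sample <- reference_sample %||% ev$sample_id[[1]]
  if (!reference_sample %in% ev$sample_id) {
    abort(sprintf("reference sample '%s' not present in evidence",
                  reference_sample))
  }
  ev$log10_raw <- log10(ev$xic_area)
  ref <- ev |>
    dplyr::filter(.data$sample_id == reference_sample) |>
    dplyr::group_by(.data$peptide_seq) |>
    dplyr::summarise(log10_ref = median(.data$log10_raw), .groups = "drop")
  shifts <- ev |>
    dplyr::inner_join(ref, by = "peptide_seq") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      shift = median(.data$log10_raw - .data$log10_ref), .groups = "drop"
    )
  no_common <- setdiff(unique(ev$sample_id), shifts$sample_id)
  if (length(no_common) > 0L) {
    abort(sprintf(
      "sample(s) share no peptides with reference '%s': %s",
      reference_sample, paste(no_common, collapse = ", ")
    ))
  }
  ev |>
    dplyr::left_join(shifts, by = "sample_id") |>
    dplyr::mutate(
      log10_intensity = .data$log10_raw - .data$shift,
      intensity = 10^.data$log10_intensity
    ) |>
    dplyr::select("sample_id", "peptide_seq", "proteins",
                  "log10_intensity", "intensity")
}

#' SUMnorm intensity index
#'
#' Sum of a protein's normalized peptide intensities (linear scale) divided
#' by the protein's residue count.
#'
#' @param xic Output of [preprocess_xic()].
#' @param proteins Annotated protein tibble.
#' @return Long tibble `accession`, `sample_id`, `abundance`.
#' @export
sumnorm_index <- function(xic, proteins) {
  ev <- expand_by_protein(xic)
  check_proteins_present(ev$accession, proteins)
  ev |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop") |>
    dplyr::left_join(
      dplyr::select(proteins, "accession", "length_aa"), by = "accession"
    ) |>
    dplyr::mutate(abundance = .data$total / .data$length_aa) |>
    dplyr::select("accession", "sample_id", "abundance")
}

#' TOP3 intensity index
#'
#' Mean of the three most intense normalized peptides of a protein (linear
#' scale). With exactly two peptides the mean of two is used; a message
#' reports how many protein-sample pairs fell below three peptides.
#'
#' @inheritParams sumnorm_index
#' @return Long tibble `accession`, `sample_id`, `abundance`.
#' @export
top3_index <- function(xic, proteins) {
  ev <- expand_by_protein(xic)
  check_proteins_present(ev$accession, proteins)
  out <- ev |>
    dplyr::arrange(
      .data$accession, .data$sample_id,
      dplyr::desc(.data$intensity), .data$peptide_seq
    ) |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(
      abundance = mean(head(.data$intensity, 3L)),
      n_pep = dplyr::n(),
      .groups = "drop"
    )
  n_short <- sum(out$n_pep < 3L)
  if (n_short > 0L) {
    inform(sprintf(
      "%d protein-sample value(s) computed from fewer than 3 peptides", n_short
    ))
  }
  dplyr::select(out, "accession", "sample_id", "abundance")
}

#' iBAQ intensity index
#'
#' Sum of all normalized peptide intensities mapped to a protein (a shared
#' peptide's full intensity counts for every protein it maps to), divided
#' by the protein's observable-peptide count. Proteins without observable
#' peptides are reported absent with a warning.
#'
#' @inheritParams sumnorm_index
#' @return Long tibble `accession`, `sample_id`, `abundance`.
#' @export
ibaq_index <- function(xic, proteins) {
  ev <- expand_by_protein(xic)
  check_proteins_present(ev$accession, proteins)
  out <- ev |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop") |>
    dplyr::left_join(
      dplyr::select(proteins, "accession", "n_observable"), by = "accession"
    ) |>
    dplyr::mutate(
      abundance = ifelse(.data$n_observable > 0,
                         .data$total / .data$n_observable, NA_real_)
    )
  n_bad <- sum(out$n_observable == 0)
  if (n_bad > 0L) {
    warn(sprintf(
      "%d protein-sample value(s) undefined: no observable peptide (iBAQ denominator 0)",
      n_bad
    ))
  }
  dplyr::select(out, "accession", "sample_id", "abundance")
}

#' Quantify relative protein abundance
#'
#' Applies the method-appropriate evidence filter chain
#' ([filter_evidence()]; plus [preprocess_xic()] for intensity methods) and
#' computes one of the seven relative abundance indices for every protein
#' and sample.
#'
#' @param evidence Raw evidence tibble.
#' @param proteins Annotated protein tibble ([annotate_proteins()]).
#' @param method One of [quant_methods()].
#' @param filter_params An [evidence_filter_params()] list.
#' @param reference_sample Reference sample for XIC normalization
#'   (default: first sample in the evidence).
#' @return A `rel_abundance` tibble: `accession`, `sample_id`, `abundance`,
#'   with `method` and `unit` attributes.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_background = 20, n_samples = 2))
#' nsaf <- quantify(sim$evidence, sim$proteins, "NSAF")
#' dplyr::count(nsaf, sample_id, wt = abundance)  # sums to 1 per sample
quantify <- function(evidence, proteins, method,
                     filter_params = evidence_filter_params(),
                     reference_sample = NULL) {
  check_method(method)
  ev <- filter_evidence(evidence, method, filter_params)
  values <- switch(
    method,
    PAI = pai_index(ev, proteins),
    emPAI = empai_index(pai_index(ev, proteins)),
    SAF = saf_index(ev, proteins),
    NSAF = nsaf_index(saf_index(ev, proteins), proteins),
    SUMnorm = sumnorm_index(preprocess_xic(ev, reference_sample), proteins),
    TOP3 = top3_index(preprocess_xic(ev, reference_sample), proteins),
    iBAQ = ibaq_index(preprocess_xic(ev, reference_sample), proteins)
  )
  new_rel_abundance(values, method)
}
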