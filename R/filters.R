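split_accessions <- function(proteins) strsplit(proteins, ";", fixed = TRUE)

n_mapped_proteins <- function(proteins) lengths(split_accessions(proteins))

#' Filter peptide evidence for a quantification method
#'
#' Applies, in order and per sample:
#' 1. for XIC methods only, removal of rows whose retention-time standard
#'    deviation exceeds `rt_sd_max_seconds` (absent values pass);
#' 2. removal of shared peptides (mapping to more than one protein) for
#'    every method except iBAQ;
#' 3. for XIC methods, removal of all evidence of proteins retaining fewer
#'    than two distinct peptide sequences (spectral-counting methods keep
#'    proteins with a single peptide).
#'
#' When shared peptides are retained (iBAQ), a row is removed by step 3
#' only if *every* protein it maps to falls below the minimum, so the
#' shared-peptide count is unchanged by filtering. The filter is
#' idempotent and preserves row order.
#'
#' @param evidence Evidence tibble (see [read_evidence_table()]).
#' @param method One of [quant_methods()].
#' @param params An [evidence_filter_params()] list.
#' @return The filtered evidence tibble.
#' @export
filter_evidence <- function(evidence, method,
                            params = evidence_filter_params()) {
  check_method(method)
  stopifnot(is.data.frame(evidence))
  xic <- is_xic_method(method)
  ev <- tibble::as_tibble(evidence)

  if (xic) {
    keep <- is.na(ev$rt_sd_seconds) | ev$rt_sd_seconds <= params$rt_sd_max_seconds
    ev <- ev[keep, , drop = FALSE]
  }

  drop_shared <- params$drop_shared %||% (method != "iBAQ")
  if (drop_shared) {
    ev <- ev[n_mapped_proteins(ev$proteins) == 1L, , drop = FALSE]
  }

  min_pep <- params$min_peptides_per_protein %||% (if (xic) 2L else 1L)
  if (min_pep > 1L && nrow(ev) > 0L) {
    long <- ev |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      tidyr::separate_longer_delim("proteins", delim = ";")
    grouping <- if (params$per_sample) c("sample_id", "proteins") else "proteins"
    counts <- long |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::summarise(
        n_pep = dplyr::n_distinct(.data$peptide_seq), .groups = "drop"
      )
    keep_rows <- long |>
      dplyr::left_join(counts, by = grouping) |>
      dplyr::group_by(.data$.row) |>
      dplyr::summarise(keep = any(.data$n_pep >= min_pep), .groups = "drop")
    ev <- ev[sort(keep_rows$.row[keep_rows$keep]), , drop = FALSE]
  }
  ev
}
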