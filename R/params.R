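#' Evidence filter parameters
#'
#' Settings for the peptide-evidence filters applied before quantification:
#' the retention-time reproducibility cutoff, the shared-peptide rule and
#' the minimum number of distinct peptides a protein must retain.
#'
#' Defaults reproduce the reference workflow: peptides whose retention-time
#' standard deviation exceeds 20 s are discarded for the XIC methods; shared
#' peptides (mapping to more than one protein) are removed for every method
#' except iBAQ; XIC methods require at least two distinct peptides per
#' protein, spectral-counting methods one.
#'
#' @param rt_sd_max_seconds Positive cutoff on the retention-time standard
#'   deviation in seconds. Rows above it are removed for XIC methods.
#' @param drop_shared `NULL` (decide from the method: keep shared peptides
#'   only for iBAQ) or a logical overriding that rule.
#' @param min_peptides_per_protein `NULL` (2 for XIC methods, 1 for
#'   spectral-counting methods) or a positive integer override.
#' @param per_sample Evaluate the minimum-peptide rule within each sample
#'   (`TRUE`, default) or across the whole experiment.
#'
#' @return A list of class `evidence_filter_params`.
#' @export
#' @examples
#' evidence_filter_params()
evidence_filter_params <- function(rt_sd_max_seconds = 20,
                                   drop_shared = NULL,
                                   min_peptides_per_protein = NULL,
                                   per_sample = TRUE) {
  stopifnot(is.numeric(rt_sd_max_seconds), rt_sd_max_seconds > 0)
  if (!is.null(min_peptides_per_protein)) {
    stopifnot(min_peptides_per_protein >= 1)
  }
  structure(
    list(
      rt_sd_max_seconds = rt_sd_max_seconds,
      drop_shared = drop_shared,
      min_peptides_per_protein = min_peptides_per_protein,
      per_sample = isTRUE(per_sample)
    ),
    class = "evidence_filter_params"
  )
}

#' In-silico digestion parameters
#'
#' @param missed_cleavages Non-negative number of internal missed cleavage
#'   sites allowed (0 for observable-peptide counting; 1 matches a typical
#'   search-engine setting).
#' @param min_peptide_len,max_peptide_len Length window (residues) defining
#'   an *observable* peptide; defaults 7-30 aa follow common emPAI/iBAQ
#'   practice.
#' @param proline_rule No cleavage C-terminal to K/R when the next residue
#'   is proline (default `TRUE`, standard trypsin specificity).
#'
#' @return A list of class `digest_params`.
#' @export
#' @examples
#' digest_params(missed_cleavages = 1)
digest_params <- function(missed_cleavages = 0L,
                          min_peptide_len = 7L,
                          max_peptide_len = 30L,
                          proline_rule = TRUE) {
  stopifnot(
    missed_cleavages >= 0,
    min_peptide_len >= 1,
    min_peptide_len <= max_peptide_len
  )
  structure(
    list(
      missed_cleavages = as.integer(missed_cleavages),
      min_peptide_len = as.integer(min_peptide_len),
      max_peptide_len = as.integer(max_peptide_len),
      proline_rule = isTRUE(proline_rule)
    ),
    class = "digest_params"
  )
}
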