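#' Average residue masses
#'
#' Average (not monoisotopic) masses of the 20 standard amino-acid residues
#' in g/mol, i.e. the free amino-acid mass minus one water. Summing residue
#' masses and adding one water (18.0153 g/mol) gives the average molecular
#' weight of a peptide or protein, the `MW` used by the total protein
#' approach and the mass-ratio metric.
#'
#' @return Named numeric vector of length 20 (one-letter residue codes).
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function() .AA_RESIDUE_MASS

.AA_RESIDUE_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MASS <- 18.0153

check_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort(sprintf("`%s` must be a single non-empty amino-acid string", what))
  }
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", sequence)
  if (bad > 0L) {
    abort(sprintf(
      "invalid residue '%s' at position %d of %s",
      substr(sequence, bad, bad), bad, what
    ))
  }
  invisible(sequence)
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to every K or R (not before P when
#' the proline rule is on) and enumerates all peptides with up to
#' `missed_cleavages` internal missed sites. Peptides are returned
#' missed-cleavage-major: all fully cleaved fragments N-to-C first, then all
#' single-miss joins N-to-C, and so on.
#'
#' @param sequence Amino-acid string (standard 20-letter alphabet).
#' @param params A [digest_params()] list.
#' @return Character vector of peptide sequences.
#' @export
#' @examples
#' tryptic_digest("AAAAAAAKCCCCCCCRDDDDDDD")
#' tryptic_digest("GGKGG", digest_params(missed_cleavages = 1))
tryptic_digest <- function(sequence, params = digest_params()) {
  check_sequence(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_after <- res %in% c("K", "R")
  if (params$proline_rule && n > 1L) {
    cut_after[-n] <- cut_after[-n] & res[-1L] != "P"
  }
  cut_after[n] <- FALSE
  ends <- c(which(cut_after), n)
  starts <- c(1L, head(ends, -1L) + 1L)
  frags <- substring(sequence, starts, ends)
  k <- length(frags)
  out <- character(0)
  for (mc in 0:min(params$missed_cleavages, k - 1L)) {
    i <- seq_len(k - mc)
    out <- c(out, substring(sequence, starts[i], ends[i + mc]))
  }
  out
}

#' Count observable tryptic peptides
#'
#' Number of distinct in-silico tryptic peptides of a sequence whose length
#' falls within the observable window of `params`. This is the expected
#' ("observable") peptide count used as the denominator of PAI and iBAQ.
#'
#' @inheritParams tryptic_digest
#' @return Non-negative integer.
#' @export
#' @examples
#' count_observable("AAAAAAAKCCCCCCCRDDDDDDD")  # 3
count_observable <- function(sequence, params = digest_params()) {
  peps <- unique(tryptic_digest(sequence, params))
  len <- nchar(peps)
  sum(len >= params$min_peptide_len & len <= params$max_peptide_len)
}

#' Average molecular mass of a peptide or protein
#'
#' Sum of the average residue masses ([residue_masses()]) plus one water
#' (18.0153 g/mol).
#'
#' @param sequence Amino-acid string.
#' @return Mass in g/mol.
#' @export
#' @examples
#' average_mass("GG")
average_mass <- function(sequence) {
  check_sequence(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(.AA_RESIDUE_MASS[res]) + .WATER_MASS
}

#' Annotate proteins with sequence-derived quantities
#'
#' Fills `length_aa`, `mw_g_per_mol` and `n_observable` for every protein
#' from its sequence; all other columns are passed through unchanged. The
#' operation is idempotent.
#'
#' @param proteins Tibble with at least `accession` and `sequence` columns.
#' @param params A [digest_params()] list controlling the observable window.
#' @return The input tibble with `length_aa`, `mw_g_per_mol` and
#'   `n_observable` (re)computed.
#' @export
annotate_proteins <- function(proteins, params = digest_params()) {
  stopifnot(is.data.frame(proteins))
  if (!all(c("accession", "sequence") %in% names(proteins))) {
    abort("`proteins` must have `accession` and `sequence` columns")
  }
  if (any(is.na(proteins$sequence))) {
    abort("every protein must have a sequence to be annotated")
  }
  proteins |>
    dplyr::mutate(
      length_aa = nchar(.data$sequence),
      mw_g_per_mol = purrr::map_dbl(.data$sequence, average_mass),
      n_observable = purrr::map_int(
        .data$sequence, \(s) as.integer(count_observable(s, params))
      )
    )
}
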