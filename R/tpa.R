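#' Total protein approach (TPA) transformation
#'
#' Converts relative abundances to molar concentrations by assuming the
#' summed signal of all quantified proteins represents the total injected
#' protein mass:
#' `conc_i = (rel_i / sum_j rel_j) * total_mass / MW_i` (mol), also
#' reported in fmol. Contaminant-flagged proteins are excluded from the
#' total and from the output. By construction
#' `sum_i conc_i * MW_i = total_mass` in every sample.
#'
#' @param rel Long abundance tibble (`accession`, `sample_id`,
#'   `abundance`).
#' @param proteins Annotated protein tibble with `mw_g_per_mol`.
#' @param total_mass_g Total injected digested-protein mass in grams:
#'   a single number, or a vector named by sample id.
#' @return Tibble `accession`, `sample_id`, `share`, `conc_mol`, `fmol`
#'   with attributes `strategy = "TPA"`, `unit = "fmol"`.
#' @export
tpa_transform <- function(rel, proteins, total_mass_g) {
  stopifnot(is.data.frame(rel), is.data.frame(proteins),
            all(total_mass_g > 0))
  contam <- contaminant_accessions(proteins)
  dat <- rel |>
    dplyr::filter(!.data$accession %in% contam, !is.na(.data$abundance)) |>
    dplyr::left_join(
      dplyr::select(proteins, "accession", "mw_g_per_mol"), by = "accession"
    )
  missing_meta <- unique(dat$accession[is.na(dat$mw_g_per_mol)])
  if (length(missing_meta) > 0L) {
    abort(sprintf(
      "missing molecular weight for protein(s): %s",
      paste(missing_meta, collapse = ", ")
    ))
  }
  mass_of <- function(sample_id) {
    if (length(total_mass_g) == 1L && is.null(names(total_mass_g))) {
      rep(total_mass_g, length(sample_id))
    } else {
      if (!all(sample_id %in% names(total_mass_g))) {
        abort("`total_mass_g` must be named by sample id or be a single number")
      }
      unname(total_mass_g[sample_id])
    }
  }
  out <- dat |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(share = .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      conc_mol = .data$share * mass_of(.data$sample_id) / .data$mw_g_per_mol,
      fmol = .data$conc_mol * 1e15
    ) |>
    dplyr::select("accession", "sample_id", "share", "conc_mol", "fmol")
  attr(out, "method") <- attr(rel, "method") %||% "none"
  attr(out, "strategy") <- "TPA"
  attr(out, "unit") <- "fmol"
  out
}
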