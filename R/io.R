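#' Read protein sequences from FASTA
#'
#' Reads a protein FASTA file into a protein tibble. The accession is the
#' first whitespace-delimited token of each header. Sequence-derived columns
#' (`mw_g_per_mol`, `n_observable`) are left to [annotate_proteins()].
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `accession`, `sequence`, `length_aa`, in file
#'   order.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    abort(sprintf("FASTA file is empty: %s", path))
  }
  acc <- sub("\\s.*$", "", names(seqs))
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicate accession(s) in FASTA: %s", paste(dup, collapse = ", ")
    ))
  }
  seq_chr <- as.character(seqs)
  for (i in seq_along(seq_chr)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seq_chr[[i]])
    if (bad > 0L) {
      abort(sprintf(
        "non-amino-acid character '%s' in record '%s' at position %d",
        substr(seq_chr[[i]], bad, bad), acc[[i]], bad
      ))
    }
  }
  tibble::tibble(
    accession = acc,
    sequence = unname(seq_chr),
    length_aa = nchar(unname(seq_chr))
  )
}

#' Read a peptide evidence table
#'
#' Reads tab-separated peptide-level evidence with the fixed column set
#' `sample_id`, `peptide_seq`, `proteins` (semicolon-joined accessions),
#' `spectral_count`, `xic_area`, `rt_sd_seconds`. Empty `xic_area` /
#' `rt_sd_seconds` cells become `NA` ("absent"); row order is preserved.
#'
#' @param path Path to the TSV file.
#' @return Tibble of evidence rows.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("evidence file not found: %s", path))
  required <- c("sample_id", "peptide_seq", "proteins", "spectral_count",
                "xic_area", "rt_sd_seconds")
  header <- names(readr::read_tsv(
    path, n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    abort(sprintf(
      "evidence table is missing required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  ev <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      peptide_seq = readr::col_character(),
      proteins = readr::col_character(),
      spectral_count = readr::col_integer(),
      xic_area = readr::col_double(),
      rt_sd_seconds = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  validate_evidence(ev[required])
}

validate_evidence <- function(ev) {
  bad <- which(!is.na(ev$spectral_count) & ev$spectral_count < 0)
  if (length(bad) > 0L) {
    abort(sprintf("negative spectral_count at row %d", bad[[1]]))
  }
  bad <- which(!is.na(ev$xic_area) & ev$xic_area <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("non-positive xic_area at row %d", bad[[1]]))
  }
  bad <- which(!is.na(ev$rt_sd_seconds) & ev$rt_sd_seconds < 0)
  if (length(bad) > 0L) {
    abort(sprintf("negative rt_sd_seconds at row %d", bad[[1]]))
  }
  bad <- which(ev$spectral_count == 0 & is.na(ev$xic_area))
  if (length(bad) > 0L) {
    abort(sprintf(
      "row %d has neither spectral counts nor an XIC area", bad[[1]]
    ))
  }
  tibble::as_tibble(ev)
}

#' Read a standards manifest
#'
#' A standards manifest is a two-column TSV (`accession`,
#' `expected_fmol`) declaring the spiked amount of each standard protein.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `accession` and `expected_fmol`.
#' @export
read_standards_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  m <- readr::read_tsv(
    path,
    col_types = readr::cols(
      accession = readr::col_character(),
      expected_fmol = readr::col_double()
    ),
    progress = FALSE
  )
  missing <- setdiff(c("accession", "expected_fmol"), names(m))
  if (length(missing) > 0L) {
    abort(sprintf(
      "standards manifest is missing column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(is.na(m$expected_fmol) | m$expected_fmol < 0)) {
    abort("expected_fmol must be non-negative and present for every standard")
  }
  m
}

#' Write / read an abundance table
#'
#' Serializes a long abundance table (`accession`, `sample_id`, one value
#' column) as a wide TSV, one row per protein and one column per sample,
#' preceded by a `#`-commented header recording method, strategy and unit.
#' Values are written with 6 significant digits and round-trip bit-exactly
#' at that precision through [read_abundance_table()].
#'
#' @param table Long tibble with columns `accession`, `sample_id` and the
#'   value column named by `value`.
#' @param path Output file path.
#' @param value Name of the value column (default `"abundance"`).
#' @param method,strategy,unit Metadata recorded in the commented header;
#'   taken from the table's attributes when present.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, value = "abundance",
                                  method = attr(table, "method") %||% "none",
                                  strategy = attr(table, "strategy") %||% "none",
                                  unit = attr(table, "unit") %||% "unitless") {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) abort("cannot write an empty abundance table")
  if (!all(c("accession", "sample_id", value) %in% names(table))) {
    abort("`table` must have `accession`, `sample_id` and the value column")
  }
  wide <- table |>
    dplyr::select("accession", "sample_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = dplyr::all_of(value)
    ) |>
    dplyr::mutate(dplyr::across(
      -"accession", \(x) ifelse(is.na(x), NA_character_, formatC(x, digits = 6, format = "g"))
    ))
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot write to '%s': %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(sprintf("# method=%s strategy=%s unit=%s", method, strategy, unit),
             con)
  writeLines(paste(names(wide), collapse = "\t"), con)
  apply(wide, 1L, \(r) paste(ifelse(is.na(r), "", r), collapse = "\t")) |>
    writeLines(con)
  invisible(path)
}

#' @rdname write_abundance_table
#' @param value_name Name to give the value column on reading.
#' @return For `read_abundance_table()`: the long tibble with `method`,
#'   `strategy` and `unit` attributes restored.
#' @export
read_abundance_table <- function(path, value_name = "abundance") {
  if (!file.exists(path)) abort(sprintf("abundance table not found: %s", path))
  header <- readLines(path, n = 1L)
  meta <- c(method = "none", strategy = "none", unit = "unitless")
  if (startsWith(header, "#")) {
    kv <- stringr::str_match_all(header, "(\\w+)=(\\S+)")[[1]]
    meta[kv[, 2]] <- kv[, 3]
  }
  wide <- readr::read_tsv(path, comment = "#", progress = FALSE,
                          col_types = readr::cols(
                            accession = readr::col_character(),
                            .default = readr::col_double()
                          ))
  out <- wide |>
    tidyr::pivot_longer(-"accession", names_to = "sample_id",
                        values_to = value_name) |>
    dplyr::filter(!is.na(.data[[value_name]]))
  attr(out, "method") <- unname(meta[["method"]])
  attr(out, "strategy") <- unname(meta[["strategy"]])
  attr(out, "unit") <- unname(meta[["unit"]])
  out
}
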