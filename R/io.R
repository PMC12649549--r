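# FASTA and CSV glue.
#
# Peptide libraries travel as FASTA with terminal modifications encoded as
# key=value tokens in the description line (never as sequence characters):
#   >W5K01 nterm=acetyl cterm=amide start_offset=1
#   KWRKWLKWLAKKK

#' Write a peptide table to FASTA
#'
#' @param tbl A peptide table or permutation library.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".fasta")
#' write_peptide_fasta(w5k_library(), tmp)
#' @export
write_peptide_fasta <- function(tbl, path) {
  tbl <- validate_peptides(tbl)
  desc <- paste0("nterm=", tbl$nterm, " cterm=", tbl$cterm)
  if ("start_offset" %in% names(tbl)) {
    desc <- paste0(desc, " start_offset=", tbl$start_offset)
  }
  aa <- Biostrings::AAStringSet(tbl$sequence)
  names(aa) <- paste(tbl$name, desc)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Read a peptide table from FASTA
#'
#' Parses the description line's `key=value` tokens back into the `nterm`,
#' `cterm` and (if present) `start_offset` columns; unannotated records get
#' free termini.
#'
#' @param path FASTA file path.
#' @return A validated peptide tibble.
#' @export
read_peptide_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(paste0("no sequences in ", path))
  headers <- names(aa)
  name <- stringr::str_extract(headers, "^\\S+")
  get_token <- function(key, default) {
    val <- stringr::str_match(headers, paste0("\\b", key, "=(\\S+)"))[, 2]
    ifelse(is.na(val), default, val)
  }
  tbl <- tibble(
    name = name,
    sequence = unname(as.character(aa)),
    nterm = get_token("nterm", "free"),
    cterm = get_token("cterm", "free")
  )
  offset <- suppressWarnings(as.integer(get_token("start_offset", NA)))
  if (any(!is.na(offset))) tbl$start_offset <- offset
  validate_peptides(tbl)
}

#' Write a descriptor table to CSV
#'
#' Writes the output of [peptide_descriptors()] with presentation rounding
#' that matches published peptide-property tables: 2 decimals for `H_mean`,
#' `muH`, `AI` and `II`, 3 for `gravy`, 2 for `MW` (half-up).
#'
#' @param descriptors Output of [peptide_descriptors()].
#' @param path Output CSV path.
#' @return The rounded tibble, invisibly.
#' @export
write_descriptor_csv <- function(descriptors, path) {
  out <- descriptors |>
    mutate(
      across(c("H_mean", "muH", "AI", "II", "MW"), ~ round_half_up(.x, 2)),
      gravy = round_half_up(.data$gravy, 3)
    )
  readr::write_csv(out, path)
  invisible(out)
}

#' Write a therapeutic-index report to CSV
#'
#' @param report Output of [ti_report()].
#' @param path Output CSV path.
#' @param digits Half-up presentation rounding (1 decimal, the convention
#'   of published selectivity tables); `NULL` writes full precision.
#' @return The written tibble, invisibly.
#' @export
write_ti_csv <- function(report, path, digits = 1) {
  if (!is.null(digits)) {
    report <- mutate(report, across(
      c("GM_neg", "GM_pos", "GM_all", "HC10",
        "TI_neg", "TI_pos", "TI_all"),
      ~ round_half_up(.x, digits)
    ))
  }
  readr::write_csv(report, path)
  invisible(report)
}

#' Read a dose-response CSV
#'
#' Expects columns `concentration` and either `response` (already in
#' percent) or a raw-signal column plus blank/full-lysis controls. When
#' `signal`, `blank` and `full` columns are present the percent response is
#' computed with [hemolysis_percent()].
#'
#' @param path CSV path.
#' @return A tibble with `concentration` and `response` (percent), sorted
#'   by concentration.
#' @export
read_dose_response <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!"concentration" %in% names(raw)) {
    abort(paste0(path, ": missing 'concentration' column"))
  }
  if ("response" %in% names(raw)) {
    out <- select(raw, "concentration", "response")
  } else if (all(c("signal", "blank", "full") %in% names(raw))) {
    out <- raw |>
      mutate(response = hemolysis_percent(.data$signal, .data$blank,
                                          .data$full)) |>
      select("concentration", "response")
  } else {
    abort(paste0(path, ": need a 'response' column or ",
                 "'signal'/'blank'/'full' columns"))
  }
  arrange(out, .data$concentration)
}

#' Export helical-wheel coordinates to CSV
#'
#' Writes `(name, residue_index, residue, angle_deg)` rows for external
#' plotting tools.
#'
#' @param wheel Output of [helical_wheel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wheel_csv <- function(wheel, path) {
  readr::write_csv(
    select(as_tibble(wheel), "name", "residue_index", "residue",
           "angle_deg"),
    path
  )
  invisible(path)
}
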