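# Censored MIC panels.
#
# A MIC panel is a long tibble with one row per (peptide, strain) cell:
# columns peptide, strain, gram ("negative"/"positive"), mic (the numeric
# concentration, ug/mL; for censored cells the assay's upper bound) and
# censored (TRUE for ">50"-style cells). Condition metadata columns
# (medium, NaCl_mM, MgCl2_mM, pH) may be carried alongside and are
# preserved by every verb here.

#' Parse censored MIC cells
#'
#' Turns assay-table text like `"3.13"` or `">50"` into a numeric
#' concentration plus a censoring flag. A `">"` prefix marks an
#' upper-censored cell whose numeric part is the assay's highest tested
#' concentration.
#'
#' @param text Character vector of MIC cells.
#' @return A tibble with columns `mic` (numeric, ug/mL) and `censored`
#'   (logical), one row per input cell.
#' @examples
#' parse_mic_cell(c("3.13", ">50"))
#' @export
parse_mic_cell <- function(text) {
  text <- stringr::str_trim(as.character(text))
  censored <- stringr::str_starts(text, ">")
  num_part <- ifelse(censored, stringr::str_sub(text, 2), text)
  mic <- suppressWarnings(as.numeric(num_part))
  bad <- which(is.na(mic) | mic <= 0)
  if (length(bad) > 0) {
    abort(paste0("malformed MIC cell '", text[bad[1]], "' (entry ", bad[1],
                 "): expected a positive number, optionally prefixed '>'"))
  }
  tibble(mic = mic, censored = censored)
}

#' Read a long-format MIC table
#'
#' Reads a CSV/TSV with one row per (peptide, strain) measurement. Required
#' columns: `peptide`, `strain`, `gram`, `mic` (text cells, `">"` prefix
#' allowed). Optional condition columns (`medium`, `NaCl_mM`, `MgCl2_mM`,
#' `pH`) are kept as-is.
#'
#' @param path File path.
#' @return A MIC panel tibble with parsed `mic`/`censored` columns.
#' @export
read_mic_long <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("peptide", "strain", "gram", "mic")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("MIC table ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  parsed <- parse_mic_cell(raw$mic)
  out <- raw
  out$mic <- parsed$mic
  out$censored <- parsed$censored
  .check_gram(out$gram)
  for (col in intersect(c("NaCl_mM", "MgCl2_mM", "pH"), names(out))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  as_tibble(out)
}

#' Read a wide-format MIC table
#'
#' Reads a CSV/TSV shaped like a published MIC table: a `strain` column, a
#' `gram` column, and one column of censored MIC cells per peptide.
#'
#' @param path File path.
#' @return A long MIC panel tibble (`peptide`, `strain`, `gram`, `mic`,
#'   `censored`).
#' @examples
#' panel <- read_mic_wide(system.file("extdata", "w5k_mic_mh.csv",
#'                                    package = "permamp"))
#' @export
read_mic_wide <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("strain", "gram") %in% names(raw))) {
    abort(paste0("wide MIC table ", path,
                 " must have 'strain' and 'gram' columns"))
  }
  long <- tidyr::pivot_longer(raw, -c("strain", "gram"),
                              names_to = "peptide", values_to = "cell")
  parsed <- parse_mic_cell(long$cell)
  out <- select(long, "peptide", "strain", "gram")
  out$mic <- parsed$mic
  out$censored <- parsed$censored
  .check_gram(out$gram)
  out
}

.check_gram <- function(gram) {
  bad <- setdiff(unique(gram), c("negative", "positive"))
  if (length(bad) > 0) {
    abort(paste0("unknown gram label(s): ", paste(bad, collapse = ", "),
                 " (expected 'negative'/'positive')"))
  }
  invisible(gram)
}

#' The published W5K/A9W MIC panel
#'
#' The Mueller-Hinton broth MIC panel for W5K/A9W and its twelve
#' cyclic-permutation derivatives against five Gram-negative and five
#' Gram-positive strains, shipped as a plain-text asset. Cells above the
#' highest tested concentration (50 ug/mL) are censored.
#'
#' @return A long MIC panel tibble (130 rows).
#' @examples
#' dplyr::count(w5k_mic_panel(), gram)
#' @export
w5k_mic_panel <- function() {
  read_mic_wide(system.file("extdata", "w5k_mic_mh.csv",
                            package = "permamp", mustWork = TRUE))
}

#' Published HC10 values for the W5K panel
#'
#' The 10%-hemolysis concentrations for W5K/A9W and derivatives, in ug/mL.
#' Peptides with no detectable hemolysis at the top tested concentration
#' (200 uM = 108.7 ug/mL) carry the cap value and `censored = TRUE`. These
#' are assay inputs (the underlying dose-response raw data are not
#' published), used to assemble the therapeutic-index report.
#'
#' @return A tibble with columns `peptide`, `hc10`, `censored`.
#' @export
w5k_hc10 <- function() {
  readr::read_csv(system.file("extdata", "w5k_hc10.csv",
                              package = "permamp", mustWork = TRUE),
                  show_col_types = FALSE,
                  col_types = readr::cols(peptide = "c", hc10 = "d",
                                          censored = "l"))
}

#' Geometric mean of censored MICs
#'
#' `exp(mean(log(c)))` over the panel values, with censored cells replaced
#' by a fixed substitute concentration (100 ug/mL by convention when no
#' activity is seen at 50 ug/mL).
#'
#' @param mic Numeric vector of concentrations, ug/mL.
#' @param censored Logical vector; `TRUE` marks upper-censored cells.
#' @param censor_substitute Concentration substituted for censored cells.
#' @return A single geometric-mean concentration, ug/mL, full precision.
#' @examples
#' geometric_mean_mic(c(50, 25, 50, 25, 50), c(FALSE, FALSE, TRUE, FALSE, TRUE))
#' @export
geometric_mean_mic <- function(mic, censored = FALSE,
                               censor_substitute = 100) {
  if (length(mic) == 0) abort("geometric_mean_mic: empty MIC vector")
  censored <- rep_len(censored, length(mic))
  if (any(is.na(mic)) || any(mic <= 0)) {
    abort("geometric_mean_mic: MICs must be positive and non-missing")
  }
  val <- ifelse(censored, censor_substitute, mic)
  exp(mean(log(val)))
}

#' Per-peptide geometric means stratified by Gram stain
#'
#' Summarises a MIC panel into the three geometric-mean columns of a
#' selectivity table: Gram-negative strains, Gram-positive strains, and
#' all strains combined.
#'
#' @param panel A long MIC panel tibble.
#' @param censor_substitute Substitute for censored cells, ug/mL.
#' @return A tibble with columns `peptide`, `GM_neg`, `GM_pos`, `GM_all`.
#' @examples
#' gm_by_gram(w5k_mic_panel())
#' @export
gm_by_gram <- function(panel, censor_substitute = 100) {
  .check_gram(panel$gram)
  panel |>
    group_by(.data$peptide) |>
    summarise(
      GM_neg = geometric_mean_mic(
        .data$mic[.data$gram == "negative"],
        .data$censored[.data$gram == "negative"], censor_substitute),
      GM_pos = geometric_mean_mic(
        .data$mic[.data$gram == "positive"],
        .data$censored[.data$gram == "positive"], censor_substitute),
      GM_all = geometric_mean_mic(.data$mic, .data$censored,
                                  censor_substitute),
      .groups = "drop"
    )
}

#' Compare panel MICs to a parent peptide
#'
#' For every (strain, condition) cell, reports the fold-change relative to
#' the parent peptide: `ratio = mic / mic_parent`, `dilution_steps =
#' log2(ratio)`, a `bound` qualifier describing how censoring affects the
#' ratio (`"exact"`, `"lower"` when the peptide's cell is censored,
#' `"upper"` when the parent's is, `"unknown"` when both are), and
#' `at_or_below_parent`, the bolding rule of published permutation MIC
#' tables: `TRUE` when the peptide's MIC is exact and at or below the
#' parent's.
#'
#' @param panel A long MIC panel tibble.
#' @param parent Name of the parent peptide (must be present in the panel).
#' @return The non-parent rows of `panel` with comparison columns appended.
#' @examples
#' cmp <- compare_to_parent(w5k_mic_panel(), "W5K/A9W")
#' table(cmp$at_or_below_parent)
#' @export
compare_to_parent <- function(panel, parent) {
  if (!parent %in% panel$peptide) {
    abort(paste0("parent peptide '", parent, "' not found in panel"))
  }
  keys <- intersect(c("strain", "medium", "NaCl_mM", "MgCl2_mM", "pH"),
                    names(panel))
  parent_tbl <- panel |>
    filter(.data$peptide == parent) |>
    select(all_of(keys), parent_mic = "mic", parent_censored = "censored")
  out <- panel |>
    filter(.data$peptide != parent) |>
    left_join(parent_tbl, by = keys)
  if (any(is.na(out$parent_mic))) {
    abort("parent peptide is missing for some strain/condition cells")
  }
  out |>
    mutate(
      ratio = .data$mic / .data$parent_mic,
      dilution_steps = log2(.data$ratio),
      bound = dplyr::case_when(
        .data$censored & .data$parent_censored ~ "unknown",
        .data$censored ~ "lower",
        .data$parent_censored ~ "upper",
        TRUE ~ "exact"
      ),
      at_or_below_parent = !.data$censored &
        (.data$parent_censored | .data$mic <= .data$parent_mic)
    )
}

#' Export a MIC panel as a heatmap-ready matrix
#'
#' Writes a wide-format TSV (strains as rows, peptides as columns) with
#' censored cells rendered as the bound prefixed with `">"`, the layout
#' heatmap tools expect.
#'
#' @param panel A long MIC panel tibble.
#' @param path Output TSV path.
#' @return The wide tibble, invisibly.
#' @export
export_heatmap_matrix <- function(panel, path) {
  wide <- panel |>
    mutate(cell = ifelse(.data$censored,
                         paste0(">", format_num(.data$mic)),
                         format_num(.data$mic))) |>
    select("strain", "peptide", "cell") |>
    tidyr::pivot_wider(names_from = "peptide", values_from = "cell")
  readr::write_tsv(wide, path)
  invisible(wide)
}

# plain decimal formatting without scientific notation or padding
format_num <- function(x) {
  trimws(format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE))
}
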