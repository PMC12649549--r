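# Workflow entry points binding the modules together. Each writes its
# outputs plus a JSON echo of the configuration used, so every number in a
# result file is auditable (scale, censor substitute, thresholds, seed).

.write_config_echo <- function(out_dir, command, config) {
  config$command <- command
  config$package_version <- as.character(utils::packageVersion("permamp"))
  jsonlite::write_json(config,
                       file.path(out_dir, paste0(command, "_config.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Generate a permutation library with descriptors
#'
#' Builds the cyclic-permutation library of a parent peptide, writes it as
#' FASTA (termini as key=value description tokens) and as a descriptor CSV
#' in the layout of published peptide-property tables.
#'
#' @param parent_sequence Parent one-letter sequence.
#' @param parent_name Parent label.
#' @param nterm,cterm Terminal states applied to parent and members.
#' @param member_names Optional names for the L-1 rotations.
#' @param out_dir Output directory (created if needed).
#' @return The descriptor tibble, invisibly. Writes `library.fasta`,
#'   `descriptors.csv` and a config echo into `out_dir`.
#' @examples
#' run_permute("KKWRKWLKWLAKK", "W5K/A9W", nterm = "acetyl",
#'             cterm = "amide", out_dir = tempfile())
#' @export
run_permute <- function(parent_sequence, parent_name = "parent",
                        nterm = "free", cterm = "free",
                        member_names = NULL, out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  parent <- peptides(parent_name, parent_sequence, nterm, cterm)
  lib <- cyclic_permutations(parent, member_names = member_names)
  desc <- peptide_descriptors(lib)
  write_peptide_fasta(lib, file.path(out_dir, "library.fasta"))
  write_descriptor_csv(desc, file.path(out_dir, "descriptors.csv"))
  .write_config_echo(out_dir, "permute",
                     list(parent_name = parent_name,
                          parent_sequence = parent_sequence,
                          nterm = nterm, cterm = cterm,
                          n_members = nrow(lib) - 1L))
  invisible(desc)
}

#' Compute descriptors for a FASTA of peptides
#'
#' @param fasta Input FASTA path (termini read from description tokens).
#' @param out Output CSV path.
#' @return The descriptor tibble, invisibly.
#' @export
run_describe <- function(fasta, out = "descriptors.csv") {
  desc <- peptide_descriptors(read_peptide_fasta(fasta))
  write_descriptor_csv(desc, out)
  invisible(desc)
}

#' Build a therapeutic-index report from assay tables
#'
#' Reads a MIC table (wide or long; `">"`-prefixed cells are censored) and
#' either a ready HC10 table or raw hemolysis dose-response CSVs (one per
#' peptide, `peptide.csv` naming), in which case HC10 is estimated first.
#'
#' @param mic_csv MIC table path.
#' @param hc10_csv Path to a CSV with `peptide`, `hc10` (and optional
#'   `censored`) columns. Exactly one of `hc10_csv`/`hemolysis_dir`.
#' @param hemolysis_dir Directory of per-peptide dose-response CSVs.
#' @param wide Is the MIC table wide-format (default) or long?
#' @param censor_substitute Substitute for censored MIC cells, ug/mL.
#' @param threshold,cap Passed to [estimate_hc10()] when estimating from
#'   raw curves.
#' @param out Output CSV path.
#' @param digits Presentation rounding for the written report.
#' @return The full-precision report tibble, invisibly.
#' @export
run_ti <- function(mic_csv, hc10_csv = NULL, hemolysis_dir = NULL,
                   wide = TRUE, censor_substitute = 100,
                   threshold = 10, cap = 108.7,
                   out = "ti_report.csv", digits = 1) {
  if (is.null(hc10_csv) == is.null(hemolysis_dir)) {
    abort("supply exactly one of hc10_csv or hemolysis_dir")
  }
  panel <- if (wide) read_mic_wide(mic_csv) else read_mic_long(mic_csv)
  hc10 <- if (!is.null(hc10_csv)) {
    readr::read_csv(hc10_csv, show_col_types = FALSE)
  } else {
    files <- list.files(hemolysis_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0) {
      abort(paste0("no dose-response CSVs in ", hemolysis_dir))
    }
    purrr::map_dfr(files, function(f) {
      fit <- estimate_hc10(read_dose_response(f), threshold = threshold,
                           cap = cap)
      tibble(peptide = sub("\\.csv$", "", basename(f)),
             hc10 = fit$hc10, censored = fit$censored)
    })
  }
  report <- ti_report(panel, hc10, censor_substitute = censor_substitute)
  write_ti_csv(report, out, digits = digits)
  invisible(report)
}

#' Simulate a synthetic assay bundle
#'
#' Generates a seeded synthetic MIC panel and hemolysis curves from a
#' default study-like ground truth (three peptides spanning potent to weak,
#' six strains split by Gram stain), writes the same CSV dialects the
#' readers consume, and saves the ground truth as JSON for recovery tests.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param replicate_sd MIC replicate noise, dilution steps.
#' @param noise_sd Curve noise, percent.
#' @return Invisibly, a list with the generated `panel`, `curves` and
#'   `truth`.
#' @export
run_simulate <- function(seed, out_dir = ".", replicate_sd = 0.5,
                         noise_sd = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- .default_recovery_truth(replicate_sd)
  panel <- gen_mic_panel(truth, seed)
  curve_truth <- curve_ground_truth(unique(truth$peptide),
                                    hc50 = c(30, 60, 120),
                                    noise_sd = noise_sd)
  curves <- purrr::map_dfr(seq_len(nrow(curve_truth)),
                           function(i) gen_hemolysis_curve(curve_truth[i, ],
                                                           seed))
  panel_out <- panel |>
    mutate(mic = ifelse(.data$censored, paste0(">", format_num(.data$mic)),
                        format_num(.data$mic))) |>
    select("peptide", "strain", "gram", "mic")
  readr::write_csv(panel_out, file.path(out_dir, "mic_long.csv"))
  readr::write_csv(curves, file.path(out_dir, "hemolysis_curves.csv"))
  jsonlite::write_json(
    list(mic_truth = truth,
         curve_truth = select(curve_truth, -"grid"),
         grid = curve_truth$grid[[1]]),
    file.path(out_dir, "ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  .write_config_echo(out_dir, "simulate",
                     list(seed = seed, replicate_sd = replicate_sd,
                          noise_sd = noise_sd))
  invisible(list(panel = panel, curves = curves, truth = truth))
}
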