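test_that("run_permute writes a library FASTA and descriptor CSV", {
  out <- withr::local_tempdir()
  desc <- run_permute("KKWRKWLKWLAKK", "W5K/A9W", nterm = "acetyl",
                      cterm = "amide",
                      member_names = sprintf("W5K%02d", 1:12),
                      out_dir = out)
  expect_equal(nrow(desc), 13)
  expect_true(file.exists(file.path(out, "library.fasta")))
  expect_true(file.exists(file.path(out, "descriptors.csv")))
  expect_true(file.exists(file.path(out, "permute_config.json")))
  back <- read_peptide_fasta(file.path(out, "library.fasta"))
  expect_equal(nrow(back), 13)
  # a short parent yields L-1 members
  out2 <- withr::local_tempdir()
  desc5 <- run_permute("KWLAK", out_dir = out2)
  expect_equal(sum(desc5$role == "member"), 4)
  expect_error(run_permute("KWZAK", out_dir = out2),
               "invalid residue 'Z'")
})

test_that("descriptor CSV applies published-table rounding", {
  out <- withr::local_tempdir()
  run_permute("KKWRKWLKWLAKK", "W5K/A9W", nterm = "acetyl",
              cterm = "amide", member_names = sprintf("W5K%02d", 1:12),
              out_dir = out)
  csv <- readr::read_csv(file.path(out, "descriptors.csv"),
                         show_col_types = FALSE)
  expect_equal(csv$muH, w5k_printed_muH)
  expect_equal(csv$II, w5k_printed_II)
  expect_equal(unique(csv$gravy), -1.631)
  expect_equal(unique(csv$AI), 67.69)
  expect_equal(unique(csv$charge), 7)
})

test_that("run_ti reproduces the selectivity report from files", {
  out <- withr::local_tempdir()
  mic_csv <- system.file("extdata", "w5k_mic_mh.csv", package = "permamp")
  hc10_csv <- system.file("extdata", "w5k_hc10.csv", package = "permamp")
  report <- run_ti(mic_csv, hc10_csv = hc10_csv,
                   out = file.path(out, "ti.csv"))
  written <- readr::read_csv(file.path(out, "ti.csv"),
                             show_col_types = FALSE)
  expect_equal(nrow(written), 13)
  expect_equal(written$GM_all[written$peptide == "W5K/A9W"], 4.1)
  expect_error(run_ti(mic_csv), "exactly one of")
})

test_that("run_ti can start from raw hemolysis curves", {
  out <- withr::local_tempdir()
  hemo_dir <- file.path(out, "hemo")
  dir.create(hemo_dir)
  # raw-signal dose-response files for two peptides
  # pepB's midpoint sits far above the grid top, so its curve never
  # reaches 10% within the tested range
  truth <- curve_ground_truth(c("pepA", "pepB"), hc50 = c(20, 600),
                              noise_sd = 0)
  for (i in 1:2) {
    curve <- gen_hemolysis_curve(truth[i, ], seed = 1)
    readr::write_csv(
      tibble::tibble(concentration = curve$concentration,
                     signal = 0.1 + curve$response / 100 * 0.9,
                     blank = 0.1, full = 1.0),
      file.path(hemo_dir, paste0(truth$peptide[i], ".csv"))
    )
  }
  mic_csv <- file.path(out, "mic.csv")
  readr::write_csv(tibble::tibble(
    peptide = rep(c("pepA", "pepB"), each = 2),
    strain = rep(c("s1", "s2"), 2),
    gram = rep(c("negative", "positive"), 2),
    mic = c("3.13", "6.25", "25", ">50")
  ), mic_csv)
  report <- run_ti(mic_csv, hemolysis_dir = hemo_dir, wide = FALSE,
                   out = file.path(out, "ti.csv"))
  expect_equal(sort(report$peptide), c("pepA", "pepB"))
  # pepB never reaches 10%: HC10 capped and censored
  expect_true(report$HC10_censored[report$peptide == "pepB"])
  expect_equal(report$HC10[report$peptide == "pepB"], 108.7)
  # pepA's estimate near the analytic inverse
  expect_lt(abs(log2(report$HC10[report$peptide == "pepA"] /
                       logistic_hc(20, 2))), 1)
})

test_that("re-running a command with the same inputs is byte-identical", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_simulate(seed = 11, out_dir = out1)
  run_simulate(seed = 11, out_dir = out2)
  for (f in c("mic_long.csv", "hemolysis_curves.csv",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = f)
  }
  # and the simulated CSV parses straight back into the analysis
  panel <- read_mic_long(file.path(out1, "mic_long.csv"))
  expect_true(all(c("mic", "censored") %in% names(panel)))
  expect_s3_class(gm_by_gram(panel), "tbl_df")
})

test_that("plots build without error", {
  wheel <- helical_wheel(w5k_library()[1:2, ])
  p1 <- ggplot2::autoplot(wheel)
  expect_s3_class(p1, "ggplot")
  curve <- data.frame(concentration = c(5, 10, 20, 40),
                      response = c(2, 6, 18, 55))
  p2 <- plot_dose_response(curve, estimate_hc10(curve))
  expect_s3_class(p2, "ggplot")
  p3 <- plot_mic_heatmap(w5k_mic_panel())
  expect_s3_class(p3, "ggplot")
})
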