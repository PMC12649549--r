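# Seeded synthetic-assay generators.
#
# These emulate the structure of the wet-lab readouts so the whole
# analysis pipeline (parse -> GM -> HC10 -> TI) can be exercised and its
# parameter recovery checked without laboratory data. A broth-microdilution
# MIC is quantised onto a two-fold dilution grid with replicate noise that
# is Gaussian in log2-dilution space; hemolysis and calcein-leakage curves
# are saturating logistics with additive percent noise. One global seed
# fans out to per-assay substreams so adding a generator does not perturb
# the draws of another.

# deterministic substream seed from a global seed and an assay label
substream_seed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Two-fold dilution grid
#'
#' The descending serial-dilution concentration series of a broth
#' microdilution assay, printed the way assay tables print it (half-up to
#' 2 decimals, so 50/16 appears as 3.13).
#'
#' @param top Highest tested concentration, ug/mL.
#' @param n Number of two-fold steps.
#' @return Numeric vector of length `n`, descending.
#' @examples
#' mic_dilution_grid() # 50, 25, 12.5, 6.25, 3.13, 1.56, 0.78
#' @export
mic_dilution_grid <- function(top = 50, n = 7) {
  round_half_up(top / 2^(0:(n - 1)), 2)
}

#' MIC ground truth table
#'
#' Bookkeeping for the MIC generator: one row per (peptide, strain) with
#' the true MIC on a log2 scale and the replicate noise, in dilution steps.
#'
#' @param peptide,strain,gram Character vectors (recycled to a common
#'   length).
#' @param true_mic True MIC, ug/mL.
#' @param replicate_sd Replicate standard deviation in two-fold dilution
#'   steps; 0.5 reflects the usual within-one-step reproducibility of
#'   microdilution assays.
#' @return A tibble with columns `peptide`, `strain`, `gram`,
#'   `true_log2_mic`, `replicate_sd`.
#' @export
mic_ground_truth <- function(peptide, strain, gram, true_mic,
                             replicate_sd = 0.5) {
  if (any(true_mic <= 0)) abort("true_mic must be positive")
  if (any(replicate_sd < 0)) abort("replicate_sd must be >= 0")
  tibble(
    peptide = peptide, strain = strain, gram = gram,
    true_log2_mic = log2(true_mic),
    replicate_sd = replicate_sd
  )
}

#' Generate a synthetic censored MIC panel
#'
#' For each ground-truth row, draws a replicate deviation in log2-dilution
#' space and reports the smallest grid concentration at or above the noisy
#' MIC; values above the top of the grid become censored `">top"` cells,
#' exactly as an endpoint-read microdilution plate would record them.
#' Deterministic for a fixed seed.
#'
#' @param truth A [mic_ground_truth()] tibble.
#' @param seed Integer seed (fans out to one substream per panel cell).
#' @param grid Descending two-fold concentration series, ug/mL.
#' @return A long MIC panel tibble (`peptide`, `strain`, `gram`, `mic`,
#'   `censored`) compatible with [gm_by_gram()] and [ti_report()].
#' @examples
#' truth <- mic_ground_truth("pep1", paste0("s", 1:4),
#'                           c("negative", "negative", "positive", "positive"),
#'                           true_mic = 6.25, replicate_sd = 0)
#' gen_mic_panel(truth, seed = 1)
#' @export
gen_mic_panel <- function(truth, seed, grid = mic_dilution_grid()) {
  stopifnot(all(c("peptide", "strain", "gram", "true_log2_mic",
                  "replicate_sd") %in% names(truth)))
  grid <- sort(grid, decreasing = TRUE)
  log_grid <- log2(grid)
  n <- nrow(truth)
  eps <- numeric(n)
  for (i in seq_len(n)) {
    sub <- substream_seed(seed, paste0("mic/", truth$peptide[i], "/",
                                       truth$strain[i]))
    eps[i] <- withr::with_seed(sub, stats::rnorm(1))
  }
  noisy <- truth$true_log2_mic + eps * truth$replicate_sd
  mic <- numeric(n)
  censored <- logical(n)
  for (i in seq_len(n)) {
    at_or_above <- which(log_grid >= noisy[i] - 1e-9)
    if (length(at_or_above) == 0) {
      mic[i] <- grid[1]
      censored[i] <- TRUE
    } else {
      mic[i] <- grid[max(at_or_above)]
      censored[i] <- FALSE
    }
  }
  tibble(
    peptide = truth$peptide, strain = truth$strain, gram = truth$gram,
    mic = mic, censored = censored
  )
}

#' Dose-response curve ground truth
#'
#' Parameters of the saturating logistic used to emulate hemolysis and
#' calcein-leakage curves: `response(c) = 100 / (1 + (HC50/c)^hill)`. The
#' analytic 10%-response point is `HC50 * 9^(-1/hill)`.
#'
#' @param peptide Character vector of labels.
#' @param hc50 Midpoint concentration, ug/mL.
#' @param hill Hill slope (> 0).
#' @param noise_sd Additive response noise, percent.
#' @param grid Concentration series for the simulated readout, ug/mL;
#'   defaults to a two-fold series from the hemolysis assay's 108.7 ug/mL
#'   (200 uM) top concentration.
#' @return A tibble with one row per peptide.
#' @export
curve_ground_truth <- function(peptide, hc50, hill = 2, noise_sd = 2,
                               grid = round_half_up(108.7 / 2^(6:0), 3)) {
  if (any(hc50 <= 0)) abort("hc50 must be positive")
  if (any(hill <= 0)) abort("hill must be positive")
  if (any(noise_sd < 0)) abort("noise_sd must be >= 0")
  tibble(peptide = peptide, hc50 = hc50, hill = hill, noise_sd = noise_sd,
         grid = list(sort(grid)))
}

logistic_response <- function(conc, hc50, hill) {
  100 / (1 + (hc50 / conc)^hill)
}

#' Analytic threshold concentration of the generating logistic
#'
#' Closed-form inverse of `100 / (1 + (HC50/c)^hill)` at a given response
#' threshold; for the 10% default this is `HC50 * 9^(-1/hill)`. Used as the
#' independent reference when checking [estimate_hc10()] on synthetic
#' curves.
#'
#' @inheritParams curve_ground_truth
#' @param threshold Response threshold, percent.
#' @return Numeric vector, ug/mL.
#' @export
logistic_hc <- function(hc50, hill, threshold = 10) {
  hc50 * ((100 - threshold) / threshold)^(-1 / hill)
}

#' Generate a synthetic hemolysis dose-response curve
#'
#' Logistic response plus additive Gaussian noise, truncated to the
#' physically meaningful 0-100% band. Deterministic for a fixed seed.
#'
#' @param truth One row of [curve_ground_truth()].
#' @param seed Integer seed.
#' @return A tibble with columns `peptide`, `concentration`, `response`.
#' @examples
#' tr <- curve_ground_truth("pep1", hc50 = 30, noise_sd = 0)
#' gen_hemolysis_curve(tr[1, ], seed = 1)
#' @export
gen_hemolysis_curve <- function(truth, seed) {
  truth <- truth[1, ]
  grid <- truth$grid[[1]]
  sub <- substream_seed(seed, paste0("hemolysis/", truth$peptide))
  noise <- withr::with_seed(sub, stats::rnorm(length(grid)))
  resp <- logistic_response(grid, truth$hc50, truth$hill) +
    noise * truth$noise_sd
  tibble(
    peptide = truth$peptide,
    concentration = grid,
    response = pmin(100, pmax(0, resp))
  )
}

#' Generate a synthetic calcein-leakage readout
#'
#' Same logistic form as [gen_hemolysis_curve()], but emitted as raw
#' fluorescence together with the intact-vesicle (`f0`) and full-release
#' (`fr`) controls, so [leakage_percent()] has to be applied before any
#' curve summary.
#'
#' @inheritParams gen_hemolysis_curve
#' @param f0 Baseline fluorescence of intact vesicles (arbitrary units).
#' @param fr Full-release fluorescence after detergent.
#' @return A tibble with columns `peptide`, `concentration`,
#'   `fluorescence`, `f0`, `fr`.
#' @export
gen_leakage_curve <- function(truth, seed, f0 = 50, fr = 1050) {
  truth <- truth[1, ]
  grid <- truth$grid[[1]]
  sub <- substream_seed(seed, paste0("leakage/", truth$peptide))
  noise <- withr::with_seed(sub, stats::rnorm(length(grid)))
  frac <- logistic_response(grid, truth$hc50, truth$hill) +
    noise * truth$noise_sd
  frac <- pmin(100, pmax(0, frac)) / 100
  tibble(
    peptide = truth$peptide,
    concentration = grid,
    fluorescence = f0 + frac * (fr - f0),
    f0 = f0, fr = fr
  )
}

# default compact study emulation used by the recovery suite: six strains
# (half Gram-negative), three peptides spanning potent to weak
.default_recovery_truth <- function(replicate_sd = 0.5) {
  peps <- c("potent", "intermediate", "weak")
  true_mic <- c(potent = 3.125, intermediate = 12.5, weak = 50)
  strains <- paste0("strain", 1:6)
  gram <- rep(c("negative", "positive"), each = 3)
  grid_truth <- expand.grid(peptide = peps, strain = strains,
                            stringsAsFactors = FALSE)
  grid_truth$gram <- gram[match(grid_truth$strain, strains)]
  mic_ground_truth(grid_truth$peptide, grid_truth$strain, grid_truth$gram,
                   true_mic = true_mic[grid_truth$peptide],
                   replicate_sd = replicate_sd)
}

#' End-to-end parameter recovery on synthetic assays
#'
#' For each seed, generates a synthetic MIC panel and hemolysis curves from
#' known ground truth, runs the full analysis (parse, geometric means, HC10
#' estimation, therapeutic index), and checks that the known parameters are
#' recovered: every geometric mean within one two-fold dilution step of the
#' truth, every HC10 within one log-grid step of the analytic logistic
#' inverse, and every TI within the product of the two tolerances.
#'
#' @param seeds Integer vector of seeds.
#' @param replicate_sd MIC replicate noise, dilution steps.
#' @param noise_sd Curve noise, percent.
#' @return A tibble with one row per (seed, peptide) carrying the recovered
#'   and true quantities and logical `gm_ok`, `hc10_ok`, `ti_ok`, `pass`.
#' @examples
#' recovery_suite(seeds = 1:2)
#' @export
recovery_suite <- function(seeds, replicate_sd = 0.5, noise_sd = 2) {
  purrr::map_dfr(seeds, function(seed) {
    truth <- .default_recovery_truth(replicate_sd)
    panel <- gen_mic_panel(truth, seed)
    curve_truth <- curve_ground_truth(
      unique(truth$peptide),
      hc50 = c(30, 60, 120)[seq_along(unique(truth$peptide))],
      noise_sd = noise_sd
    )
    hc10_tbl <- purrr::map_dfr(seq_len(nrow(curve_truth)), function(i) {
      fit <- estimate_hc10(gen_hemolysis_curve(curve_truth[i, ], seed))
      tibble(peptide = curve_truth$peptide[i], hc10 = fit$hc10,
             censored = fit$censored)
    })
    report <- ti_report(panel, hc10_tbl)

    true_gm <- truth |>
      group_by(.data$peptide) |>
      summarise(gm_true = exp(mean(log(2^.data$true_log2_mic))),
                .groups = "drop")
    hc_true <- tibble(
      peptide = curve_truth$peptide,
      hc10_true = pmin(logistic_hc(curve_truth$hc50, curve_truth$hill), 108.7)
    )
    grid_step <- 2 # two-fold series: one step is a factor of 2
    report |>
      left_join(true_gm, by = "peptide") |>
      left_join(hc_true, by = "peptide") |>
      mutate(
        seed = seed,
        gm_ok = abs(log2(.data$GM_all / .data$gm_true)) <= 1,
        hc10_ok = abs(log2(.data$HC10 / .data$hc10_true)) <=
          log2(grid_step),
        ti_ok = abs(log2(.data$TI_all /
                           (.data$hc10_true / .data$gm_true))) <= 2,
        pass = .data$gm_ok & .data$hc10_ok & .data$ti_ok
      ) |>
      select("seed", "peptide", "GM_all", "gm_true", "HC10", "hc10_true",
             "TI_all", "gm_ok", "hc10_ok", "ti_ok", "pass")
  })
}
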