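# Dose-response summaries: hemolysis and calcein-leakage percentages from
# raw readouts, HC10 estimation by log-linear interpolation, wound repair
# rate, and assembly of the therapeutic-index report.

#' Percent hemolysis from raw absorbances
#'
#' `100 * (A_sample - A_blank) / (A_triton - A_blank)`, the standard
#' normalisation against a buffer blank (0%) and a full-lysis detergent
#' control (100%). Raw values are returned untouched; small negative
#' results from blank noise should be clamped only at presentation.
#'
#' @param a_sample Sample absorbance(s).
#' @param a_blank Buffer (PBS) blank absorbance.
#' @param a_triton Full-lysis (Triton X-100) absorbance.
#' @return Numeric vector, percent.
#' @examples
#' hemolysis_percent(0.55, 0.1, 1.0) # 50
#' @export
hemolysis_percent <- function(a_sample, a_blank, a_triton) {
  if (any(a_triton == a_blank)) {
    abort("hemolysis_percent: full-lysis and blank controls are equal")
  }
  100 * (a_sample - a_blank) / (a_triton - a_blank)
}

#' Percent calcein leakage from raw fluorescence
#'
#' `100 * (F - F0) / (Fr - F0)` where `F0` is the fluorescence of intact
#' vesicles and `Fr` the maximal release after detergent.
#'
#' @param f Sample fluorescence(s).
#' @param f0 Intact-vesicle (no peptide) fluorescence.
#' @param fr Full-release (Triton) fluorescence.
#' @return Numeric vector, percent.
#' @examples
#' leakage_percent(55, 10, 100) # 50
#' @export
leakage_percent <- function(f, f0, fr) {
  if (any(fr == f0)) {
    abort("leakage_percent: full-release and baseline controls are equal")
  }
  100 * (f - f0) / (fr - f0)
}

#' Wound repair rate
#'
#' Fractional closure of a scratch-wound area over 24 h:
#' `(area_0h - area_24h) / area_0h`. Negative when the gap grew.
#'
#' @param area_0h Wound area at time zero (must be positive).
#' @param area_24h Wound area at 24 h.
#' @return Numeric vector, fraction of the initial area closed.
#' @examples
#' repair_rate(100, 25) # 0.75
#' @export
repair_rate <- function(area_0h, area_24h) {
  if (any(area_0h <= 0)) abort("repair_rate: area_0h must be positive")
  (area_0h - area_24h) / area_0h
}

#' Estimate HC10 from a dose-response curve
#'
#' Locates the lowest concentration at which the response reaches a
#' threshold (10% hemolysis by default). If a measured point hits the
#' threshold exactly it is returned; otherwise the first upward crossing is
#' interpolated linearly in log10(concentration) between the bracketing
#' points. When the whole curve stays below the threshold the assay cap is
#' returned with `censored = TRUE` (the convention for "no detectable
#' hemolysis at the top tested concentration"). Non-monotone curves are
#' resolved by the first upward crossing and flagged.
#'
#' @param curve A data frame with columns `concentration` (strictly
#'   increasing, ug/mL) and `response` (percent).
#' @param threshold Response threshold, percent.
#' @param cap Concentration reported when the curve never reaches the
#'   threshold, ug/mL (108.7 ug/mL = 200 uM for a ~1.84 kDa peptide).
#' @return An object of class `hc10_fit` with elements `hc10`, `censored`,
#'   `threshold`, `cap`, `n_points`, `nonmonotone`, and the input curve.
#'   Use [tidy()] / [glance()] for tibble views.
#' @examples
#' curve <- data.frame(concentration = c(5, 10, 20, 40),
#'                     response = c(2, 6, 18, 55))
#' tidy(estimate_hc10(curve))
#' @export
estimate_hc10 <- function(curve, threshold = 10, cap = 108.7) {
  curve <- as.data.frame(curve)
  if (!all(c("concentration", "response") %in% names(curve))) {
    abort("curve needs 'concentration' and 'response' columns")
  }
  conc <- curve$concentration
  resp <- curve$response
  if (length(conc) == 0) abort("estimate_hc10: empty curve")
  if (any(diff(conc) <= 0)) {
    abort("estimate_hc10: concentrations must be strictly increasing")
  }
  if (any(!is.finite(resp))) abort("estimate_hc10: non-finite responses")
  nonmono <- any(diff(resp) < 0)

  # exact hit: the smallest measured concentration sitting on the threshold
  exact <- which(resp == threshold)
  if (length(exact) > 0) {
    return(new_hc10_fit(conc[exact[1]], FALSE, threshold, cap,
                        length(conc), nonmono, curve))
  }
  if (max(resp) < threshold) {
    return(new_hc10_fit(cap, TRUE, threshold, cap,
                        length(conc), nonmono, curve))
  }
  if (resp[1] > threshold) {
    # already above threshold at the lowest tested dose: report that dose
    # as the smallest observed concentration reaching the threshold
    return(new_hc10_fit(conc[1], FALSE, threshold, cap,
                        length(conc), nonmono, curve))
  }
  # first upward crossing
  cross <- which(resp[-1] > threshold & resp[-length(resp)] < threshold)[1]
  if (is.na(cross)) {
    abort("estimate_hc10: no upward crossing found")
  }
  lo <- cross
  hi <- cross + 1
  frac <- (threshold - resp[lo]) / (resp[hi] - resp[lo])
  log_c <- log10(conc[lo]) + frac * (log10(conc[hi]) - log10(conc[lo]))
  new_hc10_fit(10^log_c, FALSE, threshold, cap, length(conc), nonmono, curve)
}

new_hc10_fit <- function(hc10, censored, threshold, cap, n, nonmono, curve) {
  structure(
    list(hc10 = hc10, censored = censored, threshold = threshold,
         cap = cap, n_points = n, nonmonotone = nonmono, curve = curve),
    class = "hc10_fit"
  )
}

#' @export
print.hc10_fit <- function(x, ...) {
  cat(sprintf("HC%g estimate: %.3g ug/mL%s (%d points%s)\n",
              x$threshold, x$hc10,
              if (x$censored) paste0(" [censored at cap ", x$cap, "]") else "",
              x$n_points,
              if (x$nonmonotone) ", non-monotone curve" else ""))
  invisible(x)
}

#' @rdname estimate_hc10
#' @param x,object An `hc10_fit`.
#' @param ... Unused.
#' @method tidy hc10_fit
#' @export
tidy.hc10_fit <- function(x, ...) {
  tibble(estimate = x$hc10, censored = x$censored,
         threshold = x$threshold, cap = x$cap)
}

#' @rdname estimate_hc10
#' @method glance hc10_fit
#' @export
glance.hc10_fit <- function(x, ...) {
  tibble(n_points = x$n_points, nonmonotone = x$nonmonotone,
         max_response = max(x$curve$response),
         censored = x$censored)
}

#' Therapeutic index
#'
#' `TI = HC10 / GM`: the ratio of the 10%-hemolysis concentration to the
#' geometric-mean MIC. Larger values indicate greater selectivity for
#' bacteria over host cells.
#'
#' @param hc10 HC10 concentration(s), ug/mL.
#' @param gm Geometric-mean MIC(s), ug/mL (positive).
#' @return Numeric vector, dimensionless.
#' @examples
#' therapeutic_index(30, 4.1)
#' @export
therapeutic_index <- function(hc10, gm) {
  if (any(gm <= 0)) abort("therapeutic_index: GM must be positive")
  hc10 / gm
}

#' Therapeutic-index report
#'
#' Assembles the full selectivity table: per-peptide geometric-mean MICs
#' stratified by Gram stain (with the censoring substitute), the supplied
#' HC10 values, and the three therapeutic indices `TI = HC10 / GM`.
#'
#' @param panel A long MIC panel tibble.
#' @param hc10 A data frame with columns `peptide`, `hc10` and optionally
#'   `censored` (flagging capped HC10 values).
#' @param censor_substitute Substitute for censored MIC cells, ug/mL.
#' @param digits If non-NULL, round all GM/HC10/TI columns half-up to this
#'   many decimals for presentation (published tables use 1).
#' @return A tibble with columns `peptide`, `GM_neg`, `GM_pos`, `GM_all`,
#'   `HC10`, `HC10_censored`, `TI_neg`, `TI_pos`, `TI_all`.
#' @examples
#' ti_report(w5k_mic_panel(), w5k_hc10(), digits = 1)
#' @export
ti_report <- function(panel, hc10, censor_substitute = 100, digits = NULL) {
  hc10 <- as_tibble(hc10)
  if (!all(c("peptide", "hc10") %in% names(hc10))) {
    abort("hc10 table needs 'peptide' and 'hc10' columns")
  }
  if (!"censored" %in% names(hc10)) hc10$censored <- FALSE
  gm <- gm_by_gram(panel, censor_substitute)
  missing_hc <- setdiff(gm$peptide, hc10$peptide)
  if (length(missing_hc) > 0) {
    abort(paste0("no HC10 for peptide(s): ",
                 paste(missing_hc, collapse = ", ")))
  }
  out <- gm |>
    left_join(select(hc10, "peptide", HC10 = "hc10",
                     HC10_censored = "censored"),
              by = "peptide") |>
    mutate(
      TI_neg = therapeutic_index(.data$HC10, .data$GM_neg),
      TI_pos = therapeutic_index(.data$HC10, .data$GM_pos),
      TI_all = therapeutic_index(.data$HC10, .data$GM_all)
    )
  if (!is.null(digits)) {
    out <- mutate(out, across(
      c("GM_neg", "GM_pos", "GM_all", "HC10",
        "TI_neg", "TI_pos", "TI_all"),
      ~ round_half_up(.x, digits)
    ))
  }
  out
}
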