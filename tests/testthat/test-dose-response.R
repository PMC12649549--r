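test_that("hemolysis and leakage percentages are exact normalisations", {
  expect_equal(hemolysis_percent(0.1, 0.1, 1.0), 0)
  expect_equal(hemolysis_percent(1.0, 0.1, 1.0), 100)
  expect_equal(hemolysis_percent(0.55, 0.1, 1.0), 50)
  expect_error(hemolysis_percent(0.5, 0.2, 0.2), "controls are equal")
  expect_equal(leakage_percent(10, 10, 100), 0)
  expect_equal(leakage_percent(100, 10, 100), 100)
  expect_equal(leakage_percent(55, 10, 100), 50)
  expect_error(leakage_percent(50, 30, 30), "controls are equal")
})

test_that("repair rate covers closure, stasis and growth", {
  expect_equal(repair_rate(100, 0), 1)
  expect_equal(repair_rate(100, 100), 0)
  expect_equal(repair_rate(100, 25), 0.75)
  expect_lt(repair_rate(100, 140), 0)
  expect_error(repair_rate(0, 10), "positive")
})

test_that("HC10 estimation handles exact hits, caps and crossings", {
  # exact measured hit
  fit <- estimate_hc10(data.frame(concentration = 10, response = 10))
  expect_equal(fit$hc10, 10)
  expect_false(fit$censored)
  # everything below threshold: capped and censored
  flat <- data.frame(concentration = c(10, 20, 40), response = c(1, 2, 4))
  fit <- estimate_hc10(flat)
  expect_equal(fit$hc10, 108.7)
  expect_true(fit$censored)
  expect_true(tidy(fit)$censored)
  # interpolation lies between the bracketing points, in log space
  curve <- data.frame(concentration = c(5, 10, 20, 40),
                      response = c(2, 6, 18, 55))
  fit <- estimate_hc10(curve)
  expect_gt(fit$hc10, 10)
  expect_lt(fit$hc10, 20)
  manual <- 10^(log10(10) + (10 - 6) / (18 - 6) * (log10(20) - log10(10)))
  expect_equal(fit$hc10, manual)
  expect_error(estimate_hc10(data.frame(concentration = c(2, 1),
                                        response = c(1, 2))),
               "strictly increasing")
})

test_that("HC10 matches the analytic logistic inverse within a grid step", {
  # noiseless logistic curves: the estimate must sit within one two-fold
  # step of HC50 * 9^(-1/hill)
  grid <- round_half_up(108.7 / 2^(6:0), 3)
  for (hc50 in c(10, 30, 60)) {
    for (hill in c(1, 2, 4)) {
      curve <- data.frame(
        concentration = grid,
        response = 100 / (1 + (hc50 / grid)^hill)
      )
      est <- estimate_hc10(curve)$hc10
      analytic <- logistic_hc(hc50, hill)
      expect_lt(abs(log2(est / analytic)), 1,
                label = sprintf("hc50=%g hill=%g", hc50, hill))
    }
  }
})

test_that("HC10 interpolation agrees with a dense brute-force scan", {
  # oracle: evaluate the piecewise log-linear interpolant on a dense grid
  # and take the first concentration reaching the threshold
  curve <- data.frame(concentration = c(2, 5, 12, 30, 80),
                      response = c(1, 4, 9, 35, 90))
  est <- estimate_hc10(curve)$hc10
  dense <- 10^seq(log10(2), log10(80), length.out = 200001)
  interp <- approx(log10(curve$concentration), curve$response,
                   xout = log10(dense))$y
  brute <- dense[which(interp >= 10)[1]]
  expect_equal(est, brute, tolerance = 1e-4)
})

test_that("therapeutic index is the HC10/GM ratio with its monotonicities", {
  expect_equal(therapeutic_index(30, 30), 1)
  expect_equal(round_half_up(therapeutic_index(30, 4.1233), 1), 7.3)
  expect_error(therapeutic_index(10, 0), "positive")
  # linear in HC10, anti-monotone in GM
  expect_equal(therapeutic_index(60, 5), 2 * therapeutic_index(30, 5))
  expect_gt(therapeutic_index(30, 2), therapeutic_index(30, 4))
})

test_that("the selectivity report reproduces the published table", {
  report <- ti_report(w5k_mic_panel(), w5k_hc10())
  rounded <- report |>
    dplyr::mutate(dplyr::across(c(GM_neg, GM_pos, GM_all, HC10,
                                  TI_neg, TI_pos, TI_all),
                                ~ round_half_up(.x, 1))) |>
    dplyr::arrange(match(peptide, w5k_printed_ti$peptide))
  # GM columns: exact agreement with the printed table at 1 d.p.
  expect_equal(rounded$GM_neg, w5k_printed_ti$GM_neg)
  expect_equal(rounded$GM_pos, w5k_printed_ti$GM_pos)
  expect_equal(rounded$GM_all, w5k_printed_ti$GM_all)
  # TI columns: agreement within one printed ulp (the HC10 inputs are
  # themselves rounded to 1 d.p., which can move a TI cell by 0.1)
  expect_true(all(abs(rounded$TI_neg - w5k_printed_ti$TI_neg) <= 0.1))
  expect_true(all(abs(rounded$TI_pos - w5k_printed_ti$TI_pos) <= 0.1))
  expect_true(all(abs(rounded$TI_all - w5k_printed_ti$TI_all) <= 0.1))
  # at most one TI cell may differ at all, and only by the input precision
  diffs <- c(rounded$TI_neg - w5k_printed_ti$TI_neg,
             rounded$TI_pos - w5k_printed_ti$TI_pos,
             rounded$TI_all - w5k_printed_ti$TI_all)
  expect_lte(sum(abs(diffs) > 1e-9), 1)
  # capped HC10 values carry the censoring flag through
  expect_true(all(report$HC10_censored[report$HC10 == 108.7]))
})
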