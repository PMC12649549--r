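# Shared fixtures: the published W5K permutation panel and its printed
# summary values, plus a tiny random-peptide generator for property tests.

w5k_sequences <- c(
  "W5K/A9W" = "KKWRKWLKWLAKK",
  "W5K01" = "KWRKWLKWLAKKK",
  "W5K02" = "WRKWLKWLAKKKK",
  "W5K03" = "RKWLKWLAKKKKW",
  "W5K04" = "KWLKWLAKKKKWR",
  "W5K05" = "WLKWLAKKKKWRK",
  "W5K06" = "LKWLAKKKKWRKW",
  "W5K07" = "KWLAKKKKWRKWL",
  "W5K08" = "WLAKKKKWRKWLK",
  "W5K09" = "LAKKKKWRKWLKW",
  "W5K10" = "AKKKKWRKWLKWL",
  "W5K11" = "KKKKWRKWLKWLA",
  "W5K12" = "KKKWRKWLKWLAK"
)

# published physicochemical table: hydrophobic moment and instability index
w5k_printed_muH <- c(0.72, 0.59, 0.67, 0.54, 0.39, 0.44, 0.28, 0.52, 0.57,
                     0.37, 0.61, 0.61, 0.75)
w5k_printed_II <- c(21.68, 21.68, 21.68, 21.68, 21.68, 21.68, 12.19, 28.22,
                    21.68, 12.19, 21.68, 21.68, 21.68)

# published selectivity table (GM and TI columns, 1 d.p.)
w5k_printed_ti <- tibble::tribble(
  ~peptide, ~GM_neg, ~GM_pos, ~GM_all, ~HC10, ~TI_neg, ~TI_pos, ~TI_all,
  "W5K/A9W", 2.1, 8.2, 4.1, 30.0, 14.5, 3.6, 7.3,
  "W5K01", 8.2, 28.7, 15.4, 70.9, 8.6, 2.5, 4.6,
  "W5K02", 7.2, 21.8, 12.5, 16.7, 2.3, 0.8, 1.3,
  "W5K03", 16.5, 66.0, 33.0, 108.7, 6.6, 1.6, 3.3,
  "W5K04", 18.9, 66.0, 35.4, 108.7, 5.7, 1.6, 3.1,
  "W5K05", 12.5, 33.0, 20.3, 108.7, 8.7, 3.3, 5.4,
  "W5K06", 43.5, 75.8, 57.4, 108.7, 2.5, 1.4, 1.9,
  "W5K07", 21.8, 87.1, 43.5, 108.7, 5.0, 1.2, 2.5,
  "W5K08", 50.0, 75.8, 61.6, 108.7, 2.2, 1.4, 1.8,
  "W5K09", 33.0, 75.8, 50.0, 108.7, 3.3, 1.4, 2.2,
  "W5K10", 3.1, 9.5, 5.4, 108.7, 34.8, 11.5, 20.0,
  "W5K11", 2.1, 5.4, 3.3, 71.0, 34.5, 13.0, 21.2,
  "W5K12", 2.4, 4.7, 3.4, 41.7, 17.6, 8.8, 12.4
)

random_sequence <- function(len) {
  paste(sample(permamp:::AA_CODES, len, replace = TRUE), collapse = "")
}
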