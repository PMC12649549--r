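test_that("composition descriptors reproduce the published parent values", {
  parent <- "KKWRKWLKWLAKK"
  expect_equal(round_half_up(gravy(parent), 3), -1.631)
  expect_equal(round_half_up(mean_hydrophobicity(parent), 2), 0.27)
  expect_equal(round_half_up(aliphatic_index(parent), 2), 67.69)
  expect_equal(net_charge(parent, nterm = "acetyl", cterm = "amide"), 7)
})

test_that("descriptor base cases match scale values", {
  expect_equal(gravy("II"), 4.5)
  expect_equal(gravy("GGGG"), -0.4)
  expect_equal(mean_hydrophobicity("WWWW"),
               hydrophobicity_scale("FP")[["W"]])
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("GGKK"), 0)
  zero_scale <- setNames(rep(0, 20), permamp:::AA_CODES)
  expect_equal(mean_hydrophobicity("KWLA", scale = zero_scale), 0)
  expect_equal(hydrophobic_moment("KWLA", scale = zero_scale), 0)
})

test_that("hydrophobic moment matches the full published column at 2 d.p.", {
  expect_equal(round_half_up(hydrophobic_moment(w5k_sequences), 2),
               setNames(w5k_printed_muH, names(w5k_sequences)))
})

test_that("instability index matches the full published column at 2 d.p.", {
  expect_equal(round_half_up(instability_index(w5k_sequences), 2),
               setNames(w5k_printed_II, names(w5k_sequences)))
  # length-2 closed form: II = 5 * DIWV(X, Y)
  expect_equal(instability_index("KW"), 5 * diwv_table()["K", "W"])
  expect_error(instability_index("K"), "length >= 2")
})

test_that("rotation II equals cyclic sum minus the omitted adjacent pair", {
  # brute-force oracle: the cyclic dipeptide sum is rotation-invariant, and
  # rotation k omits exactly one adjacent pair of the cycle
  set.seed(7)
  diwv <- diwv_table()
  for (rep in 1:5) {
    s <- random_sequence(sample(6:14, 1))
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    cyc_pairs <- cbind(ch, ch[c(2:L, 1)])
    s_cyc <- sum(diwv[cyc_pairs])
    lib <- cyclic_permutations(peptides("r", s))
    for (i in seq_len(nrow(lib))) {
      k <- lib$start_offset[i]
      omitted <- diwv[ch[if (k == 0) L else k], ch[(k %% L) + 1]]
      expect_equal(instability_index(lib$sequence[i]),
                   10 / L * (s_cyc - omitted))
    }
  }
})

test_that("composition descriptors are rotation-invariant, order-sensitive ones are not", {
  desc <- peptide_descriptors(w5k_library())
  for (col in c("H_mean", "gravy", "AI", "charge", "MW")) {
    expect_equal(max(desc[[col]]) - min(desc[[col]]), 0,
                 tolerance = 1e-9, label = col)
  }
  expect_gt(length(unique(round(desc$muH, 6))), 1)
  expect_gt(length(unique(round(desc$II, 6))), 1)
  expect_true(all(desc$stable)) # whole published panel has II < 40
})

test_that("hydrophobic moment obeys its bounds and single-residue limit", {
  fp <- hydrophobicity_scale("FP")
  set.seed(11)
  for (rep in 1:10) {
    s <- random_sequence(sample(2:20, 1))
    mu <- hydrophobic_moment(s)
    expect_gte(mu, 0)
    expect_lte(mu, max(abs(fp)) + 1e-12)
  }
  expect_equal(hydrophobic_moment("W"), abs(fp[["W"]]))
  expect_equal(hydrophobic_moment("K"), abs(fp[["K"]]))
})

test_that("net charge handles termini and the titration model", {
  expect_equal(net_charge("GG"), 0) # +1 N-term, -1 C-term
  expect_equal(net_charge("GG", nterm = "acetyl", cterm = "amide"), 0)
  expect_equal(net_charge("KKHH", nterm = "acetyl", cterm = "amide"), 2)
  expect_equal(net_charge("KKHH", nterm = "acetyl", cterm = "amide",
                          pH = 5), 4) # His counts below pH 6
  # titration charge decreases monotonically with pH
  z <- vapply(c(3, 5, 7.4, 10, 12),
              function(p) net_charge("KKWRKWLKWLAKK", "acetyl", "amide",
                                     model = "titration", pH = p),
              numeric(1))
  expect_true(all(diff(z) < 0))
  # near-neutral pH the titration charge approaches the formal +7
  expect_equal(z[3], 7, tolerance = 0.05)
})

test_that("molecular weight matches an independent residue-mass summation", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01)
  # frozen oracle: average-mass summation for Ac-KKWRKWLKWLAKK-NH2
  # computed independently before the implementation (1840.31 Da)
  expect_equal(molecular_weight("KKWRKWLKWLAKK", "acetyl", "amide"),
               1840.31, tolerance = 0.1)
  set.seed(3)
  s <- random_sequence(10)
  expect_equal(molecular_weight(s, "acetyl", "free") -
                 molecular_weight(s, "free", "free"),
               42.037, tolerance = 1e-3)
})
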