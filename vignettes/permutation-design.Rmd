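---
title: "Cyclic permutation design and selectivity scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclic permutation design and selectivity scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permamp)
library(dplyr)
```

## The design problem

Short cationic, tryptophan-rich peptides kill bacteria by disrupting their
membranes. Because activity and toxicity both depend on how charge and
hydrophobic bulk are arranged around the helix — not just on composition —
a natural design move is *cyclic sequence permutation*: read the parent
sequence from every start position around a circle. All rotations share the
parent's residue multiset, so molecular weight, net charge, mean
hydrophobicity, GRAVY and aliphatic index are held fixed, while the
helical-wheel hydrophobic moment and the dipeptide-based instability index
vary. Comparing rotations therefore isolates the effect of residue *order*.

`cyclic_permutations()` implements rotation k as
`sequence[k+1..L] + sequence[1..k]`, which corresponds to reading the wheel
clockwise from position k+1. A length-L parent yields exactly L−1 members;
rotations of a periodic parent that repeat an earlier sequence are kept and
flagged `duplicate` rather than dropped, so the library size is always
predictable. Terminal modifications (N-acetyl, C-amide) are metadata flags
carried unchanged through rotation — they are never sequence characters,
in FASTA they travel as `nterm=`/`cterm=` description tokens.

## Descriptors

* **Mean hydrophobicity** `<H>` and the **hydrophobic moment** `<μH>` use
  the Fauchère–Pliska octanol/water scale, the scale behind the
  helical-wheel web calculators whose outputs populate published AMP
  design tables. The moment is

  \[ \mu_H = \frac{1}{N}\left|\sum_{i=0}^{N-1} H_i
     (\cos i\delta, \sin i\delta)\right|, \qquad \delta = 100^\circ, \]

  with the first residue at angle 0. Both the scale and the i = 0 indexing
  were fixed by verifying that they reproduce the published W5K panel
  column (0.72 for the parent, 0.28 for the W5K06 rotation, all 13 values
  at 2 d.p.).
* **GRAVY** is the Kyte–Doolittle mean; **aliphatic index** is Ikai's
  `100 X_A + 290 X_V + 390 (X_I + X_L)` over mole fractions.
* **Instability index** is Guruprasad's `(10/L) Σ DIWV(res_i, res_{i+1})`
  over adjacent dipeptides, computed on the bare sequence (the
  modifications are invisible to the dipeptide table, matching the
  ProtParam-style calculators). The DIWV weights ship as a plain-text CSV.
  A useful identity falls out of the rotation structure: the *cyclic*
  dipeptide sum is rotation-invariant, and rotation k omits exactly one
  adjacent pair of the cycle, so
  `II_k = (10/L)(S_cyc − DIWV(omitted pair))`. Most dipeptide weights are
  the neutral value 1.0, which is why ten of the thirteen W5K rotations
  share the same instability index; the tests exercise this identity with
  a brute-force cyclic-sum oracle on random sequences.
* **Net charge** defaults to the formal model
  (`#K + #R − #D − #E`, His counted below pH 6, ±1 for free termini); a
  Henderson–Hasselbalch titration model with the EMBOSS pKa set is
  available when a real-valued expectation at arbitrary pH is wanted. The
  formal model is the one that matches the "+7" convention of design
  tables.
* **Molecular weight** sums average residue masses plus water, +42.037 Da
  for acetylation and −0.985 Da for amidation. For the Ac/NH2 13-mer
  parent this gives ≈1840.3 Da (≈1.84 kDa).

All descriptors are computed and stored at full precision. Published-table
comparisons round half-up (2 d.p. for `<H>`, `<μH>`, AI, II; 3 d.p. for
GRAVY; 1 d.p. for GM/TI) only at the presentation layer
(`round_half_up()`, the CSV writers).

## Censored MIC analysis

Broth-microdilution MICs live on a descending two-fold grid (50, 25, 12.5,
6.25, 3.13, 1.56, 0.78 µg/mL); a strain untouched at the top concentration
is recorded as the censored cell `">50"`. `geometric_mean_mic()` implements
the standard panel summary `exp(mean(log c))` with censored cells replaced
by a fixed substitute, 100 µg/mL by convention (one two-fold step above the
top tested concentration). The substitute is configurable but deliberately
defaulted: it is part of the summary's definition, not a tuning knob.
`gm_by_gram()` stratifies the summary into Gram-negative, Gram-positive and
combined columns.

`compare_to_parent()` reports, per cell, the MIC ratio to the parent and
its log2 (dilution steps) — published prose about "n-fold differences" is
ambiguous between the two, so both are always reported — plus the bolding
rule of published permutation tables (`at_or_below_parent`), under which a
censored cell can never qualify.

## HC10 and the therapeutic index

HC10 is the lowest concentration producing 10% hemolysis.
`estimate_hc10()` returns a measured point that hits the threshold exactly;
otherwise it interpolates the first upward crossing linearly in
log10(concentration), the natural scale for a serial-dilution curve. A
curve that never reaches the threshold returns the assay cap
(108.7 µg/mL, the 200 µM top concentration for a ≈1.84 kDa peptide) with a
`censored` flag that propagates into the report. Non-monotone curves are
resolved by the first upward crossing and flagged rather than refused. The
estimator is validated two ways: against the closed-form inverse of the
generating logistic, `HC50 · 9^{−1/hill}`, on noiseless synthetic curves
(agreement within one two-fold grid step), and against a brute-force dense
scan of the same interpolant.

The therapeutic index is `TI = HC10 / GM`; larger is more selective for
bacteria over host cells. `ti_report()` assembles the full selectivity
table. Reconstructing the published W5K table from its MIC panel and HC10
column reproduces all 39 GM cells exactly at 1 d.p. and 38 of 39 TI cells;
the one remaining cell (the parent's Gram-negative TI) is indeterminate at
the inputs' precision — the HC10 inputs are printed at 1 d.p., and the
unrounded ratio sits on a rounding boundary, so the tests require TI cells
to agree within one printed ulp (0.1) and at most one cell to differ at
all.

Unit discipline: the MIC pipeline is µg/mL throughout. µM↔µg/mL conversion
always requires an explicit molecular weight and is never implicit.

## The synthetic generator

No raw assay data are published, so the generators emulate the assays'
*structure* for testing:

* `gen_mic_panel()` draws a replicate deviation that is Gaussian in
  log2-dilution space (`replicate_sd` in two-fold steps, default 0.5 —
  the usual within-one-step reproducibility of microdilution assays),
  then reports the smallest grid concentration at or above the noisy MIC;
  values above the grid top become censored cells, exactly as an
  endpoint-read plate would record them.
* `gen_hemolysis_curve()` / `gen_leakage_curve()` produce
  `100/(1 + (HC50/c)^hill)` plus additive Gaussian noise (default sd 2%),
  truncated to [0, 100]; the default Hill slope of 2 gives the saturating
  sigmoid shape typical of membrane-lysis curves, and the default dose
  grid is a two-fold series from 108.7 µg/mL, mirroring the hemolysis
  assay's top concentration. The leakage generator emits raw fluorescence
  together with its intact-vesicle and full-release controls, so
  `leakage_percent()` must be applied before any curve summary — the same
  order of operations as the real assay.
* One global seed fans out to per-assay substreams keyed by assay and
  label, so adding a generator never perturbs another's draws, and equal
  seeds give bit-identical tables.

What the generators deliberately do **not** model: inoculum effects,
strain-specific noise structure, plate position effects, cooperative
(super-Hill) lysis, or any mechanistic membrane binding. Passing recovery
tests therefore demonstrates that the *analysis* is correct and stable
under dilution-grid quantisation and modest noise — not that real assays
will match the generator's error model.

`recovery_suite()` runs the whole loop — generate, parse, geometric means,
HC10, TI — on a compact default truth (three peptides spanning potent to
weak, six strains split by Gram stain; sizes chosen so the suite runs in
seconds) and checks GM within one dilution step, HC10 within one log-grid
step of the analytic inverse, and TI within the product of those
tolerances.

## Numerical and design choices

* Half-up decimal rounding everywhere a printed table is matched; base R's
  round-half-even is never used for presentation.
* The HC10 interpolation scale (log-concentration) and tie-break (first
  upward crossing) are choices; published tables only pin the exact-hit
  and cap cases, and the synthetic closed-form oracle covers the rest.
* A curve already above threshold at its lowest tested dose reports that
  dose (the smallest *observed* concentration reaching the threshold)
  rather than extrapolating below the data.
* The wheel step δ is a parameter (degenerate inputs δ ≤ 0 are refused);
  100° is the α-helix default, and for L = 13 the 13 angles are pairwise
  distinct, so the parent panel has no angular collisions.
* Degenerate inputs are errors, not warnings: empty MIC vectors,
  non-positive concentrations, equal blank/full-lysis controls,
  non-increasing dose grids, unknown Gram labels.

## Known limitations

* The instability table and hydrophobicity scales are fixed published
  assets; no provision is made for user-supplied dipeptide weights beyond
  passing a replacement matrix to `instability_index()`.
* HC10 values for the published panel are consumed as inputs (their raw
  dose-response curves are not published); the estimator is validated on
  synthetic curves only.
* Secondary-structure content, wound-closure image analysis and any
  statistical hypothesis testing are out of scope; wound areas enter only
  through the arithmetic `repair_rate()`.
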