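# Physicochemical descriptors.
#
# Composition descriptors (GRAVY, mean hydrophobicity, aliphatic index,
# net charge, molecular weight) are invariant under cyclic permutation;
# the helical-wheel hydrophobic moment and the Guruprasad instability index
# depend on residue order and are what distinguishes rotations.

.seq_chars <- function(sequence) strsplit(toupper(sequence), "")

.check_residues <- function(chars_list, sequence) {
  for (i in seq_along(chars_list)) {
    bad <- which(!chars_list[[i]] %in% AA_CODES)
    if (length(bad) > 0) {
      abort(paste0("invalid residue '", chars_list[[i]][bad[1]],
                   "' at position ", bad[1], " of '", sequence[[i]], "'"))
    }
  }
  invisible(chars_list)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over the sequence.
#'
#' @param sequence Character vector of one-letter sequences.
#' @return Numeric vector of GRAVY values (dimensionless).
#' @examples
#' gravy("KKWRKWLKWLAKK") # -1.631 at 3 d.p.
#' @export
gravy <- function(sequence) {
  mean_hydrophobicity(sequence, scale = "KD")
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of residue hydrophobicities on a chosen scale. The
#' default Fauchere-Pliska scale is the one used by helical-wheel web
#' calculators for the `<H>` column of AMP design tables.
#'
#' @inheritParams gravy
#' @param scale Scale identifier passed to [hydrophobicity_scale()], or a
#'   named numeric vector over the 20 residue codes.
#' @return Numeric vector (dimensionless).
#' @examples
#' mean_hydrophobicity("KKWRKWLKWLAKK") # 0.27 at 2 d.p.
#' @export
mean_hydrophobicity <- function(sequence, scale = "FP") {
  sc <- if (is.character(scale)) hydrophobicity_scale(scale) else scale
  chars <- .check_residues(.seq_chars(sequence), sequence)
  vapply(chars, function(ch) mean(sc[ch]), numeric(1))
}

#' Helical-wheel hydrophobic moment
#'
#' Magnitude of the vector sum of per-residue hydrophobicities placed at
#' `delta_deg` increments around a helical wheel, normalised by sequence
#' length:
#' `muH = (1/N) * sqrt((sum H_i cos(i*delta))^2 + (sum H_i sin(i*delta))^2)`
#' with the first residue at angle 0 (i = 0..N-1). This is the standard
#' amphipathicity measure for alpha-helical AMPs.
#'
#' @inheritParams mean_hydrophobicity
#' @param delta_deg Angular step per residue, degrees (100 for an
#'   alpha-helix).
#' @return Numeric vector, non-negative (dimensionless).
#' @examples
#' hydrophobic_moment("KKWRKWLKWLAKK") # 0.72 at 2 d.p.
#' hydrophobic_moment("LKWLAKKKKWRKW") # 0.28 at 2 d.p.
#' @export
hydrophobic_moment <- function(sequence, scale = "FP", delta_deg = 100) {
  if (delta_deg <= 0) abort("delta_deg must be positive")
  sc <- if (is.character(scale)) hydrophobicity_scale(scale) else scale
  chars <- .check_residues(.seq_chars(sequence), sequence)
  vapply(chars, function(ch) {
    n <- length(ch)
    if (n == 0) abort("empty sequence")
    ang <- (seq_len(n) - 1) * delta_deg * pi / 180
    h <- sc[ch]
    sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / n
  }, numeric(1))
}

#' Aliphatic index
#'
#' Ikai's relative volume of aliphatic side chains:
#' `AI = 100 * X_A + 290 * X_V + 390 * (X_I + X_L)` with `X` the mole
#' fractions of Ala, Val, Ile and Leu.
#'
#' @inheritParams gravy
#' @return Numeric vector, non-negative (dimensionless).
#' @examples
#' aliphatic_index("KKWRKWLKWLAKK") # 67.69 at 2 d.p.
#' @export
aliphatic_index <- function(sequence) {
  chars <- .check_residues(.seq_chars(sequence), sequence)
  vapply(chars, function(ch) {
    n <- length(ch)
    100 * sum(ch == "A") / n + 290 * sum(ch == "V") / n +
      390 * (sum(ch == "I") + sum(ch == "L")) / n
  }, numeric(1))
}

#' Guruprasad instability index
#'
#' `II = (10/L) * sum over the L-1 adjacent dipeptides of their DIWV
#' weight` (Guruprasad et al. 1990). Computed on the bare sequence;
#' terminal modifications are ignored, matching the ProtParam-style web
#' calculators. Peptides with `II < 40` are conventionally called stable.
#'
#' @inheritParams gravy
#' @param table Dipeptide weight matrix; defaults to the bundled
#'   [diwv_table()].
#' @return Numeric vector (dimensionless).
#' @examples
#' instability_index("KKWRKWLKWLAKK") # 21.68 at 2 d.p.
#' instability_index("KWLAKKKKWRKWL") # 28.22 at 2 d.p.
#' @export
instability_index <- function(sequence, table = diwv_table()) {
  chars <- .check_residues(.seq_chars(sequence), sequence)
  vapply(chars, function(ch) {
    L <- length(ch)
    if (L < 2) abort("instability index needs length >= 2")
    idx <- cbind(ch[-L], ch[-1])
    10 / L * sum(table[idx])
  }, numeric(1))
}

#' Net charge
#'
#' Formal model (default): `z = #K + #R + (#H if pH < 6) - #D - #E`, plus 1
#' for a free N-terminus and minus 1 for a free C-terminus; acetylation and
#' amidation remove the respective terminal charge. The `"titration"` model
#' instead returns the Henderson-Hasselbalch expected charge at the given
#' pH using the EMBOSS pKa set.
#'
#' @inheritParams gravy
#' @param nterm,cterm Terminal states, `"free"`/`"acetyl"` and
#'   `"free"`/`"amide"` (recycled).
#' @param model `"formal"` (integer charge) or `"titration"` (real-valued).
#' @param pH Solution pH (used by both models; the formal model only counts
#'   histidine below pH 6).
#' @return Numeric vector (integer-valued for the formal model).
#' @examples
#' net_charge("KKWRKWLKWLAKK", nterm = "acetyl", cterm = "amide") # +7
#' @export
net_charge <- function(sequence, nterm = "free", cterm = "free",
                       model = c("formal", "titration"), pH = 7.4) {
  model <- match.arg(model)
  chars <- .check_residues(.seq_chars(sequence), sequence)
  nterm <- rep_len(nterm, length(chars))
  cterm <- rep_len(cterm, length(chars))
  vapply(seq_along(chars), function(i) {
    ch <- chars[[i]]
    if (model == "formal") {
      z <- sum(ch == "K") + sum(ch == "R") - sum(ch == "D") - sum(ch == "E")
      if (pH < 6) z <- z + sum(ch == "H")
      z + (nterm[i] == "free") - (cterm[i] == "free")
    } else {
      pos <- sum(vapply(c("K", "R", "H"), function(a) {
        sum(ch == a) / (1 + 10^(pH - .PKA$basic[[a]]))
      }, numeric(1)))
      if (nterm[i] == "free") {
        pos <- pos + 1 / (1 + 10^(pH - .PKA$basic[["Nterm"]]))
      }
      neg <- sum(vapply(c("D", "E", "C", "Y"), function(a) {
        sum(ch == a) / (1 + 10^(.PKA$acidic[[a]] - pH))
      }, numeric(1)))
      if (cterm[i] == "free") {
        neg <- neg + 1 / (1 + 10^(.PKA$acidic[["Cterm"]] - pH))
      }
      pos - neg
    }
  }, numeric(1))
}

#' Average molecular weight
#'
#' Sum of average residue masses plus one water, with +42.037 Da for
#' N-terminal acetylation and -0.985 Da for C-terminal amidation.
#'
#' @inheritParams net_charge
#' @return Numeric vector, Daltons.
#' @examples
#' molecular_weight("G", nterm = "free", cterm = "free") # glycine, ~75.07
#' @export
molecular_weight <- function(sequence, nterm = "free", cterm = "free") {
  chars <- .check_residues(.seq_chars(sequence), sequence)
  nterm <- rep_len(nterm, length(chars))
  cterm <- rep_len(cterm, length(chars))
  vapply(seq_along(chars), function(i) {
    mw <- sum(.RESIDUE_MASS[chars[[i]]]) + .MASS_WATER
    if (nterm[i] == "acetyl") mw <- mw + .MASS_ACETYL
    if (cterm[i] == "amide") mw <- mw + .MASS_AMIDE
    mw
  }, numeric(1))
}

#' Descriptor table for a peptide library
#'
#' Computes the full descriptor set for every row of a peptide table:
#' mean hydrophobicity `H_mean` (FP), hydrophobic moment `muH`, `gravy`
#' (KD), aliphatic index `AI`, Guruprasad instability index `II` with its
#' `stable` call (`II < 40`), formal net `charge`, and average `MW`.
#' All values are returned at full precision; use [round_half_up()] (or
#' [write_descriptor_csv()]) when matching printed tables.
#'
#' @param tbl A peptide table (see [peptides()]) or permutation library.
#' @param scale Hydrophobicity scale for `H_mean` and `muH` (default FP).
#' @param delta_deg Helical-wheel step for `muH`, degrees.
#' @param pH pH for the formal charge model.
#' @return The input tibble with descriptor columns appended.
#' @examples
#' peptide_descriptors(w5k_library())
#' @export
peptide_descriptors <- function(tbl, scale = "FP", delta_deg = 100,
                                pH = 7.4) {
  tbl <- validate_peptides(tbl)
  mutate(
    tbl,
    H_mean = mean_hydrophobicity(.data$sequence, scale = scale),
    muH = hydrophobic_moment(.data$sequence, scale = scale,
                             delta_deg = delta_deg),
    gravy = gravy(.data$sequence),
    AI = aliphatic_index(.data$sequence),
    II = instability_index(.data$sequence),
    stable = .data$II < 40,
    charge = net_charge(.data$sequence, .data$nterm, .data$cterm, pH = pH),
    MW = molecular_weight(.data$sequence, .data$nterm, .data$cterm)
  )
}
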