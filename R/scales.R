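# Bundled physicochemical reference data.
#
# Two hydrophobicity scales are shipped: Fauchere-Pliska (FP), the scale
# behind HeliQuest-style mean hydrophobicity and helical-wheel hydrophobic
# moments, and Kyte-Doolittle (KD), the hydropathy scale behind GRAVY.
# The Guruprasad dipeptide instability weights (DIWV) live in
# inst/extdata/diwv_guruprasad1990.csv as a plain-text asset.

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Fauchere & Pliska (1983) octanol/water side-chain transfer free energies
.FP_SCALE <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

# Kyte & Doolittle (1982) hydropathy
.KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Average (isotope-abundance-weighted) residue masses, Da
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.MASS_WATER <- 18.01524
.MASS_ACETYL <- 42.0367   # H -> COCH3 on the alpha-amine
.MASS_AMIDE <- -0.9848    # OH -> NH2 on the alpha-carboxyl

# EMBOSS pKa set used by the optional titration charge model
.PKA <- list(
  basic = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
  acidic = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

#' Bundled hydrophobicity scales
#'
#' Returns one of the two residue hydrophobicity scales shipped with the
#' package: `"FP"` (Fauchere-Pliska octanol/water scale, used for mean
#' hydrophobicity and the helical-wheel hydrophobic moment) or `"KD"`
#' (Kyte-Doolittle hydropathy, used for GRAVY).
#'
#' @param name Scale identifier, `"FP"` or `"KD"`.
#' @return Named numeric vector over the 20 canonical one-letter codes.
#' @examples
#' hydrophobicity_scale("FP")[["W"]]
#' @export
hydrophobicity_scale <- function(name = c("FP", "KD")) {
  name <- match.arg(name)
  switch(name, FP = .FP_SCALE, KD = .KD_SCALE)
}

.diwv_cache <- new.env(parent = emptyenv())

#' Guruprasad dipeptide instability weights (DIWV)
#'
#' The 20 x 20 dipeptide instability weight table of Guruprasad et al.
#' (1990), as used by the ProtParam-style instability index. Rows index the
#' first residue of an adjacent pair, columns the second.
#'
#' @return A 20 x 20 numeric matrix with residue one-letter dimnames.
#' @examples
#' diwv_table()["K", "K"]
#' @export
diwv_table <- function() {
  if (is.null(.diwv_cache$diwv)) {
    path <- system.file("extdata", "diwv_guruprasad1990.csv",
                        package = "permamp", mustWork = TRUE)
    raw <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(raw[, -1])
    rownames(m) <- raw[[1]]
    storage.mode(m) <- "double"
    m <- m[AA_CODES, AA_CODES]
    .diwv_cache$diwv <- m
  }
  .diwv_cache$diwv
}
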