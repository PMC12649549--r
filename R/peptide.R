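# Peptide tables and cyclic-permutation library generation.
#
# A "peptide table" is an ordinary tibble with one row per peptide and the
# columns name, sequence, nterm, cterm. Terminal modifications are metadata
# flags, never sequence characters, so "Ac-KKW...KK-NH2" is stored as
# sequence "KKW...KK" with nterm = "acetyl", cterm = "amide".

.TERMINI_N <- c("free", "acetyl")
.TERMINI_C <- c("free", "amide")

#' Build a validated peptide table
#'
#' Constructs a tibble of peptides (one row each) and validates every entry:
#' sequences must use only the 20 canonical one-letter amino-acid codes
#' (ambiguity codes B, J, O, U, X, Z are rejected), be at least two residues
#' long, and carry a non-empty unique name.
#'
#' @param name Character vector of peptide labels.
#' @param sequence Character vector of one-letter sequences.
#' @param nterm N-terminal state, `"free"` or `"acetyl"` (recycled).
#' @param cterm C-terminal state, `"free"` or `"amide"` (recycled).
#' @return A tibble with columns `name`, `sequence`, `nterm`, `cterm`.
#' @examples
#' peptides("W5K/A9W", "KKWRKWLKWLAKK", nterm = "acetyl", cterm = "amide")
#' @export
peptides <- function(name, sequence, nterm = "free", cterm = "free") {
  tbl <- tibble(
    name = as.character(name),
    sequence = toupper(as.character(sequence)),
    nterm = rep_len(as.character(nterm), length(name)),
    cterm = rep_len(as.character(cterm), length(name))
  )
  validate_peptides(tbl)
}

#' Validate a peptide table
#'
#' Checks the invariants of a peptide table and returns it unchanged;
#' signals an error naming the offending peptide, character and position
#' otherwise.
#'
#' @param tbl A data frame with columns `name`, `sequence`, `nterm`, `cterm`.
#' @return The validated tibble (invisibly identical input).
#' @export
validate_peptides <- function(tbl) {
  tbl <- as_tibble(tbl)
  required <- c("name", "sequence", "nterm", "cterm")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("peptide table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(tbl$name) | !nzchar(tbl$name))) {
    abort("every peptide needs a non-empty name")
  }
  if (!all(tbl$nterm %in% .TERMINI_N)) {
    abort("nterm must be one of: ", paste(.TERMINI_N, collapse = ", "))
  }
  if (!all(tbl$cterm %in% .TERMINI_C)) {
    abort("cterm must be one of: ", paste(.TERMINI_C, collapse = ", "))
  }
  for (i in seq_len(nrow(tbl))) {
    seq_i <- tbl$sequence[[i]]
    if (is.na(seq_i) || nchar(seq_i) < 2) {
      abort(paste0("peptide '", tbl$name[[i]],
                   "': sequence must have length >= 2"))
    }
    chars <- strsplit(seq_i, "")[[1]]
    bad <- which(!chars %in% AA_CODES)
    if (length(bad) > 0) {
      abort(paste0("peptide '", tbl$name[[i]], "': invalid residue '",
                   chars[bad[1]], "' at position ", bad[1]))
    }
  }
  tbl
}

#' Cyclic permutation library of a parent peptide
#'
#' Generates every cyclic rotation of a parent sequence: member k
#' (k = 1..L-1) reads the parent from position k+1 around the circle, i.e.
#' has sequence `substr(parent, k+1, L)` followed by `substr(parent, 1, k)`.
#' Composition and terminal modifications are preserved; only residue order
#' changes. Rotations of a periodic parent that duplicate an earlier
#' sequence are retained and flagged, so a length-L parent always yields
#' L-1 members.
#'
#' @param parent A one-row peptide table (see [peptides()]), or a data frame
#'   whose first row is used.
#' @param member_names Optional character vector of length L-1 naming the
#'   rotations in order of start offset; defaults to `"<parent>_rot<k>"`.
#' @param include_parent If `TRUE` (default) the parent is included as the
#'   first row with `start_offset = 0` and `role = "parent"`.
#' @return A tibble with columns `name`, `sequence`, `nterm`, `cterm`,
#'   `start_offset`, `role` (`"parent"`/`"member"`), and `duplicate`
#'   (`TRUE` for rotations whose sequence already occurred at a smaller
#'   offset, parent included).
#' @examples
#' parent <- peptides("W5K/A9W", "KKWRKWLKWLAKK", "acetyl", "amide")
#' lib <- cyclic_permutations(parent)
#' nrow(dplyr::filter(lib, role == "member"))
#' @export
cyclic_permutations <- function(parent, member_names = NULL,
                                include_parent = TRUE) {
  parent <- validate_peptides(parent)[1, ]
  s <- parent$sequence
  L <- nchar(s)
  k <- seq_len(L - 1)
  rotated <- vapply(
    k,
    function(i) paste0(substr(s, i + 1, L), substr(s, 1, i)),
    character(1)
  )
  if (is.null(member_names)) {
    member_names <- sprintf("%s_rot%02d", parent$name, k)
  }
  if (length(member_names) != L - 1) {
    abort(paste0("member_names must have length ", L - 1,
                 " (one per rotation), got ", length(member_names)))
  }
  all_seq <- c(s, rotated)
  lib <- tibble(
    name = c(parent$name, member_names),
    sequence = all_seq,
    nterm = parent$nterm,
    cterm = parent$cterm,
    start_offset = c(0L, k),
    role = c("parent", rep("member", L - 1)),
    duplicate = duplicated(all_seq)
  )
  if (!include_parent) {
    lib <- filter(lib, .data$role == "member")
  }
  lib
}

#' Helical-wheel projection of peptide sequences
#'
#' Places each residue on an idealised alpha-helical wheel, advancing
#' `delta_deg` degrees per residue (100 degrees for a canonical 3.6
#' residues/turn helix). Residue i (0-based) sits at `(i * delta_deg) mod
#' 360`. The unit-vector components are returned for downstream hydrophobic
#' moment computation and plotting.
#'
#' @param tbl A peptide table (see [peptides()]).
#' @param delta_deg Angular step per residue in degrees; must be positive.
#' @return A tibble of class `wheel_projection` with columns `name`,
#'   `residue_index` (0-based), `residue`, `angle_deg` in `[0, 360)`,
#'   `cos_angle`, `sin_angle`, and `delta_deg`.
#' @examples
#' wheel <- helical_wheel(peptides("demo", "KKWRKWLKWLAKK"))
#' wheel$angle_deg[1:4]
#' @export
helical_wheel <- function(tbl, delta_deg = 100) {
  if (!is.numeric(delta_deg) || length(delta_deg) != 1 || delta_deg <= 0) {
    abort("delta_deg must be a single positive number")
  }
  tbl <- validate_peptides(tbl)
  out <- purrr::map_dfr(seq_len(nrow(tbl)), function(r) {
    chars <- strsplit(tbl$sequence[[r]], "")[[1]]
    idx <- seq_along(chars) - 1L
    ang <- (idx * delta_deg) %% 360
    tibble(
      name = tbl$name[[r]],
      residue_index = idx,
      residue = chars,
      angle_deg = ang,
      cos_angle = cos(ang * pi / 180),
      sin_angle = sin(ang * pi / 180),
      delta_deg = delta_deg
    )
  })
  class(out) <- c("wheel_projection", class(out))
  out
}

#' The W5K/A9W permutation panel
#'
#' Convenience constructor for the lysine/tryptophan-rich AMP W5K/A9W
#' (Ac-KKWRKWLKWLAKK-NH2) and its twelve published cyclic-permutation
#' derivatives W5K01..W5K12, the worked example used throughout the package
#' documentation.
#'
#' @return A permutation-library tibble as returned by
#'   [cyclic_permutations()], 13 rows.
#' @examples
#' w5k_library()$name
#' @export
w5k_library <- function() {
  parent <- peptides("W5K/A9W", "KKWRKWLKWLAKK",
                     nterm = "acetyl", cterm = "amide")
  cyclic_permutations(parent, member_names = sprintf("W5K%02d", 1:12))
}
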