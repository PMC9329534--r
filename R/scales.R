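# Per-residue physicochemical scales for the 20 standard amino acids.
#
# Masses are average residue masses (peptide-bond residues, no water term),
# fixed at 2-decimal precision so that concatemer masses are exactly linear in
# the repeat number at the reporting precision used throughout the package.
# Hydrophobicities are the Wimley-White whole-residue water-to-octanol
# transfer free energies (kcal/mol; positive disfavours octanol). pKa values
# follow the Bjellqvist/ProtParam convention: a single C-terminal carboxyl
# pKa, residue-specific N-terminal amine pKa values, and standard side-chain
# pKa values for the seven ionizable residues.

.aa_codes <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_mass <- c(
  A = 71.08,  R = 156.19, N = 114.10, D = 115.09, C = 103.14,
  E = 129.12, Q = 128.13, G = 57.05,  H = 137.14, I = 113.16,
  L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
  S = 87.08,  T = 101.10, W = 186.21, Y = 163.18, V = 99.13
)

.ww_octanol_scale <- c(
  A = 0.50,  R = 1.81,  N = 0.85,  D = 3.64,  C = -0.02,
  E = 3.63,  Q = 0.77,  G = 1.15,  H = 2.33,  I = -1.12,
  L = -1.25, K = 2.80,  M = -0.67, F = -1.71, P = 0.14,
  S = 0.46,  T = 0.25,  W = -2.09, Y = -0.71, V = -0.46
)

# Side-chain pKa (NA = not ionizable). Charge sign: positive for R/K/H,
# negative for D/E/C/Y.
.pka_side <- c(
  A = NA, R = 12.0, N = NA, D = 4.05, C = 9.0,
  E = 4.45, Q = NA, G = NA, H = 5.98, I = NA,
  L = NA, K = 10.0, M = NA, F = NA, P = NA,
  S = NA, T = NA, W = NA, Y = 10.0, V = NA
)

.pka_side_sign <- c(
  A = 0, R = 1, N = 0, D = -1, C = -1,
  E = -1, Q = 0, G = 0, H = 1, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0,
  S = 0, T = 0, W = 0, Y = -1, V = 0
)

# N-terminal amine pKa depends on the identity of the first residue.
.pka_nterm <- c(
  A = 7.59, R = 7.50, N = 7.50, D = 7.50, C = 7.50,
  E = 7.70, Q = 7.50, G = 7.50, H = 7.50, I = 7.50,
  L = 7.50, K = 7.50, M = 7.00, F = 7.50, P = 8.36,
  S = 6.93, T = 6.82, W = 7.50, Y = 7.50, V = 7.44
)

.pka_cterm <- 3.55

# Bondi-type van der Waals radii by element (Angstrom), used for SASA.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.vdw_default <- 1.70

#' Residue-level physicochemical scale table
#'
#' Returns the per-residue scales the package computes with: average residue
#' mass (Da, 2-decimal convention so concatemer masses are exactly additive),
#' Wimley-White water-to-octanol transfer free energy (kcal/mol), side-chain
#' pKa with its charge sign where the side chain is ionizable, and the
#' N-terminal amine pKa used when the residue is first in a peptide. The
#' single C-terminal carboxyl pKa (3.55) is attached as the `pka_cterm`
#' attribute.
#'
#' @return A tibble with one row per standard residue and columns `residue`,
#'   `mass_da`, `ww_octanol`, `pka_side`, `side_charge_sign`, `pka_nterm`.
#' @examples
#' aa_scales()
#' @export
aa_scales <- function() {
  out <- tibble::tibble(
    residue = .aa_codes,
    mass_da = unname(.aa_mass[.aa_codes]),
    ww_octanol = unname(.ww_octanol_scale[.aa_codes]),
    pka_side = unname(.pka_side[.aa_codes]),
    side_charge_sign = unname(.pka_side_sign[.aa_codes]),
    pka_nterm = unname(.pka_nterm[.aa_codes])
  )
  attr(out, "pka_cterm") <- .pka_cterm
  out
}

# Splits a one-letter sequence into residues, failing loudly on anything
# outside the 20 standard codes (the offending character is named).
split_residues <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort(sprintf("`%s` must be a single non-empty character string.", arg))
  }
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), .aa_codes)
  if (length(bad) > 0L) {
    abort(sprintf(
      "`%s` contains non-standard residue code%s: %s",
      arg, if (length(bad) > 1L) "s" else "", paste0("'", bad, "'", collapse = ", ")
    ))
  }
  res
}

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}
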