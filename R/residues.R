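#' Amino-acid physicochemical categories
#'
#' The twenty standard amino acids partitioned into three categories used
#' throughout the site analyses: charged (DEKR), hydrophobic (LVWIFMPC) and
#' weakly hydrophobic / polar (AGNQSTHY). The partition is total and
#' disjoint: 4 + 8 + 8 = 20 residues.
#'
#' @format Named character vector mapping one-letter residue codes to one of
#'   `"charged"`, `"hydrophobic"`, `"weak_polar"`.
#' @export
residue_categories <- c(
  D = "charged", E = "charged", K = "charged", R = "charged",
  L = "hydrophobic", V = "hydrophobic", W = "hydrophobic", I = "hydrophobic",
  F = "hydrophobic", M = "hydrophobic", P = "hydrophobic", C = "hydrophobic",
  A = "weak_polar", G = "weak_polar", N = "weak_polar", Q = "weak_polar",
  S = "weak_polar", T = "weak_polar", H = "weak_polar", Y = "weak_polar"
)

#' Theoretical maximum solvent-accessible surface areas
#'
#' Per-residue theoretical maximum SASA values (Angstrom^2) from Tien et al.
#' (2013, PLoS ONE 8:e80635), used as the denominator of relative solvent
#' accessibility, RSA = SASA / MaxSASA.
#'
#' @format Named numeric vector, one positive entry per standard amino acid.
#' @export
max_sasa_tien2013 <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  E = 223, Q = 225, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174
)

#' Classify a residue into charged / hydrophobic / weak-polar
#'
#' @param aa Character vector of one-letter amino-acid codes (case
#'   insensitive).
#' @return Character vector of categories (`"charged"`, `"hydrophobic"`,
#'   `"weak_polar"`).
#' @examples
#' classify_residue(c("K", "M", "S"))
#' @export
classify_residue <- function(aa) {
  aa <- toupper(as.character(aa))
  bad <- !aa %in% names(residue_categories)
  if (any(bad)) {
    stop("not a standard amino acid: ", paste(unique(aa[bad]), collapse = ", "))
  }
  unname(residue_categories[aa])
}

#' Relative solvent accessibility
#'
#' Computes RSA = SASA / MaxSASA(residue). Values above 1 are allowed (a
#' residue can exceed the theoretical maximum in extended conformations) but
#' flagged with a warning.
#'
#' @param sasa Numeric vector of solvent-accessible surface areas
#'   (Angstrom^2), non-negative.
#' @param residue Character vector of one-letter residue codes (recycled
#'   against `sasa`).
#' @param max_sasa Named numeric lookup of per-residue maxima; defaults to
#'   [max_sasa_tien2013].
#' @return Numeric vector of RSA values (dimensionless, >= 0).
#' @export
compute_rsa <- function(sasa, residue, max_sasa = max_sasa_tien2013) {
  residue <- toupper(as.character(residue))
  bad <- !residue %in% names(max_sasa)
  if (any(bad)) {
    stop("no MaxSASA entry for residue: ",
         paste(unique(residue[bad]), collapse = ", "))
  }
  if (any(sasa < 0, na.rm = TRUE)) stop("sasa must be non-negative")
  rsa <- sasa / unname(max_sasa[residue])
  if (any(rsa > 1, na.rm = TRUE)) {
    warning(sum(rsa > 1, na.rm = TRUE),
            " RSA value(s) exceed 1 (SASA above the theoretical maximum)")
  }
  rsa
}
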