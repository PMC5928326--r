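## Periodic (proper) dihedral potentials in the GROMOS functional form
## V(phi) = sum_n k_n (1 + cos(n phi - phi0)), phi0 in {0, 180} deg, and
## their linear least-squares fit to a QM-minus-MM torsion energy profile.

#' Construct a torsion energy profile
#'
#' @param angles Dihedral angles in degrees, strictly increasing within one
#'   360-degree period (a 30-degree scan grid is typical).
#' @param energies Energies in kJ/mol, same length as `angles`.
#' @param zero_convention `"raw"` or `"min_shifted"`.
#' @return Object of class `torsion_profile`.
#' @export
torsion_profile <- function(angles, energies, zero_convention = "raw") {
  angles <- as.numeric(angles); energies <- as.numeric(energies)
  if (length(angles) != length(energies))
    stop("angles and energies must have the same length")
  if (any(diff(angles) <= 0)) stop("angles must be strictly increasing")
  if (diff(range(angles)) >= 360)
    stop("angle grid must span at most one period (360 degrees)")
  structure(list(angles = angles, energies = energies,
                 zero_convention = zero_convention),
            class = "torsion_profile")
}

#' Construct a set of periodic dihedral terms
#'
#' @param k Force constants k_n in kJ/mol (must be >= 0).
#' @param n Integer multiplicities in 1..6, unique.
#' @param phase Phases phi0 in degrees, each 0 or 180.
#' @return Object of class `dihedral_params` (data.frame of terms).
#' @export
dihedral_params <- function(k = numeric(0), n = integer(0),
                            phase = numeric(0)) {
  if (length(unique(n)) != length(n)) stop("multiplicities must be unique")
  if (any(k < 0)) stop("force constants must be non-negative")
  if (!all(n %in% 1:6)) stop("multiplicities must lie in 1..6")
  if (!all(phase %in% c(0, 180))) stop("phases must be 0 or 180 degrees")
  structure(data.frame(k = as.numeric(k), n = as.integer(n),
                       phase = as.numeric(phase)),
            class = c("dihedral_params", "data.frame"))
}

#' Evaluate a periodic dihedral potential
#'
#' V(phi) = sum_n k_n (1 + cos(n phi - phi0)), exact and periodic in 360.
#'
#' @param params A [dihedral_params()].
#' @param phi Dihedral angle(s) in degrees.
#' @return Energy in kJ/mol, vectorized over `phi`.
#' @export
evaluate_dihedral <- function(params, phi) {
  if (!nrow(params)) return(rep(0, length(phi)))
  rad <- pi / 180
  vapply(phi, function(p)
    sum(params$k * (1 + cos((params$n * p - params$phase) * rad))),
    numeric(1))
}

#' Fit periodic dihedral terms to a QM-minus-MM torsion profile
#'
#' The target and the MM background profile (computed externally with the
#' fitted dihedral zeroed) are each min-shifted to zero, subtracted, and the
#' difference is fit by ordinary linear least squares onto the basis
#' cos(n phi) for the requested multiplicities plus an intercept. A negative
#' cosine coefficient is expressed as a positive force constant with the
#' opposite (180-degree) phase, keeping every term GROMOS-legal. The
#' intercept absorbs the (unphysical) constant offset and is reported, not
#' fitted into the terms.
#'
#' @param target [torsion_profile()] of the QM scan.
#' @param mm_background [torsion_profile()] on the same angle grid.
#' @param multiplicities Integer set of multiplicities to include
#'   (default `c(1, 2, 3, 6)`).
#' @return List with `params` ([dihedral_params()]), `rmsd` (kJ/mol, on the
#'   grid between the min-shifted difference and the min-shifted fitted
#'   curve) and `offset` (the fitted intercept, kJ/mol).
#' @export
fit_torsion <- function(target, mm_background = NULL,
                        multiplicities = c(1, 2, 3, 6)) {
  if (is.null(mm_background))
    mm_background <- torsion_profile(target$angles,
                                     rep(0, length(target$angles)))
  if (length(target$angles) != length(mm_background$angles) ||
      any(abs(target$angles - mm_background$angles) > 1e-9))
    stop("target and background profiles must share the same angle grid")
  multiplicities <- sort(unique(as.integer(multiplicities)))
  if (!all(multiplicities %in% 1:6))
    stop("multiplicities must lie in 1..6")
  y <- (target$energies - min(target$energies)) -
       (mm_background$energies - min(mm_background$energies))
  if (length(y) < length(multiplicities) + 1L)
    stop("profile has too few points for ", length(multiplicities),
         " multiplicities")
  rad <- pi / 180
  X <- cbind(1, vapply(multiplicities,
                       function(n) cos(n * target$angles * rad),
                       numeric(length(y))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design matrix: angle grid cannot resolve the requested ",
         "multiplicities")
  beta <- qr.coef(qrX, y)
  cn <- beta[-1]
  keep <- abs(cn) > 0
  params <- dihedral_params(k = abs(cn[keep]),
                            n = multiplicities[keep],
                            phase = ifelse(cn[keep] >= 0, 0, 180))
  fitted <- evaluate_dihedral(params, target$angles)
  resid <- (y - min(y)) - (fitted - min(fitted))
  list(params = params,
       rmsd = sqrt(mean(resid^2)),
       offset = unname(beta[1]))
}

#' Classify whether a dihedral's rotamer population is localized or spread
#'
#' Scans the fitted potential on a 1-degree grid; if the highest barrier
#' (max minus min) is below 2.5 kJ/mol -- roughly kT at room temperature --
#' thermal motion carries the dihedral across it freely and the rotamer
#' distribution is classified as `"spread"`, otherwise `"localized"`.
#'
#' @param params A [dihedral_params()].
#' @param kT Thermal energy in kJ/mol (default 2.479, 298.15 K); recorded
#'   for context, the 2.5 kJ/mol decision threshold itself is fixed.
#' @return `"localized"` or `"spread"`, with attributes `barrier` (kJ/mol).
#' @export
classify_rotamer_spread <- function(params, kT = 2.479) {
  grid <- seq(0, 359, by = 1)
  v <- evaluate_dihedral(params, grid)
  barrier <- max(v) - min(v)
  out <- if (barrier < 2.5) "spread" else "localized"
  attr(out, "barrier") <- barrier
  out
}

#' Format dihedral terms as ITP parameter lines
#'
#' One `[dihedrals]`-style parameter line per term
#' (`ai aj ak al funct phi0 k n`, funct 1).
#'
#' @param params A [dihedral_params()].
#' @param atoms Length-4 integer vector of atom indices (default 1:4).
#' @return Character vector of ITP lines.
#' @export
format_dihedral_itp <- function(params, atoms = 1:4) {
  vapply(seq_len(nrow(params)), function(i)
    sprintf("%4d %4d %4d %4d  1  %8.2f %10.5f %d",
            atoms[1], atoms[2], atoms[3], atoms[4],
            params$phase[i], params$k[i], params$n[i]),
    character(1))
}
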