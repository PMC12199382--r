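#' Reduction potential from the Nernst relation
#'
#' Converts a disulfide reduction free energy to a reduction potential:
#' `E = -dG / (n F)` with `F = 96.485 kJ mol^-1 V^-1`, reported in mV.
#'
#' @param dG free energy difference between reduced and oxidized states,
#'   kJ/mol.
#' @param n number of electrons transferred (disulfide reduction: 2).
#' @return Potential in mV.
#' @export
#' @examples
#' nernstPotential(19.297)  # -100 mV
nernstPotential <- function(dG, n = 2L) {
  if (any(n <= 0)) stop("n must be a positive integer", call. = FALSE)
  -dG / (n * 96.485) * 1000
}

#' Empirically corrected reduction potential
#'
#' Applies the affine calibration `E_corr = 1.5 * E_cal - 43` (mV) that
#' maps calculated reduction potentials onto the experimental scale.
#'
#' @param eCal calculated potential, mV.
#' @return Corrected potential, mV.
#' @export
#' @examples
#' correctedPotential(-137.1)  # -248.65
correctedPotential <- function(eCal) 1.5 * eCal - 43

#' Classify disulfide reduction propensity
#'
#' Disulfides with corrected potentials below -330 mV stabilise the
#' fold; potentials in the -330 to -89 mV band mark bonds prone to
#' enzymatic reduction. The boundary value -330 mV is assigned to the
#' risk class (conservative flagging), and values above -89 mV are
#' additionally marked highly labile.
#'
#' @param eCorr corrected potential(s), mV.
#' @param stableBelow stabilising threshold, mV (default -330).
#' @param labileAbove highly-labile threshold, mV (default -89).
#' @return character vector `"stabilizing"`/`"reduction-prone"` with a
#'   logical `highly_labile` attribute.
#' @export
#' @examples
#' classifyRedox(c(-248.7, -434.8))
classifyRedox <- function(eCorr, stableBelow = -330, labileAbove = -89) {
  cls <- ifelse(eCorr < stableBelow, "stabilizing", "reduction-prone")
  attr(cls, "highly_labile") <- eCorr > labileAbove
  cls
}

#' Redox classification table for disulfide bonds
#'
#' Takes a table of disulfide bonds with free energies and/or calculated
#' potentials, fills in the missing potential column via
#' [nernstPotential()], applies the empirical correction and the
#' propensity classification. When an `E_cal_mV` column is present it is
#' used as-is (externally computed potentials pass through unchanged).
#'
#' @param table `data.frame` with columns `bond_label` and `dG_kJ_mol`
#'   and/or `E_cal_mV`; an optional `resno` column is carried through.
#' @param n electrons transferred (default 2).
#' @param stableBelow,labileAbove classification thresholds, mV.
#' @return The input with added columns `E_cal_mV` (if derived),
#'   `E_corr_mV`, `classification`, `highly_labile`.
#' @export
#' @examples
#' redoxTable(data.frame(bond_label = "C130-C130", E_cal_mV = -137.1))
redoxTable <- function(table, n = 2L, stableBelow = -330, labileAbove = -89) {
  if (!"bond_label" %in% names(table))
    stop("table must have a bond_label column", call. = FALSE)
  if (!"E_cal_mV" %in% names(table)) {
    if (!"dG_kJ_mol" %in% names(table))
      stop("table needs dG_kJ_mol and/or E_cal_mV", call. = FALSE)
    table$E_cal_mV <- nernstPotential(table$dG_kJ_mol, n)
  } else if ("dG_kJ_mol" %in% names(table)) {
    miss <- is.na(table$E_cal_mV)
    table$E_cal_mV[miss] <- nernstPotential(table$dG_kJ_mol[miss], n)
  }
  table$E_corr_mV <- correctedPotential(table$E_cal_mV)
  cls <- classifyRedox(table$E_corr_mV, stableBelow, labileAbove)
  table$classification <- as.character(cls)
  table$highly_labile <- attr(cls, "highly_labile")
  table
}
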