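# Reference tables used across the package. All are exposed through small
# accessor functions so analyses can substitute their own tables; the
# constants themselves are internal.

# Bondi-style van der Waals radii (Angstrom) by element.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)
.VDW_DEFAULT <- 1.70

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(.AA1) <- .AA3
.AA3_FROM_1 <- structure(.AA3, names = .AA1)

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Van der Waals radius lookup
#'
#' Returns the bundled per-element van der Waals radius table (Angstrom).
#' Elements missing from the table fall back to the carbon radius.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdwRadii()[["S"]]
vdwRadii <- function() .VDW_RADII

# Theoretical maximum accessible surface areas per residue type (Angstrom^2),
# Tien et al. (2013) theoretical values. Used as the denominator of relative
# SASA. The Met entry is overridable (see maxASARef) so that absolute/percent
# SASA pairs quoted for Met-containing antibodies can be reproduced with the
# implied reference of 231.7 A^2.
.MAX_ASA_TIEN <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Reference fully-exposed residue SASA table
#'
#' Theoretical maximum accessible surface areas per residue type, used as
#' the denominator when converting absolute residue SASA to percent
#' exposure.
#'
#' @param met Reference value for methionine. The default `231.7` is the
#'   value implied by published absolute/percent SASA pairs for antibody
#'   methionines (47.5 Angstrom^2 at 20.5 percent); set to `NULL` to keep
#'   the theoretical value of 224.0.
#' @return Named numeric vector, Angstrom^2.
#' @export
#' @examples
#' maxASARef()[["MET"]]
maxASARef <- function(met = 231.7) {
  tab <- .MAX_ASA_TIEN
  if (!is.null(met)) tab[["MET"]] <- met
  tab
}

# Black & Mould (1991) relative hydrophobicity, 0..1 scale.
.BLACK_MOULD <- c(
  ALA = 0.616, ARG = 0.000, ASN = 0.236, ASP = 0.028, CYS = 0.680,
  GLN = 0.251, GLU = 0.043, GLY = 0.501, HIS = 0.165, ILE = 0.943,
  LEU = 0.943, LYS = 0.283, MET = 0.738, PHE = 1.000, PRO = 0.711,
  SER = 0.359, THR = 0.450, TRP = 0.878, TYR = 0.880, VAL = 0.825)

#' Residue hydrophobicity scale for SAP
#'
#' Black & Mould relative hydrophobicities shifted so that glycine scores
#' exactly zero, the normalisation used by the spatial aggregation
#' propensity method: hydrophobic residues are positive, hydrophilic
#' residues negative.
#'
#' @return Named numeric vector over the 20 standard residue types.
#' @export
#' @examples
#' sapHydrophobicityScale()[["GLY"]]  # 0
sapHydrophobicityScale <- function() .BLACK_MOULD - .BLACK_MOULD[["GLY"]]

# EMBOSS-style intrinsic pKa values.
.PKA_SETS <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
)

#' Intrinsic pKa sets
#'
#' @param name Name of the bundled set; currently `"emboss"`.
#' @return Named numeric vector of pKa values for the ionizable side
#'   chains (one-letter codes) plus `Nterm`/`Cterm`.
#' @export
#' @examples
#' pkaSet("emboss")
pkaSet <- function(name = "emboss") {
  if (!name %in% names(.PKA_SETS))
    stop("unknown pKa set: ", name, call. = FALSE)
  .PKA_SETS[[name]]
}

# Simplified per-atom hydrophobicity used for surface patch detection:
# side-chain carbons not bonded to N/O are positive (aliphatic 0.5,
# aromatic 0.3), sulfur slightly positive (0.1); all other atoms are
# treated as polar (negative) and never seed a hydrophobic patch.
.HYDROPHOBIC_ATOMS <- list(
  ALA = c(CB = 0.5),
  VAL = c(CB = 0.5, CG1 = 0.5, CG2 = 0.5),
  LEU = c(CB = 0.5, CG = 0.5, CD1 = 0.5, CD2 = 0.5),
  ILE = c(CB = 0.5, CG1 = 0.5, CG2 = 0.5, CD1 = 0.5),
  MET = c(CB = 0.5, CG = 0.5, SD = 0.1, CE = 0.1),
  PHE = c(CB = 0.5, CG = 0.3, CD1 = 0.3, CD2 = 0.3,
          CE1 = 0.3, CE2 = 0.3, CZ = 0.3),
  TRP = c(CB = 0.5, CG = 0.3, CD2 = 0.3, CE3 = 0.3,
          CZ2 = 0.3, CZ3 = 0.3, CH2 = 0.3),
  TYR = c(CB = 0.5, CG = 0.3, CD1 = 0.3, CD2 = 0.3, CE1 = 0.3, CE2 = 0.3),
  PRO = c(CB = 0.5, CG = 0.5),
  THR = c(CG2 = 0.5),
  LYS = c(CB = 0.5, CG = 0.5, CD = 0.5),
  ARG = c(CB = 0.5, CG = 0.5),
  GLU = c(CB = 0.5, CG = 0.5),
  GLN = c(CB = 0.5, CG = 0.5),
  ASP = c(CB = 0.5),
  ASN = c(CB = 0.5),
  HIS = c(CB = 0.5),
  CYS = c(CB = 0.5, SG = 0.1)
)

#' Atomic hydrophobicity table for patch detection
#'
#' Simplified logP-style atomic hydrophobicity contributions: side-chain
#' carbons with no bonded heteroatom are positive, aromatic carbons get a
#' smaller positive weight, sulfur a small positive weight; every other
#' atom is polar. Only atoms with a positive entry can belong to a
#' hydrophobic patch.
#'
#' @return Named list: residue type -> named numeric vector of positive
#'   atom contributions.
#' @export
hydrophobicAtomTable <- function() .HYDROPHOBIC_ATOMS

# Formal side-chain charges placed on terminal heavy atoms. Histidine
# entries are only applied when the charge model protonates histidine at
# the working pH.
.CHARGE_ATOMS <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0),
  ARG = c(NH1 = 0.5, NH2 = 0.5),
  HIS = c(ND1 = 0.5, NE2 = 0.5)
)

#' Formal charge placement table for ionic patch detection
#'
#' @return Named list: residue type -> named numeric vector of formal
#'   charges on side-chain terminal heavy atoms.
#' @export
chargeAtomTable <- function() .CHARGE_ATOMS

# Fully-exposed side-chain SASA reference (Angstrom^2) per residue type,
# precomputed with this package's own Shrake-Rupley engine (960 points,
# probe 1.4 A) on extended Gly-X-Gly tripeptides so that the numerator and
# denominator of the SAP exposure ratio come from the same engine.
# Regenerate with inst/scripts/make-sidechain-reference.R.
.SIDECHAIN_REF <- c(
  ALA = 57.24, ARG = 192.00, ASN = 105.26, ASP = 102.48, CYS = 89.83,
  GLN = 139.08, GLU = 137.06, GLY = 0, HIS = 137.91, ILE = 129.82,
  LEU = 119.50, LYS = 156.73, MET = 146.04, PHE = 157.24, PRO = 93.34,
  SER = 74.39, THR = 95.86, TRP = 196.45, TYR = 175.57, VAL = 106.30)

#' Fully-exposed side-chain SASA reference for SAP
#'
#' Side-chain solvent accessibilities of residue X in an extended
#' Gly-X-Gly tripeptide, computed with the package's own SASA engine so
#' the SAP exposure ratio is self-consistent. Glycine has no side chain
#' and scores zero.
#'
#' @return Named numeric vector, Angstrom^2.
#' @export
sidechainRefSASA <- function() .SIDECHAIN_REF

# one-letter <-> three-letter helpers (internal)
aa3to1 <- function(x) {
  out <- .AA1[x]
  if (anyNA(out)) stop("unknown residue type: ",
                       paste(unique(x[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  unname(out)
}

aa1to3 <- function(x) {
  out <- .AA3_FROM_1[x]
  if (anyNA(out)) stop("unknown residue code: ",
                       paste(unique(x[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  unname(out)
}
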