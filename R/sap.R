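#' @include sasa.R
NULL

#' Spatial aggregation propensity (SAP) per atom
#'
#' For every atom i, SAP sums over all residues having at least one
#' heavy atom within the radius (5 Angstrom, boundary inclusive):
#' the solvent accessibility of that residue's side-chain atoms lying
#' within the radius, divided by the fully-exposed side-chain
#' accessibility of the residue type, times the residue hydrophobicity
#' (Black & Mould, normalised to Gly = 0). Multi-model structures are
#' averaged model by model, so a single model gives the static value.
#'
#' @param structure a [ProteinStructure-class].
#' @param profile matching [SASAProfile-class] (default: computed here).
#' @param radius neighbourhood radius in Angstrom (default 5.0).
#' @param scale residue hydrophobicity scale, Gly-normalised
#'   (default [sapHydrophobicityScale()]).
#' @param reference fully-exposed side-chain SASA per residue type
#'   (default [sidechainRefSASA()]).
#' @return `data.frame` with the atom identity columns plus `sap`.
#' @export
#' @examples
#' s <- buildPeptide("GFG")
#' head(sapProfile(s))
sapProfile <- function(structure, profile = shrakeRupley(structure),
                       radius = 5.0, scale = sapHydrophobicityScale(),
                       reference = sidechainRefSASA()) {
  a <- structure@atoms
  n <- nrow(a)
  restype <- a$resid
  known <- restype %in% names(reference) | restype %in% names(scale)
  missing <- setdiff(unique(restype[a$type == "ATOM"]),
                     union(names(reference), names(scale)))
  if (length(missing))
    stop("no side-chain reference SASA for residue type: ",
         paste(missing, collapse = ", "), call. = FALSE)
  reskey <- paste(a$chain, a$resno, sep = "\r")
  sidechain <- !(a$name %in% .BACKBONE_ATOMS) & a$type == "ATOM"
  m <- nModels(structure)
  sap <- matrix(0, nrow = n, ncol = m)
  for (k in seq_len(m)) {
    xyz <- atomCoords(structure, k)
    sasa <- profile@sasa[, min(k, ncol(profile@sasa))]
    dm <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n)) {
      within <- dm[i, ] <= radius
      for (rk in unique(reskey[within])) {
        inres <- reskey == rk
        rt <- restype[inres][1]
        phi <- if (rt %in% names(scale)) scale[[rt]] else 0
        ref <- if (rt %in% names(reference)) reference[[rt]] else 0
        if (ref <= 0 || phi == 0) next
        num <- sum(sasa[inres & sidechain & within])
        sap[i, k] <- sap[i, k] + num / ref * phi
      }
    }
  }
  out <- a[, c("serial", "name", "element", "resno", "resid", "chain")]
  out$sap <- rowMeans(sap)
  out
}

#' SAP score over the CDRs
#'
#' Sum of all positive per-atom SAP values for atoms in CDR residues.
#'
#' @param sap `data.frame` from [sapProfile()] (columns `resno`, `sap`).
#' @param cdr CDR ranges ([IRanges::IRanges], [DomainAnnotation-class],
#'   or integer residue numbers).
#' @return Non-negative SAP score.
#' @export
#' @examples
#' s <- buildPeptide("GFGAG")
#' sapScore(sapProfile(s), cdr = IRanges::IRanges(2, 3))
sapScore <- function(sap, cdr) {
  resnos <- if (is.numeric(cdr)) as.integer(cdr) else .cdrResidues(cdr)
  if (!length(resnos)) stop("empty CDR set", call. = FALSE)
  v <- sap$sap[sap$resno %in% resnos]
  sum(v[v > 0])
}

#' Developability index
#'
#' `DI = SAP score - beta * net_charge^2` with the regressed
#' `beta = 0.0498`. Lower DI predicts lower aggregation risk; the
#' net-charge penalty is symmetric in the sign of the charge.
#'
#' @param sapScore SAP score (dimensionless).
#' @param netCharge net charge in elementary charges.
#' @param beta regression coefficient (default 0.0498).
#' @return DI value.
#' @export
#' @examples
#' developabilityIndex(10, 10)  # 10 - 0.0498 * 100 = 5.02
developabilityIndex <- function(sapScore, netCharge, beta = 0.0498) {
  sapScore - beta * netCharge^2
}
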