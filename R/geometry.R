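# Internal-coordinate geometry used by the synthetic structure builders.
# Atoms are placed NeRF-style: given three reference positions a-b-c, the
# new atom d is set at |c-d| = bond, angle(b,c,d) = angle and
# torsion(a,b,c,d) = torsion (degrees).

.placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Side-chain templates: each row places one heavy atom from three parent
# atoms of the same residue (backbone or previously placed side-chain
# atoms). Geometry is idealised (single canonical rotamer, chi ~ 180
# zig-zags, planar rings); it is deterministic, clash-free and carries the
# correct PDB atom names, which is what the scoring rules need.
.SC_ROW <- function(name, p1, p2, p3, bond, angle, torsion)
  list(name = name, p = c(p1, p2, p3), bond = bond,
       angle = angle, torsion = torsion)

.CB <- .SC_ROW("CB", "C", "N", "CA", 1.53, 110.5, -122.0)

.SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(.CB),
  SER = list(.CB, .SC_ROW("OG",  "N", "CA", "CB", 1.42, 110.5, 180)),
  CYS = list(.CB, .SC_ROW("SG",  "N", "CA", "CB", 1.81, 114.0, 180)),
  THR = list(.CB, .SC_ROW("OG1", "N", "CA", "CB", 1.42, 110.0, 180),
                  .SC_ROW("CG2", "N", "CA", "CB", 1.53, 110.0, -60)),
  VAL = list(.CB, .SC_ROW("CG1", "N", "CA", "CB", 1.53, 110.5, 180),
                  .SC_ROW("CG2", "N", "CA", "CB", 1.53, 110.5, 60)),
  LEU = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.53, 116.0, 180),
                  .SC_ROW("CD1", "CA", "CB", "CG", 1.53, 110.0, 180),
                  .SC_ROW("CD2", "CA", "CB", "CG", 1.53, 110.0, -60)),
  ILE = list(.CB, .SC_ROW("CG1", "N", "CA", "CB", 1.53, 110.5, 180),
                  .SC_ROW("CG2", "N", "CA", "CB", 1.53, 110.5, 60),
                  .SC_ROW("CD1", "CA", "CB", "CG1", 1.53, 113.0, 180)),
  MET = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.53, 114.0, 180),
                  .SC_ROW("SD",  "CA", "CB", "CG", 1.80, 112.7, 180),
                  .SC_ROW("CE",  "CB", "CG", "SD", 1.79, 100.2, 180)),
  PRO = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.49, 104.5, 30),
                  .SC_ROW("CD",  "CA", "CB", "CG", 1.51, 106.1, -35)),
  PHE = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.50, 113.8, 180),
                  .SC_ROW("CD1", "CA", "CB", "CG", 1.39, 120.8, 90),
                  .SC_ROW("CD2", "CA", "CB", "CG", 1.39, 120.8, -90),
                  .SC_ROW("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
                  .SC_ROW("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
                  .SC_ROW("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.51, 113.9, 180),
                  .SC_ROW("CD1", "CA", "CB", "CG", 1.39, 120.8, 90),
                  .SC_ROW("CD2", "CA", "CB", "CG", 1.39, 120.8, -90),
                  .SC_ROW("CE1", "CB", "CG", "CD1", 1.39, 121.2, 180),
                  .SC_ROW("CE2", "CB", "CG", "CD2", 1.39, 121.2, 180),
                  .SC_ROW("CZ",  "CG", "CD1", "CE1", 1.38, 119.6, 0),
                  .SC_ROW("OH",  "CD1", "CE1", "CZ", 1.38, 119.9, 180)),
  TRP = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.50, 113.6, 180),
                  .SC_ROW("CD1", "CA", "CB", "CG", 1.37, 126.9, 90),
                  .SC_ROW("CD2", "CA", "CB", "CG", 1.43, 126.7, -90),
                  .SC_ROW("NE1", "CB", "CG", "CD1", 1.38, 110.2, 180),
                  .SC_ROW("CE2", "CB", "CG", "CD2", 1.41, 107.2, 180),
                  .SC_ROW("CE3", "NE1", "CE2", "CD2", 1.40, 118.0, 180),
                  .SC_ROW("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
                  .SC_ROW("CZ3", "CE2", "CD2", "CE3", 1.40, 118.0, 0),
                  .SC_ROW("CH2", "CD2", "CE2", "CZ2", 1.37, 117.0, 0)),
  HIS = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.50, 113.8, 180),
                  .SC_ROW("ND1", "CA", "CB", "CG", 1.38, 122.7, 90),
                  .SC_ROW("CD2", "CA", "CB", "CG", 1.36, 131.0, -90),
                  .SC_ROW("CE1", "CB", "CG", "ND1", 1.32, 109.0, 180),
                  .SC_ROW("NE2", "CB", "CG", "CD2", 1.37, 107.0, 180)),
  ASP = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.52, 112.6, 180),
                  .SC_ROW("OD1", "CA", "CB", "CG", 1.25, 118.4, 0),
                  .SC_ROW("OD2", "CA", "CB", "CG", 1.25, 118.4, 180)),
  ASN = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.52, 112.6, 180),
                  .SC_ROW("OD1", "CA", "CB", "CG", 1.23, 120.8, 0),
                  .SC_ROW("ND2", "CA", "CB", "CG", 1.33, 116.4, 180)),
  GLU = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.53, 114.0, 180),
                  .SC_ROW("CD",  "CA", "CB", "CG", 1.52, 112.6, 180),
                  .SC_ROW("OE1", "CB", "CG", "CD", 1.25, 118.4, 0),
                  .SC_ROW("OE2", "CB", "CG", "CD", 1.25, 118.4, 180)),
  GLN = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.53, 114.0, 180),
                  .SC_ROW("CD",  "CA", "CB", "CG", 1.52, 112.6, 180),
                  .SC_ROW("OE1", "CB", "CG", "CD", 1.23, 120.8, 0),
                  .SC_ROW("NE2", "CB", "CG", "CD", 1.33, 116.4, 180)),
  LYS = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.53, 114.0, 180),
                  .SC_ROW("CD",  "CA", "CB", "CG", 1.53, 111.3, 180),
                  .SC_ROW("CE",  "CB", "CG", "CD", 1.53, 111.3, 180),
                  .SC_ROW("NZ",  "CG", "CD", "CE", 1.49, 111.9, 180)),
  ARG = list(.CB, .SC_ROW("CG",  "N", "CA", "CB", 1.53, 114.0, 180),
                  .SC_ROW("CD",  "CA", "CB", "CG", 1.53, 111.3, 180),
                  .SC_ROW("NE",  "CB", "CG", "CD", 1.46, 112.0, 180),
                  .SC_ROW("CZ",  "CG", "CD", "NE", 1.33, 124.2, 180),
                  .SC_ROW("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
                  .SC_ROW("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180))
)

.elementFromName <- function(name) {
  # PDB convention: the element is the leading alphabetic part of the atom
  # name once digits are stripped; two-letter elements (SE, CL, ...) are
  # rare in proteins, so the first letter is correct for heavy atoms.
  first <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)), 1, 1))
  first
}

.radiusForElement <- function(element) {
  r <- .VDW_RADII[element]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Build one chain of idealised peptide coordinates.
# Returns list(atoms = data.frame(name, resno, resid), xyz = matrix)
.buildChainCoords <- function(resids, conformation = c("extended", "helix"),
                              startRes = 1L) {
  conformation <- match.arg(conformation)
  tor <- if (conformation == "helix") c(phi = -57, psi = -47)
         else c(phi = -139, psi = 135)
  n <- length(resids)
  names_out <- character(0); resno_out <- integer(0); res_out <- character(0)
  xyz <- matrix(numeric(0), ncol = 3)
  # backbone seeds
  Npos <- c(0, 0, 0)
  CApos <- c(1.458, 0, 0)
  Cpos <- .placeAtom(c(0, -1, 0), Npos, CApos, 1.525, 111.0, 0)
  prevC <- NULL; prevCA <- NULL; prevN <- NULL
  for (i in seq_len(n)) {
    if (i > 1) {
      Npos <- .placeAtom(prevN, prevCA, prevC, 1.329, 116.6, tor[["psi"]])
      CApos <- .placeAtom(prevCA, prevC, Npos, 1.458, 121.7, 180)
      Cpos <- .placeAtom(prevC, Npos, CApos, 1.525, 111.0, tor[["phi"]])
    }
    Opos <- .placeAtom(Npos, CApos, Cpos, 1.231, 120.5, tor[["psi"]] + 180)
    pos <- list(N = Npos, CA = CApos, C = Cpos, O = Opos)
    tmpl <- .SIDECHAIN_TEMPLATES[[resids[i]]]
    if (is.null(tmpl))
      stop("no side-chain template for residue type ", resids[i],
           call. = FALSE)
    for (row in tmpl) {
      pos[[row$name]] <- .placeAtom(pos[[row$p[1]]], pos[[row$p[2]]],
                                    pos[[row$p[3]]], row$bond, row$angle,
                                    row$torsion)
    }
    an <- names(pos)
    names_out <- c(names_out, an)
    resno_out <- c(resno_out, rep.int(startRes + i - 1L, length(an)))
    res_out <- c(res_out, rep.int(resids[i], length(an)))
    xyz <- rbind(xyz, do.call(rbind, pos))
    prevN <- Npos; prevCA <- CApos; prevC <- Cpos
  }
  list(atoms = data.frame(name = names_out, resno = resno_out,
                          resid = res_out, stringsAsFactors = FALSE),
       xyz = unname(xyz))
}
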