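#' @include structure.R
NULL

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom SASA by the Shrake-Rupley quadrature: each atom is
#' covered with a deterministic golden-spiral point set on its solvent-
#' expanded sphere (van der Waals radius + probe), and the accessible
#' fraction is the share of points not inside any neighbouring atom's
#' expanded sphere. Deterministic for a fixed point count; computed per
#' model for multi-model structures.
#'
#' @param structure a [ProteinStructure-class].
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param nPoints quadrature points per atom (>= 92).
#' @param models model indices to evaluate (default: all).
#' @return A [SASAProfile-class].
#' @export
#' @examples
#' s <- buildPeptide("GMG")
#' p <- shrakeRupley(s)
#' sum(atomSASA(p))
shrakeRupley <- function(structure, probe = 1.4, nPoints = 960L,
                         models = NULL) {
  stopifnot(probe > 0)
  nPoints <- as.integer(nPoints)
  if (nPoints < 92L) stop("nPoints must be at least 92", call. = FALSE)
  a <- structure@atoms
  if (is.null(models)) models <- seq_len(nModels(structure))
  pts <- .spherePoints(nPoints)
  n <- nrow(a)
  radii <- a$radius + probe
  out <- matrix(NA_real_, nrow = n, ncol = length(models))
  for (mi in seq_along(models)) {
    xyz <- atomCoords(structure, models[mi])
    if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
    dm <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n)) {
      nb <- which(dm[i, ] < radii[i] + radii & seq_len(n) != i)
      if (!length(nb)) {
        out[i, mi] <- 4 * pi * radii[i]^2
        next
      }
      sp <- pts * radii[i] +
        matrix(xyz[i, ], nPoints, 3, byrow = TRUE)
      acc <- rep(TRUE, nPoints)
      for (j in nb) {
        d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        acc <- acc & d2 >= radii[j]^2
        if (!any(acc)) break
      }
      out[i, mi] <- 4 * pi * radii[i]^2 * sum(acc) / nPoints
    }
  }
  new("SASAProfile",
      atoms = a[, c("serial", "name", "element", "resno", "resid",
                    "chain", "type")],
      sasa = out, probe = probe, nPoints = nPoints)
}

#' @rdname sasa-accessors
#' @export
setMethod("atomSASA", "SASAProfile", function(x) x@sasa)

setMethod("show", "SASAProfile", function(object) {
  cat("SASAProfile:", nrow(object@sasa), "atoms,", ncol(object@sasa),
      "model(s); probe", object@probe, "A,", object@nPoints,
      "points\n  total SASA:",
      round(mean(colSums(object@sasa)), 1), "A^2 (model mean)\n")
})

#' Per-residue SASA
#'
#' Sums per-atom SASA over each residue (model mean for multi-model
#' profiles), for all atoms or side-chain atoms only.
#'
#' @param profile a [SASAProfile-class].
#' @param what `"all"` or `"sidechain"` (excludes N, CA, C, O, OXT).
#' @return `data.frame` with columns `chain`, `resno`, `resid`, `sasa`.
#' @export
residueSASA <- function(profile, what = c("all", "sidechain")) {
  what <- match.arg(what)
  a <- profile@atoms
  s <- rowMeans(profile@sasa)
  if (what == "sidechain") s[a$name %in% .BACKBONE_ATOMS] <- 0
  key <- paste(a$chain, a$resno, sep = "\r")
  agg <- tapply(s, key, sum)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first],
                    sasa = as.numeric(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Relative SASA (percent of fully-exposed reference)
#'
#' Converts absolute residue SASA to percent of the residue type's
#' fully-exposed reference area. Values above 100 percent are possible
#' for terminal or unusually exposed residues and are flagged.
#'
#' @param profile a [SASAProfile-class].
#' @param reference named numeric vector of reference areas per residue
#'   type (default [maxASARef()]).
#' @param residues optional residue numbers to restrict to; residue
#'   types without a reference entry raise an error naming the type.
#' @param chains optional chain identifiers to restrict to.
#' @return `data.frame` with columns `chain`, `resno`, `resid`, `sasa`,
#'   `reference`, `pct`, `over_exposed`.
#' @export
#' @examples
#' p <- shrakeRupley(buildPeptide("GMG"))
#' relativeSASA(p, residues = 2)
relativeSASA <- function(profile, reference = maxASARef(), residues = NULL,
                         chains = NULL) {
  res <- residueSASA(profile)
  if (!is.null(chains)) res <- res[res$chain %in% chains, , drop = FALSE]
  if (!is.null(residues)) res <- res[res$resno %in% residues, , drop = FALSE]
  unknown <- setdiff(unique(res$resid), names(reference))
  if (length(unknown))
    stop("no reference SASA for residue type: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  res$reference <- as.numeric(reference[res$resid])
  res$pct <- 100 * res$sasa / res$reference
  res$over_exposed <- res$pct > 100
  res
}

# single-linkage connected components at a distance threshold:
# cutree(hclust(single), h) groups exactly the threshold-graph components
.distanceClusters <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(xyz), method = "single")
  stats::cutree(hc, h = cutoff)
}

.patchTable <- function(idx, clusters, sasa, atoms, kind, minArea) {
  if (!length(idx)) {
    return(data.frame(kind = character(0), area = numeric(0),
                      n_atoms = integer(0), atoms = I(list()),
                      residues = I(list())))
  }
  out <- lapply(split(seq_along(idx), clusters), function(members) {
    ai <- idx[members]
    data.frame(kind = kind, area = sum(sasa[ai]), n_atoms = length(ai),
               atoms = I(list(ai)),
               residues = I(list(sort(unique(atoms$resno[ai])))))
  })
  tab <- do.call(rbind, out)
  tab <- tab[tab$area > minArea, , drop = FALSE]
  tab <- tab[order(-tab$area), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Hydrophobic surface patches
#'
#' Clusters exposed hydrophobic atoms (surface atoms with a positive
#' entry in the atomic hydrophobicity table) into connected components
#' at a distance cutoff and reports patches whose summed SASA exceeds
#' the area threshold, sorted by area descending.
#'
#' @param structure a [ProteinStructure-class].
#' @param profile the matching [SASAProfile-class].
#' @param minArea minimum patch area, Angstrom^2 (default 50).
#' @param cutoff atom-centre adjacency cutoff, Angstrom (default 4.5).
#' @param surfaceThreshold minimum atom SASA to count as surface (0.1).
#' @param table atomic hydrophobicity table
#'   (default [hydrophobicAtomTable()]).
#' @param model model index used for geometry.
#' @return `data.frame`: `kind`, `area`, `n_atoms`, list-columns `atoms`
#'   (atom row indices) and `residues`.
#' @export
hydrophobicPatches <- function(structure, profile, minArea = 50,
                               cutoff = 4.5, surfaceThreshold = 0.1,
                               table = hydrophobicAtomTable(), model = 1L) {
  a <- structure@atoms
  s <- rowMeans(profile@sasa)
  phi <- mapply(function(resid, name) {
    v <- table[[resid]]
    if (!is.null(v) && name %in% names(v)) v[[name]] else 0
  }, a$resid, a$name)
  idx <- which(s > surfaceThreshold & phi > 0)
  if (!length(idx)) return(.patchTable(integer(0), integer(0), s, a,
                                       "hydrophobic", minArea))
  cl <- .distanceClusters(atomCoords(structure, model)[idx, , drop = FALSE],
                          cutoff)
  .patchTable(idx, cl, s, a, "hydrophobic", minArea)
}

#' Ionic surface patches
#'
#' Clusters exposed formally charged side-chain atoms (positive and
#' negative handled separately) and reports patches whose summed SASA
#' exceeds the area threshold. Histidine counts as positive only when
#' the working pH is below its pKa.
#'
#' @inheritParams hydrophobicPatches
#' @param minArea minimum patch area, Angstrom^2 (default 40).
#' @param pH working pH deciding histidine protonation (default 6.0).
#' @param pka pKa set used for the histidine rule.
#' @param table formal charge table (default [chargeAtomTable()]).
#' @return `data.frame` as in [hydrophobicPatches()], with `kind` in
#'   `"positive"`/`"negative"`.
#' @export
ionicPatches <- function(structure, profile, minArea = 40, cutoff = 4.5,
                         surfaceThreshold = 0.1, pH = 6.0,
                         pka = pkaSet("emboss"),
                         table = chargeAtomTable(), model = 1L) {
  a <- structure@atoms
  s <- rowMeans(profile@sasa)
  hisCharged <- pH < pka[["H"]]
  q <- mapply(function(resid, name) {
    if (resid == "HIS" && !hisCharged) return(0)
    v <- table[[resid]]
    if (!is.null(v) && name %in% names(v)) v[[name]] else 0
  }, a$resid, a$name)
  out <- lapply(c(positive = 1, negative = -1), function(sign) {
    kind <- if (sign > 0) "positive" else "negative"
    idx <- which(s > surfaceThreshold & sign * q > 0)
    if (!length(idx)) return(.patchTable(integer(0), integer(0), s, a,
                                         kind, minArea))
    cl <- .distanceClusters(atomCoords(structure, model)[idx, , drop = FALSE],
                            cutoff)
    .patchTable(idx, cl, s, a, kind, minArea)
  })
  tab <- rbind(out$positive, out$negative)
  tab[order(-tab$area), , drop = FALSE]
}
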