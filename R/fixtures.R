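#' @include structure.R
NULL

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  force(seed)  # resolve before snapshotting the RNG state: the seed
               # expression may itself consume random numbers
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build an idealised peptide structure
#'
#' Constructs a single-chain peptide on an idealised backbone (extended
#' strand or alpha helix) with side chains in one canonical rotamer.
#' Geometry is deterministic and clash-free by construction; it is meant
#' for testing and for self-consistent reference calculations, not as a
#' physically realistic conformer.
#'
#' @param sequence one-letter amino-acid sequence.
#' @param chain chain identifier.
#' @param conformation `"extended"` (default) or `"helix"`.
#' @param startRes first residue number.
#' @return A [ProteinStructure-class] with one model.
#' @export
#' @examples
#' buildPeptide("GMG")
buildPeptide <- function(sequence, chain = "A",
                         conformation = c("extended", "helix"),
                         startRes = 1L) {
  conformation <- match.arg(conformation)
  resids <- aa1to3(strsplit(toupper(sequence), "")[[1]])
  built <- .buildChainCoords(resids, conformation, as.integer(startRes))
  atoms <- built$atoms
  atoms$chain <- chain
  proteinStructure(atoms, built$xyz)
}

# rotation matrix mapping unit vector a onto unit vector b (Rodrigues)
.rotationBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) return(-diag(3))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# golden-spiral unit sphere points (deterministic)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.appendAtoms <- function(structure, atoms, xyz) {
  a <- rbind(structure@atoms[names(structure@atoms)],
             atoms[names(structure@atoms)])
  a$serial <- seq_len(nrow(a))
  m <- nModels(structure)
  coords <- array(NA_real_, dim = c(nrow(a), 3, m))
  for (k in seq_len(m))
    coords[, , k] <- rbind(atomCoords(structure, k), xyz)
  proteinStructure(a, coords)
}

#' Generate a toy structure with known ground truth
#'
#' Builds mini-structures for testing: an idealised peptide in which
#' selected residues can be buried under a sealed carbon-shell cage, and
#' an optional free histidine placed at a controlled distance from a
#' methionine sulfur. The returned ground truth records what the layout
#' planted (burial classes, achieved distances), so tests never have to
#' trust the code under test.
#'
#' @param layout list with elements `sequence` (one-letter string),
#'   optional `conformation`, optional `buried` (residue positions to
#'   cage), optional `hisNear = list(target = <Met resno>, distance =
#'   <Angstrom>)`.
#' @param seed integer seed for the (small) placement jitter.
#' @return list with elements `structure` ([ProteinStructure-class]) and
#'   `truth` (list: `buried`, `hisDistance` as planted/measured values).
#' @export
#' @examples
#' fx <- makeToyStructure(list(sequence = "GAMAG",
#'                             hisNear = list(target = 3, distance = 8)))
#' fx$truth$hisDistance
makeToyStructure <- function(layout, seed = 1L) {
  .withSeed(seed, {
    conformation <- layout$conformation %||% "extended"
    s <- buildPeptide(layout$sequence, conformation = conformation)
    truth <- list(buried = layout$buried %||% integer(0))
    # burial cages: sealed shell of carbon pseudo-atoms around the residue
    for (p in (layout$buried %||% integer(0))) {
      sel <- s@atoms$resno == p & s@atoms$chain == "A"
      if (!any(sel)) stop("buried position ", p, " not in sequence",
                          call. = FALSE)
      xyz <- atomCoords(s)[sel, , drop = FALSE]
      ctr <- colMeans(xyz)
      R <- max(sqrt(rowSums((xyz - matrix(ctr, nrow(xyz), 3,
                                          byrow = TRUE))^2))) + 2.9
      npts <- ceiling(4 * pi * R^2 / 1.2^2)
      cage <- .spherePoints(npts) * R +
        matrix(ctr, npts, 3, byrow = TRUE)
      # keep the shell sealed but drop points clashing with other residues
      other <- atomCoords(s)[!sel, , drop = FALSE]
      keep <- apply(cage, 1, function(pt)
        min(sqrt(rowSums((other - matrix(pt, nrow(other), 3,
                                         byrow = TRUE))^2))) > 2.6)
      cage <- cage[keep, , drop = FALSE]
      atoms <- data.frame(serial = NA_integer_, name = "C", element = "C",
                          resno = max(s@atoms$resno) + seq_len(nrow(cage)),
                          resid = "DUM",
                          chain = "Z", radius = .radiusForElement("C"),
                          type = "HETATM", stringsAsFactors = FALSE)
      s <- .appendAtoms(s, atoms, cage)
    }
    # controlled His placement near a Met sulfur
    if (!is.null(layout$hisNear)) {
      tgt <- layout$hisNear$target
      d <- layout$hisNear$distance
      a <- s@atoms
      sdIdx <- which(a$resno == tgt & a$chain == "A" & a$name == "SD")
      if (!length(sdIdx)) stop("hisNear target ", tgt, " has no SD atom",
                               call. = FALSE)
      sdPos <- atomCoords(s)[sdIdx, ]
      his <- buildPeptide("H", chain = "H")
      hx <- atomCoords(his)
      nd1 <- hx[his@atoms$name == "ND1", ]
      ctrH <- colMeans(hx)
      protein <- atomCoords(s)
      ctrP <- colMeans(protein)
      u <- sdPos - ctrP
      u <- u / sqrt(sum(u^2))
      # orient the imidazole so ND1 points back toward the Met sulfur
      rot <- .rotationBetween(ctrH - nd1, u)
      hx2 <- (hx - matrix(nd1, nrow(hx), 3, byrow = TRUE)) %*% t(rot)
      hx2 <- hx2 + matrix(sdPos + d * u, nrow(hx2), 3, byrow = TRUE)
      clash <- min(as.matrix(stats::dist(rbind(protein, hx2)))[
        seq_len(nrow(protein)), nrow(protein) + seq_len(nrow(hx2))])
      if (clash < 2.0) stop("impossible layout: His placement clashes",
                            call. = FALSE)
      hisAtoms <- his@atoms
      hisAtoms$chain <- "H"
      s <- .appendAtoms(s, hisAtoms, hx2)
      a2 <- s@atoms
      imid <- which(a2$chain == "H" & a2$name %in% c("ND1", "NE2"))
      dists <- sqrt(colSums((t(atomCoords(s)[imid, , drop = FALSE]) -
                               atomCoords(s)[sdIdx, ])^2))
      truth$hisDistance <- list(planted = d, measured = min(dists))
    }
    list(structure = s, truth = truth)
  })
}

# three-segment "dumbbell" monomer: VHH / hinge / Fc rods stacked along z
# with unequal spacing so that every domain-pair sum is unique.
.DUMBBELL_Z <- c(VHH = 0, hinge = 18, Fc = 48)

#' Build a three-domain dumbbell monomer
#'
#' A synthetic VHH/hinge/Fc monomer for interface tests: three extended
#' peptide rods stacked along z at unequal offsets, so that when two
#' copies are docked only one planted domain pair can come into contact.
#'
#' @param domainLengths named integer vector of residue counts.
#' @param chain chain identifier.
#' @return list: `structure`, `boundaries` (for [annotateDomains()]).
#' @export
makeDumbbell <- function(domainLengths = c(VHH = 6L, hinge = 4L, Fc = 6L),
                         chain = "A") {
  stopifnot(identical(names(domainLengths), c("VHH", "hinge", "Fc")))
  segs <- list(); bounds <- list(); start <- 1L
  for (dom in names(domainLengths)) {
    n <- domainLengths[[dom]]
    seg <- buildPeptide(strrep("A", n), chain = chain, startRes = start)
    xyz <- atomCoords(seg)
    xyz[, 3] <- xyz[, 3] + .DUMBBELL_Z[[dom]]
    segs[[dom]] <- list(atoms = seg@atoms, xyz = xyz)
    bounds[[dom]] <- c(start, start + n - 1L)
    start <- start + n
  }
  atoms <- do.call(rbind, lapply(segs, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(segs, `[[`, "xyz"))
  rownames(atoms) <- NULL
  atoms$serial <- seq_len(nrow(atoms))
  list(structure = proteinStructure(atoms, xyz), boundaries = bounds)
}

.MODE_LEVELS <- c("Fc-Fc", "Fc-VHH", "Fc-hinge", "hinge-hinge",
                  "hinge-VHH", "VHH-VHH")

.modeLabel <- function(d1, d2) {
  pr <- c(Fc = 1L, hinge = 2L, VHH = 3L)
  paste(sort(c(d1, d2))[order(pr[sort(c(d1, d2))])], collapse = "-")
}

#' Generate a docked pose ensemble with a planted mode distribution
#'
#' Places two copies of the dumbbell monomer so that each pose realises
#' exactly one planted domain-pair binding mode: the ligand copy is
#' flipped about the y axis and shifted along z so that only the planted
#' segment pair comes within contact range. The returned truth table
#' lists the planted mode per pose and brute-force (double loop)
#' per-residue contact counts, computed independently of the package's
#' contact engine.
#'
#' @param modeCounts named integer vector of poses per mode, e.g.
#'   `c("Fc-VHH" = 3, "VHH-VHH" = 1)`.
#' @param seed integer seed for the placement jitter.
#' @param gap approximate inter-backbone gap in Angstrom.
#' @param energyPerMode optional named numeric of mean energies; poses
#'   get Gaussian noise (sd 1) around their mode mean.
#' @return list: `ensemble` ([PoseEnsemble-class]), `annotation`
#'   ([DomainAnnotation-class]), `truth` (list with `modes`, `counts`).
#' @export
#' @examples
#' fx <- makePoseEnsemble(c("Fc-VHH" = 2, "VHH-VHH" = 1), seed = 7)
#' fx$truth$modes
makePoseEnsemble <- function(modeCounts, seed = 1L, gap = 5.0,
                             energyPerMode = NULL) {
  if (!length(modeCounts) || sum(modeCounts) < 1)
    stop("empty mode distribution", call. = FALSE)
  bad <- setdiff(names(modeCounts), .MODE_LEVELS)
  if (length(bad)) stop("unknown binding mode: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  .withSeed(seed, {
    rec <- makeDumbbell(chain = "A")
    lig <- makeDumbbell(chain = "B")
    rxyz <- atomCoords(rec$structure)
    lxyz0 <- atomCoords(lig$structure)
    # flip ligand about the y axis: (x, y, z) -> (-x, y, -z)
    lflip <- lxyz0 %*% diag(c(-1, 1, -1))
    xmid <- min(rxyz[, 1]) + max(rxyz[, 1])   # restores the x mid-range
    modes <- rep(names(modeCounts), modeCounts)
    poses <- vector("list", length(modes))
    energies <- rep(NA_real_, length(modes))
    for (k in seq_along(modes)) {
      pair <- strsplit(modes[k], "-", fixed = TRUE)[[1]]
      dy <- gap + stats::runif(1, -0.3, 0.3)
      dx <- stats::runif(1, -1.5, 1.5)
      if (pair[1] == pair[2]) {
        # same-domain pair: flipped ligand; the segment-z sums are unique,
        # so only the planted pair can touch
        tz <- 2 * .DUMBBELL_Z[[pair[1]]]
        poses[[k]] <- lflip + matrix(c(xmid + dx, dy, tz),
                                     nrow(lflip), 3, byrow = TRUE)
      } else {
        # mixed pair: plain z-shift; the segment-z differences are unique
        tz <- .DUMBBELL_Z[[pair[1]]] - .DUMBBELL_Z[[pair[2]]]
        poses[[k]] <- lxyz0 + matrix(c(dx, dy, tz),
                                     nrow(lxyz0), 3, byrow = TRUE)
      }
      if (!is.null(energyPerMode))
        energies[k] <- energyPerMode[[modes[k]]] + stats::rnorm(1)
    }
    atoms <- rbind(rec$structure@atoms, lig$structure@atoms)
    atoms$serial <- seq_len(nrow(atoms))
    rownames(atoms) <- NULL
    coords <- array(NA_real_, dim = c(nrow(atoms), 3, length(modes)))
    for (k in seq_along(modes)) coords[, , k] <- rbind(rxyz, poses[[k]])
    structure <- proteinStructure(atoms, coords)
    annotation <- annotateDomains(rec$structure,
                                  boundaries = rec$boundaries)
    # brute-force truth: plain double loop over atoms, all poses
    counts <- integer(0)
    recIdx <- which(atoms$chain == "A")
    ligIdx <- which(atoms$chain == "B")
    for (k in seq_along(modes)) {
      xyz <- coords[, , k]
      for (i in recIdx) for (j in ligIdx) {
        dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (dij <= 5.0) {
          for (rr in as.character(c(atoms$resno[i], atoms$resno[j]))) {
            counts[rr] <- (if (rr %in% names(counts)) counts[[rr]] else 0L) + 1L
          }
        }
      }
    }
    ensemble <- new("PoseEnsemble", structure = structure,
                    receptorChains = "A", ligandChains = "B",
                    energies = energies, label = "synthetic")
    list(ensemble = ensemble, annotation = annotation,
         truth = list(modes = modes, counts = counts))
  })
}

#' Generate synthetic feature/attribute stability tables
#'
#' Draws per-sample feature and attribute columns from standard normals,
#' with specified Pearson correlations planted between named
#' feature/attribute pairs; all other pairs are independent (null).
#'
#' @param nSamples number of samples (rows).
#' @param features,attributes character vectors of column names.
#' @param planted `data.frame` with columns `feature`, `attribute`,
#'   `rho`.
#' @param seed integer seed.
#' @return list: `features`, `attributes` (data.frames with rownames
#'   `sample1..n`), `truth` (the planted table).
#' @export
#' @examples
#' tb <- makeStabilityTable(12, planted = data.frame(
#'   feature = "sap_score", attribute = "hmw_rate", rho = 0.8), seed = 3)
makeStabilityTable <- function(nSamples = 12L,
                               features = c("sap_score", "di",
                                            "hydrophobic_area", "net_charge"),
                               attributes = c("hmw_rate", "dls_rate",
                                              "appearance", "yield"),
                               planted = NULL, seed = 1L) {
  .withSeed(seed, {
    f <- matrix(stats::rnorm(nSamples * length(features)),
                nrow = nSamples, dimnames = list(NULL, features))
    a <- matrix(stats::rnorm(nSamples * length(attributes)),
                nrow = nSamples, dimnames = list(NULL, attributes))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        ft <- planted$feature[i]; at <- planted$attribute[i]
        rho <- planted$rho[i]
        a[, at] <- rho * f[, ft] + sqrt(1 - rho^2) * stats::rnorm(nSamples)
      }
    }
    rn <- paste0("sample", seq_len(nSamples))
    features <- as.data.frame(f, row.names = rn)
    attributes <- as.data.frame(a, row.names = rn)
    list(features = features, attributes = attributes,
         truth = planted %||% data.frame(feature = character(0),
                                         attribute = character(0),
                                         rho = numeric(0)))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
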