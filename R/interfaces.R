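#' @include structure.R
NULL

#' Construct a PoseEnsemble
#'
#' @param structure multi-model [ProteinStructure-class]; each model is
#'   one docked pose.
#' @param receptorChains,ligandChains chain identifiers of the partners;
#'   when omitted and the structure has exactly two chains, the first is
#'   the receptor and the second the ligand.
#' @param energies optional numeric vector (one per pose, kcal/mol) or a
#'   `data.frame` with columns `pose_index`, `energy_kcal_mol`.
#' @param label free-text combination label (for example `"3SS-3SS"`).
#' @return A [PoseEnsemble-class].
#' @export
poseEnsemble <- function(structure, receptorChains = NULL,
                         ligandChains = NULL, energies = NULL,
                         label = "") {
  chains <- unique(structure@atoms$chain)
  if (is.null(receptorChains) || is.null(ligandChains)) {
    if (length(chains) != 2L)
      stop("pose models must contain exactly two partner groups; found ",
           length(chains), " chain(s): supply receptorChains/ligandChains",
           call. = FALSE)
    receptorChains <- chains[1]
    ligandChains <- chains[2]
  }
  np <- dim(structure@coords)[3]
  if (is.data.frame(energies)) {
    if (!all(c("pose_index", "energy_kcal_mol") %in% names(energies)))
      stop("energy table needs pose_index and energy_kcal_mol columns",
           call. = FALSE)
    if (nrow(energies) != np)
      stop("energy table has ", nrow(energies), " rows but the ensemble has ",
           np, " poses", call. = FALSE)
    e <- rep(NA_real_, np)
    e[energies$pose_index] <- energies$energy_kcal_mol
    energies <- e
  }
  if (is.null(energies)) energies <- rep(NA_real_, np)
  if (length(energies) != np)
    stop("energies must have one value per pose", call. = FALSE)
  new("PoseEnsemble", structure = structure,
      receptorChains = receptorChains, ligandChains = ligandChains,
      energies = as.numeric(energies), label = label)
}

#' Load a docked pose ensemble from a multi-model PDB
#'
#' @param path multi-model PDB file (one MODEL per pose).
#' @param energies optional CSV path or `data.frame` with columns
#'   `pose_index`, `energy_kcal_mol`; joined by pose index.
#' @inheritParams poseEnsemble
#' @return A [PoseEnsemble-class].
#' @export
loadPoseEnsemble <- function(path, energies = NULL, receptorChains = NULL,
                             ligandChains = NULL, label = "") {
  structure <- readPDB(path)
  if (is.character(energies))
    energies <- utils::read.csv(energies, stringsAsFactors = FALSE)
  poseEnsemble(structure, receptorChains, ligandChains, energies, label)
}

#' @rdname ensemble-accessors
#' @export
setMethod("nPoses", "PoseEnsemble", function(x) dim(x@structure@coords)[3])

#' @rdname ensemble-accessors
#' @export
setMethod("poseEnergies", "PoseEnsemble", function(x) x@energies)

setMethod("show", "PoseEnsemble", function(object) {
  cat("PoseEnsemble", if (nzchar(object@label)) paste0("[", object@label, "]"),
      ":", nPoses(object), "pose(s); receptor",
      paste(object@receptorChains, collapse = "/"), "vs ligand",
      paste(object@ligandChains, collapse = "/"), "\n")
})

.partnerIndices <- function(ensemble) {
  a <- ensemble@structure@atoms
  heavy <- a$element != "H"
  list(rec = which(a$chain %in% ensemble@receptorChains & heavy),
       lig = which(a$chain %in% ensemble@ligandChains & heavy))
}

#' Cross-partner interface contacts of one pose
#'
#' All receptor/ligand heavy-atom pairs within the distance cutoff
#' (boundary inclusive), ordered by receptor then ligand atom index.
#'
#' @param ensemble a [PoseEnsemble-class].
#' @param pose pose (model) index.
#' @param cutoff contact distance cutoff, Angstrom (default 5.0).
#' @return `data.frame`: `rec_atom`, `lig_atom` (atom row indices),
#'   `rec_resno`, `lig_resno`, `distance`.
#' @export
interfaceContacts <- function(ensemble, pose = 1L, cutoff = 5.0) {
  idx <- .partnerIndices(ensemble)
  a <- ensemble@structure@atoms
  xyz <- atomCoords(ensemble@structure, pose)
  rx <- xyz[idx$rec, , drop = FALSE]
  lx <- xyz[idx$lig, , drop = FALSE]
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  data.frame(rec_atom = idx$rec[hit[, 1]], lig_atom = idx$lig[hit[, 2]],
             rec_resno = a$resno[idx$rec[hit[, 1]]],
             lig_resno = a$resno[idx$lig[hit[, 2]]],
             distance = sqrt(pmax(0, d2[hit])))
}

#' Classify the binding mode of one pose
#'
#' For each partner the domain owning the most interface contacts is
#' selected; the mode is the unordered pair of the two domains. Domain
#' ties are resolved with the fixed priority VHH > hinge > Fc (the
#' antigen-binding domain is flagged preferentially because it is the
#' designable region). Poses without any contact get the `"unbound"`
#' sentinel and are excluded from summaries.
#'
#' @param ensemble a [PoseEnsemble-class].
#' @param annotation a [DomainAnnotation-class] on the shared monomer
#'   numbering.
#' @param pose pose index.
#' @param cutoff contact cutoff, Angstrom.
#' @return Mode label, one of `"Fc-Fc"`, `"Fc-VHH"`, `"Fc-hinge"`,
#'   `"hinge-hinge"`, `"hinge-VHH"`, `"VHH-VHH"`, or `"unbound"`.
#' @export
classifyBindingMode <- function(ensemble, annotation, pose = 1L,
                                cutoff = 5.0) {
  ct <- interfaceContacts(ensemble, pose, cutoff)
  if (!nrow(ct)) return("unbound")
  pick <- function(resnos) {
    dom <- domainOf(annotation, resnos)
    tab <- table(factor(dom, levels = c("VHH", "hinge", "Fc")))
    names(tab)[which.max(tab)]   # which.max takes the first on ties
  }
  .modeLabel(pick(ct$rec_resno), pick(ct$lig_resno))
}

#' Binding-mode summary of an ensemble
#'
#' Counts and percentages (over classifiable poses) of the six domain-
#' pair binding modes, with mean and standard deviation of the pose
#' energies per mode where energies are available.
#'
#' @inheritParams classifyBindingMode
#' @return `data.frame`: `mode`, `count`, `percentage`, `mean_energy`,
#'   `sd_energy`, plus an `unbound` attribute with the excluded count.
#' @export
modeSummary <- function(ensemble, annotation, cutoff = 5.0) {
  modes <- vapply(seq_len(nPoses(ensemble)), function(k)
    classifyBindingMode(ensemble, annotation, k, cutoff), character(1))
  keep <- modes != "unbound"
  e <- poseEnergies(ensemble)[keep]
  m <- factor(modes[keep], levels = .MODE_LEVELS)
  counts <- as.integer(table(m))
  out <- data.frame(mode = .MODE_LEVELS, count = counts,
                    percentage = if (sum(counts)) 100 * counts / sum(counts)
                                 else rep(NA_real_, length(counts)))
  out$mean_energy <- vapply(.MODE_LEVELS, function(mm) {
    v <- e[m == mm & !is.na(e)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out$sd_energy <- vapply(.MODE_LEVELS, function(mm) {
    v <- e[m == mm & !is.na(e)]
    if (length(v) > 1) stats::sd(v) else NA_real_
  }, numeric(1))
  attr(out, "unbound") <- sum(!keep)
  rownames(out) <- NULL
  out
}

#' Per-residue protein-protein interface preference (PPIP)
#'
#' Counts cross-partner atom contacts per sequence position, summed over
#' poses, over both partner roles (homodimer symmetry: receptor and
#' ligand chains map onto one monomer numbering) and over all supplied
#' ensembles, then normalises by the maximum count so the preference
#' lies in `[0, 1]` with at least one exact 1 whenever any contact
#' exists. Per-ensemble maps can be obtained by passing one ensemble.
#'
#' @param ensembles a [PoseEnsemble-class] or list of them (for example
#'   the three dimer combinations of a two-redox-state antibody).
#' @param cutoff contact cutoff, Angstrom.
#' @return A [PPIPMap-class].
#' @export
ppiPreference <- function(ensembles, cutoff = 5.0) {
  if (is(ensembles, "PoseEnsemble")) ensembles <- list(ensembles)
  counts <- integer(0)
  for (ens in ensembles) {
    for (k in seq_len(nPoses(ens))) {
      ct <- interfaceContacts(ens, k, cutoff)
      if (!nrow(ct)) next
      tab <- table(as.character(c(ct$rec_resno, ct$lig_resno)))
      for (rr in names(tab))
        counts[rr] <- (if (rr %in% names(counts)) counts[[rr]] else 0L) +
          as.integer(tab[[rr]])
    }
  }
  if (!length(counts) || sum(counts) == 0L)
    stop("no cross-partner contacts in any pose", call. = FALSE)
  # include never-contacted positions of the monomer numbering
  resnos <- sort(unique(c(as.integer(names(counts)),
    unlist(lapply(ensembles, function(e) residueNumbers(e@structure))))))
  full <- integer(length(resnos))
  names(full) <- resnos
  full[names(counts)] <- counts
  new("PPIPMap", counts = full, preference = full / max(full))
}

#' @rdname ppip-accessors
#' @export
setMethod("contactCounts", "PPIPMap", function(x) x@counts)

#' @rdname ppip-accessors
#' @export
setMethod("preference", "PPIPMap", function(x) x@preference)

setMethod("show", "PPIPMap", function(object) {
  cat("PPIPMap:", length(object@counts), "positions;",
      sum(object@preference > 0.5), "on the aggregation interface",
      "(preference > 0.5)\n")
})

#' Aggregation interface from a PPIP map
#'
#' Residues whose interface preference strictly exceeds the threshold.
#'
#' @param ppipmap a [PPIPMap-class].
#' @param threshold preference threshold (default 0.5).
#' @return Integer residue numbers.
#' @export
aggregationInterface <- function(ppipmap, threshold = 0.5) {
  p <- preference(ppipmap)
  sort(as.integer(names(p)[p > threshold]))
}
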