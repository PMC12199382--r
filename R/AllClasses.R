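#' @import methods
#' @importFrom IRanges IRanges start end width
NULL

#' ProteinStructure: atoms, coordinates and models
#'
#' Container for a parsed (or synthetically built) protein structure.
#' Atom identities (serial, name, element, residue, chain, van der Waals
#' radius) are stored once; coordinates are stored per model, so every
#' model shares identical atom identities by construction.
#'
#' @slot atoms `data.frame` with columns `serial`, `name`, `element`,
#'   `resno`, `resid`, `chain`, `radius` (Angstrom) and `type`
#'   (`ATOM`/`HETATM`).
#' @slot coords numeric array `n_atoms x 3 x n_models`, Angstrom.
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", coords = "array"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  x <- object@coords
  msgs <- character(0)
  need <- c("serial", "name", "element", "resno", "resid", "chain",
            "radius", "type")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, paste("atoms must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(a) < 1L) msgs <- c(msgs, "structure must contain at least one atom")
    if (any(a$radius <= 0)) msgs <- c(msgs, "van der Waals radii must be positive")
    key <- paste(a$chain, a$resno, a$name)
    if (anyDuplicated(key))
      msgs <- c(msgs, paste("duplicated atom identity:",
                            key[duplicated(key)][1]))
    # residue numbers strictly increasing within a chain
    for (ch in unique(a$chain)) {
      r <- a$resno[a$chain == ch]
      if (is.unsorted(r[!duplicated(r)], strictly = TRUE))
        msgs <- c(msgs, paste0("residue numbers not strictly increasing in chain ", ch))
    }
  }
  if (length(dim(x)) != 3L || dim(x)[2] != 3L)
    msgs <- c(msgs, "coords must be an n_atoms x 3 x n_models array")
  else {
    if (dim(x)[1] != nrow(a))
      msgs <- c(msgs, "coords and atoms disagree on atom count")
    if (dim(x)[3] < 1L) msgs <- c(msgs, "at least one model required")
    if (!all(is.finite(x))) msgs <- c(msgs, "non-finite coordinates")
  }
  if (length(msgs)) msgs else TRUE
})

#' DomainAnnotation: VHH/hinge/Fc labels, CDR ranges and conserved set
#'
#' @slot domains named character vector, one of `"VHH"`, `"hinge"`,
#'   `"Fc"` per residue number (names are residue numbers).
#' @slot cdrRanges [IRanges::IRanges] of inclusive CDR residue-number
#'   intervals (must lie inside the VHH domain).
#' @slot conserved integer vector of conserved residue numbers.
#' @export
setClass("DomainAnnotation",
  representation(domains = "character", cdrRanges = "IRanges",
                 conserved = "integer"))

setValidity("DomainAnnotation", function(object) {
  msgs <- character(0)
  d <- object@domains
  if (is.null(names(d)) || anyNA(suppressWarnings(as.integer(names(d)))))
    msgs <- c(msgs, "domains must be named by residue number")
  bad <- setdiff(unique(d), c("VHH", "hinge", "Fc"))
  if (length(bad))
    msgs <- c(msgs, paste("unknown domain label:", paste(bad, collapse = ", ")))
  if (length(object@cdrRanges)) {
    resno <- as.integer(names(d))
    vhh <- resno[d == "VHH"]
    cdr <- unlist(lapply(seq_along(object@cdrRanges), function(i)
      seq.int(IRanges::start(object@cdrRanges)[i],
              IRanges::end(object@cdrRanges)[i])))
    out <- setdiff(intersect(cdr, resno), vhh)
    if (length(out))
      msgs <- c(msgs, paste("CDR residues outside the VHH domain:",
                            paste(out, collapse = ", ")))
    ov <- IRanges::findOverlaps(object@cdrRanges, object@cdrRanges)
    if (length(ov) > length(object@cdrRanges))
      msgs <- c(msgs, "CDR ranges overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' SASAProfile: per-atom solvent accessibility
#'
#' Result of the Shrake-Rupley calculation: one SASA value per atom and
#' model, together with the atom identities it was computed on and the
#' quadrature parameters.
#'
#' @slot atoms `data.frame` copy of the structure's atom identity columns.
#' @slot sasa numeric matrix `n_atoms x n_models`, Angstrom^2.
#' @slot probe probe radius, Angstrom.
#' @slot nPoints quadrature points per atom.
#' @export
setClass("SASAProfile",
  representation(atoms = "data.frame", sasa = "matrix",
                 probe = "numeric", nPoints = "integer"))

setValidity("SASAProfile", function(object) {
  msgs <- character(0)
  if (nrow(object@sasa) != nrow(object@atoms))
    msgs <- c(msgs, "sasa rows must match atom count")
  if (any(object@sasa < -1e-9)) msgs <- c(msgs, "SASA values must be non-negative")
  if (object@probe <= 0) msgs <- c(msgs, "probe radius must be positive")
  if (length(msgs)) msgs else TRUE
})

#' PoseEnsemble: docked dimer poses with optional energies
#'
#' A multi-model structure in which every model holds one docked pose of
#' a receptor/ligand pair (identified by chain), plus optional per-pose
#' energies and a free-text combination label (for example `"3SS-3SS"`).
#'
#' @slot structure [ProteinStructure-class] with one model per pose.
#' @slot receptorChains,ligandChains chain identifiers of the two
#'   partners.
#' @slot energies numeric vector, one per pose (NA when absent), kcal/mol.
#' @slot label character combination label.
#' @export
setClass("PoseEnsemble",
  representation(structure = "ProteinStructure",
                 receptorChains = "character", ligandChains = "character",
                 energies = "numeric", label = "character"))

setValidity("PoseEnsemble", function(object) {
  msgs <- character(0)
  ch <- unique(object@structure@atoms$chain)
  if (!all(object@receptorChains %in% ch))
    msgs <- c(msgs, "receptor chains not present in structure")
  if (!all(object@ligandChains %in% ch))
    msgs <- c(msgs, "ligand chains not present in structure")
  if (length(intersect(object@receptorChains, object@ligandChains)))
    msgs <- c(msgs, "receptor and ligand chains overlap")
  np <- dim(object@structure@coords)[3]
  if (length(object@energies) && length(object@energies) != np)
    msgs <- c(msgs, "energies must have one value per pose")
  if (length(msgs)) msgs else TRUE
})

#' PPIPMap: per-residue interface preference
#'
#' Raw cross-partner contact counts per sequence position and their
#' normalisation to the `[0, 1]` protein-protein interface preference
#' (PPIP): `preference = count / max(count)`.
#'
#' @slot counts named integer vector (names are residue numbers).
#' @slot preference named numeric vector in `[0, 1]`.
#' @export
setClass("PPIPMap",
  representation(counts = "integer", preference = "numeric"))

setValidity("PPIPMap", function(object) {
  msgs <- character(0)
  if (length(object@counts) != length(object@preference))
    msgs <- c(msgs, "counts and preference lengths differ")
  if (length(object@preference)) {
    if (any(object@preference < 0 | object@preference > 1 + 1e-12))
      msgs <- c(msgs, "preferences must lie in [0, 1]")
    if (sum(object@counts) > 0 && abs(max(object@preference) - 1) > 1e-12)
      msgs <- c(msgs, "maximum preference must be 1 when contacts exist")
  }
  if (length(msgs)) msgs else TRUE
})

#' HotspotReport: flagged residues, reasons and mutability
#'
#' One row per flagged residue with the set of reasons
#' (`redox`, `STAP-interface`, `oxidation`, `oxidation-catalysis`), the
#' applicable exclusions (`conserved`, `binding-critical`,
#' `off-interface`) and the resulting mutability flag.
#'
#' @slot table `data.frame` with columns `resno`, `resid`, `reasons`,
#'   `excluded_because`, `mutable`.
#' @export
setClass("HotspotReport", representation(table = "data.frame"))

setValidity("HotspotReport", function(object) {
  tab <- object@table
  need <- c("resno", "resid", "reasons", "excluded_because", "mutable")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  bad <- nzchar(tab$reasons) & !nzchar(tab$excluded_because) & !tab$mutable
  if (any(bad))
    return("a flagged residue without exclusions must be mutable")
  TRUE
})
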