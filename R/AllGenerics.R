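#' @include AllClasses.R
NULL

#' Accessors for HcAbStab classes
#'
#' `atomTable()` returns the atom identity table; `atomCoords()` the
#' coordinate matrix of one model; `nModels()` the model count;
#' `chainSequences()` the one-letter sequence per chain as an
#' [Biostrings::AAStringSet]; `residueNumbers()` the unique residue
#' numbers.
#'
#' @param x a `ProteinStructure` (or object wrapping one).
#' @param model model index (1-based).
#' @name structure-accessors
#' @aliases atomTable atomCoords nModels chainSequences residueNumbers
NULL

#' @rdname structure-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname structure-accessors
#' @export
setGeneric("atomCoords", function(x, model = 1L) standardGeneric("atomCoords"))

#' @rdname structure-accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname structure-accessors
#' @export
setGeneric("chainSequences", function(x) standardGeneric("chainSequences"))

#' @rdname structure-accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' Domain annotation accessors
#'
#' `domainOf()` returns the domain label for given residue numbers,
#' `cdrRanges()` the CDR intervals, `conservedResidues()` the conserved
#' residue numbers.
#'
#' @param x a `DomainAnnotation`.
#' @param resno integer residue numbers (for `domainOf`).
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("domainOf", function(x, resno) standardGeneric("domainOf"))

#' @rdname annotation-accessors
#' @export
setGeneric("cdrRanges", function(x) standardGeneric("cdrRanges"))

#' @rdname annotation-accessors
#' @export
setGeneric("conservedResidues", function(x) standardGeneric("conservedResidues"))

#' SASA profile accessors
#'
#' `atomSASA()` returns the per-atom SASA matrix (atoms x models).
#'
#' @param x a `SASAProfile`.
#' @name sasa-accessors
NULL

#' @rdname sasa-accessors
#' @export
setGeneric("atomSASA", function(x) standardGeneric("atomSASA"))

#' Pose ensemble accessors
#'
#' `nPoses()` returns the number of docked poses, `poseEnergies()` the
#' per-pose energies (kcal/mol, NA when not supplied).
#'
#' @param x a `PoseEnsemble`.
#' @name ensemble-accessors
NULL

#' @rdname ensemble-accessors
#' @export
setGeneric("nPoses", function(x) standardGeneric("nPoses"))

#' @rdname ensemble-accessors
#' @export
setGeneric("poseEnergies", function(x) standardGeneric("poseEnergies"))

#' PPIP map accessors
#'
#' `contactCounts()` returns raw per-residue cross-partner contact
#' counts; `preference()` the normalised interface preference in
#' `[0, 1]`.
#'
#' @param x a `PPIPMap`.
#' @name ppip-accessors
NULL

#' @rdname ppip-accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname ppip-accessors
#' @export
setGeneric("preference", function(x) standardGeneric("preference"))

#' Hotspot report accessor
#'
#' @param x a `HotspotReport`.
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
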