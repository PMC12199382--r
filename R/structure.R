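#' @include AllGenerics.R
NULL

#' Construct a ProteinStructure
#'
#' Low-level constructor used by the PDB reader and the synthetic
#' structure builders.
#'
#' @param atoms `data.frame` with columns `name`, `resno`, `resid`,
#'   `chain` and optionally `serial`, `element`, `radius`, `type`.
#'   Missing elements are inferred from atom names, missing radii from
#'   the bundled element table.
#' @param coords numeric matrix `n x 3` (single model) or array
#'   `n x 3 x m`.
#' @return A [ProteinStructure-class].
#' @export
proteinStructure <- function(atoms, coords) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (is.null(atoms$element) || any(!nzchar(atoms$element)) || anyNA(atoms$element)) {
    inferred <- vapply(atoms$name, .elementFromName, character(1))
    if (is.null(atoms$element)) atoms$element <- inferred
    else {
      miss <- !nzchar(atoms$element) | is.na(atoms$element)
      atoms$element[miss] <- inferred[miss]
    }
  }
  if (is.null(atoms$radius)) atoms$radius <- .radiusForElement(atoms$element)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms, coords = coords)
}

#' @rdname structure-accessors
#' @export
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' @rdname structure-accessors
#' @export
setMethod("atomCoords", "ProteinStructure", function(x, model = 1L) {
  m <- x@coords[, , model, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})

#' @rdname structure-accessors
#' @export
setMethod("nModels", "ProteinStructure", function(x) dim(x@coords)[3])

#' @rdname structure-accessors
#' @export
setMethod("chainSequences", "ProteinStructure", function(x) {
  a <- x@atoms[x@atoms$type == "ATOM", ]
  seqs <- vapply(split(a, a$chain), function(d) {
    d <- d[!duplicated(d$resno), ]
    d <- d[order(d$resno), ]
    letters1 <- ifelse(d$resid %in% names(.AA1), .AA1[d$resid], "X")
    paste(letters1, collapse = "")
  }, character(1))
  Biostrings::AAStringSet(seqs)
})

#' @rdname structure-accessors
#' @export
setMethod("residueNumbers", "ProteinStructure", function(x)
  sort(unique(x@atoms$resno[x@atoms$type == "ATOM"])))

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      length(unique(a$chain)), "chain(s),",
      nModels(object), "model(s)\n")
})

# Internal: residue-level table (one row per chain/resno)
.residueIndex <- function(structure) {
  a <- structure@atoms
  key <- !duplicated(paste(a$chain, a$resno))
  data.frame(chain = a$chain[key], resno = a$resno[key],
             resid = a$resid[key], stringsAsFactors = FALSE)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM/MODEL records into a [ProteinStructure-class].
#' Multi-model files (for example docked pose ensembles) become multiple
#' models sharing one atom identity table. The element is inferred from
#' the atom name when the element column is absent, and van der Waals
#' radii are assigned from the bundled element table.
#'
#' @param path PDB file path.
#' @return A [ProteinStructure-class].
#' @export
#' @examples
#' s <- buildPeptide("ACDEFG")
#' f <- tempfile(fileext = ".pdb")
#' writePDB(s, f)
#' readPDB(f)
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isatom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isatom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  # validate coordinate fields with line numbers before delegating
  for (i in which(isatom)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("malformed ATOM record at line ", i, " of ", path, call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  n <- nrow(a)
  element <- toupper(a$elesy)
  miss <- is.na(element) | !nzchar(trimws(element))
  element[miss] <- vapply(a$elety[miss], .elementFromName, character(1))
  element <- trimws(element)
  chain <- a$chain
  chain[is.na(chain) | !nzchar(chain)] <- " "
  atoms <- data.frame(serial = a$eleno, name = a$elety, element = element,
                      resno = a$resno, resid = a$resid, chain = chain,
                      radius = .radiusForElement(element), type = a$type,
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  m <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n, 3, m))
  for (k in seq_len(m))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  proteinStructure(atoms, coords)
}

#' Write a PDB file
#'
#' Emits ATOM/HETATM records; multi-model structures are written as
#' MODEL/ENDMDL blocks. Coordinates are preserved to three decimals, so
#' `readPDB(writePDB(s))` reproduces atom identities and coordinates at
#' PDB precision.
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  a <- structure@atoms
  m <- nModels(structure)
  xyz <- t(vapply(seq_len(m), function(k) as.numeric(t(atomCoords(structure, k))),
                  numeric(3 * nrow(a))))
  chain <- a$chain
  chain[chain == " "] <- ""
  bio3d::write.pdb(file = path, xyz = xyz, type = a$type, eleno = a$serial,
                   elety = a$name, resid = a$resid, chain = chain,
                   resno = a$resno, elesy = a$element)
  invisible(path)
}

#' Default VHH/hinge/Fc domain boundaries
#'
#' The default split places the VHH domain at residues 1-129, the hinge
#' (carrying the three interchain cysteines C130/C136/C139) at 130-142,
#' and the Fc domain from 143 to the last residue. The VHH/hinge junction
#' follows the known S129-C130 cleavage site of VHH-Fc heavy chains.
#'
#' @param structure optional [ProteinStructure-class] used to determine
#'   the last residue number.
#' @param last last residue number when no structure is given.
#' @return Named list of `c(first, last)` integer vectors.
#' @export
defaultDomainBoundaries <- function(structure = NULL, last = NULL) {
  if (is.null(last)) {
    if (is.null(structure)) stop("either structure or last is required",
                                 call. = FALSE)
    last <- max(residueNumbers(structure))
  }
  list(VHH = c(1L, 129L), hinge = c(130L, 142L), Fc = c(143L, as.integer(last)))
}

#' Annotate VHH/hinge/Fc domains
#'
#' Labels every residue of the structure with exactly one domain, from
#' residue-number boundaries. Boundaries must cover all residues and be
#' pairwise disjoint; violations are reported with the offending residue
#' numbers.
#'
#' @param structure a [ProteinStructure-class].
#' @param boundaries named list of inclusive `c(first, last)` residue
#'   intervals per domain (`VHH`, `hinge`, `Fc`); defaults to
#'   [defaultDomainBoundaries()].
#' @param cdr optional [IRanges::IRanges] (or 2-column matrix) of CDR
#'   residue intervals.
#' @param conserved integer vector of conserved residue numbers.
#' @return A [DomainAnnotation-class].
#' @export
#' @examples
#' s <- buildPeptide(strrep("A", 10))
#' annotateDomains(s, boundaries = list(VHH = c(1, 6), hinge = c(7, 8),
#'                                      Fc = c(9, 10)))
annotateDomains <- function(structure,
                            boundaries = defaultDomainBoundaries(structure),
                            cdr = NULL, conserved = integer(0)) {
  resno <- residueNumbers(structure)
  lab <- rep(NA_character_, length(resno))
  names(lab) <- resno
  for (dom in names(boundaries)) {
    b <- boundaries[[dom]]
    hit <- resno >= b[1] & resno <= b[2]
    clash <- hit & !is.na(lab)
    if (any(clash))
      stop("overlapping domain boundaries at residues: ",
           paste(resno[clash], collapse = ", "), call. = FALSE)
    lab[hit] <- dom
  }
  if (anyNA(lab))
    stop("domain boundaries leave residues unassigned: ",
         paste(resno[is.na(lab)], collapse = ", "), call. = FALSE)
  if (is.null(cdr)) cdr <- IRanges::IRanges()
  if (is.matrix(cdr)) cdr <- IRanges::IRanges(start = cdr[, 1], end = cdr[, 2])
  new("DomainAnnotation", domains = lab, cdrRanges = cdr,
      conserved = as.integer(conserved))
}

#' @rdname annotation-accessors
#' @export
setMethod("domainOf", "DomainAnnotation", function(x, resno) {
  out <- x@domains[as.character(resno)]
  names(out) <- resno
  out
})

#' @rdname annotation-accessors
#' @export
setMethod("cdrRanges", "DomainAnnotation", function(x) x@cdrRanges)

#' @rdname annotation-accessors
#' @export
setMethod("conservedResidues", "DomainAnnotation", function(x) x@conserved)

setMethod("show", "DomainAnnotation", function(object) {
  tb <- table(object@domains)
  cat("DomainAnnotation:", paste(names(tb), tb, sep = "=", collapse = ", "),
      "\n  CDR ranges:", if (length(object@cdrRanges))
        paste(IRanges::start(object@cdrRanges), IRanges::end(object@cdrRanges),
              sep = "-", collapse = ", ") else "none",
      "\n  conserved:", length(object@conserved), "residues\n")
})

# residue numbers covered by CDR ranges
.cdrResidues <- function(annotation) {
  rng <- if (is(annotation, "DomainAnnotation")) cdrRanges(annotation)
         else annotation
  if (!length(rng)) return(integer(0))
  sort(unique(unlist(lapply(seq_along(rng), function(i)
    seq.int(IRanges::start(rng)[i], IRanges::end(rng)[i])))))
}

#' Kabat CDR ranges for a VHH heavy-chain sequence
#'
#' Identifies the three heavy-chain CDRs by conserved anchor patterns:
#' CDR-H1 starts nine residues after the first framework cysteine and
#' ends before the conserved tryptophan; CDR-H2 starts fifteen residues
#' after the end of CDR-H1 and ends 27 residues before the second
#' framework cysteine; CDR-H3 starts three residues after the second
#' cysteine and ends before the tryptophan of the W-G-x-G motif. On a
#' canonically numbered heavy chain these anchors yield the classic
#' Kabat intervals 31-35, 50-65 and 95-102. Supplying `override` returns
#' it verbatim; it is the authoritative path whenever explicit ranges
#' are known.
#'
#' @param sequence one-letter VHH sequence (character or
#'   [Biostrings::AAString]).
#' @param override optional explicit ranges: [IRanges::IRanges], or a
#'   2-column matrix / list of `c(start, end)` pairs.
#' @return [IRanges::IRanges] named `CDR-H1`..`CDR-H3`.
#' @export
#' @examples
#' kabatCDRs("X", override = list(c(26, 35), c(50, 65), c(95, 112)))
kabatCDRs <- function(sequence, override = NULL) {
  if (!is.null(override)) {
    if (is(override, "IRanges")) return(override)
    if (is.list(override)) override <- do.call(rbind, override)
    return(IRanges::IRanges(start = override[, 1], end = override[, 2],
                            names = paste0("CDR-H", seq_len(nrow(override)))))
  }
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  fail <- function(what)
    stop("Kabat anchor not found (", what, "); supply explicit CDR ranges ",
         "via `override`", call. = FALSE)
  c1 <- which(s == "C")
  c1 <- c1[c1 >= 15 & c1 <= 30][1]
  if (is.na(c1)) fail("first framework cysteine near position 22")
  h1s <- c1 + 9L
  w1 <- which(s == "W")
  w1 <- w1[w1 > h1s & w1 <= h1s + 12L][1]
  if (is.na(w1)) fail("tryptophan after CDR-H1")
  h1e <- w1 - 1L
  h2s <- h1e + 15L
  c2 <- which(s == "C")
  c2 <- c2[c2 > h2s + 10L][1]
  if (is.na(c2)) fail("second framework cysteine")
  h2e <- c2 - 27L
  if (h2e < h2s) fail("CDR-H2 span")
  h3s <- c2 + 3L
  w3 <- which(s == "W")
  w3 <- w3[w3 > h3s][1]
  if (is.na(w3)) fail("tryptophan of the W-G-x-G motif after CDR-H3")
  h3e <- w3 - 1L
  IRanges::IRanges(start = c(h1s, h2s, h3s), end = c(h1e, h2e, h3e),
                   names = c("CDR-H1", "CDR-H2", "CDR-H3"))
}
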