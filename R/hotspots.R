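#' @include sasa.R
NULL

#' Oxidation liability of methionine and tryptophan
#'
#' Flags solvent-exposed Met and Trp residues: methionine is considered
#' oxidation-prone when its relative SASA strictly exceeds 20 percent,
#' tryptophan when it strictly exceeds 30 percent.
#'
#' @param profile a [SASAProfile-class].
#' @param metThr,trpThr SASA percent thresholds (strict `>`).
#' @param reference fully-exposed reference table for percent SASA.
#' @param annotation optional [DomainAnnotation-class]; adds an
#'   `in_cdr`/`near_cdr` annotation (within `nearCdr` residues of a CDR).
#' @param nearCdr window for the near-CDR annotation (default 3).
#' @return `data.frame`: `chain`, `resno`, `resid`, `sasa_pct`,
#'   `threshold`, `flagged`, and `in_cdr`/`near_cdr` when annotated.
#' @export
oxidationRisk <- function(profile, metThr = 20, trpThr = 30,
                          reference = maxASARef(), annotation = NULL,
                          nearCdr = 3L) {
  res <- residueSASA(profile)
  res <- res[res$resid %in% c("MET", "TRP"), , drop = FALSE]
  if (!nrow(res)) {
    out <- data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), sasa_pct = numeric(0),
                      threshold = numeric(0), flagged = logical(0))
    return(out)
  }
  res$sasa_pct <- 100 * res$sasa / as.numeric(reference[res$resid])
  res$threshold <- ifelse(res$resid == "MET", metThr, trpThr)
  res$flagged <- res$sasa_pct > res$threshold
  res$sasa <- NULL
  if (!is.null(annotation)) {
    cdr <- .cdrResidues(annotation)
    res$in_cdr <- res$resno %in% cdr
    near <- unique(unlist(lapply(cdr, function(r) (r - nearCdr):(r + nearCdr))))
    res$near_cdr <- !res$in_cdr & res$resno %in% near
  }
  rownames(res) <- NULL
  res
}

#' Histidine-catalysed methionine oxidation
#'
#' A methionine is at risk of histidine-catalysed oxidation when at
#' least one histidine imidazole heavy atom lies within `hisRadius` of
#' its sulfur AND the methionine is itself exposure-flagged, or a
#' different exposure-flagged methionine sulfur lies within
#' `metPairRadius`. This generalises the buried-Met case where a
#' neighbouring exposed methionine relays the oxidation.
#'
#' @param structure a [ProteinStructure-class].
#' @param metResno residue number of the methionine to assess.
#' @param flags oxidation table from [oxidationRisk()] (supplies the
#'   exposure flags).
#' @param chain chain of the methionine (default: first chain carrying
#'   that residue).
#' @param hisRadius His-imidazole to Met-sulfur radius, Angstrom (10).
#' @param metPairRadius Met-sulfur pair radius, Angstrom (6).
#' @param model model index.
#' @return list: `his_catalysis` (logical), `nearby_his` (`data.frame`
#'   of histidines with closest imidazole heavy-atom distance), and
#'   `paired_met` (flagged Met sulfurs within the pair radius).
#' @export
hisCatalysis <- function(structure, metResno, flags, chain = NULL,
                         hisRadius = 10.0, metPairRadius = 6.0, model = 1L) {
  a <- structure@atoms
  if (is.null(chain)) {
    chain <- a$chain[a$resno == metResno & a$resid == "MET"][1]
    if (is.na(chain)) stop("residue ", metResno, " is not a methionine",
                           call. = FALSE)
  }
  sdIdx <- which(a$resno == metResno & a$chain == chain & a$name == "SD")
  if (!length(sdIdx)) stop("residue ", metResno, " has no SD atom",
                           call. = FALSE)
  xyz <- atomCoords(structure, model)
  sd <- xyz[sdIdx[1], ]
  imidNames <- c("CG", "ND1", "CD2", "CE1", "NE2")
  hisRows <- which(a$resid == "HIS" & a$name %in% imidNames)
  nearbyHis <- data.frame(chain = character(0), resno = integer(0),
                          distance = numeric(0))
  if (length(hisRows)) {
    d <- sqrt(colSums((t(xyz[hisRows, , drop = FALSE]) - sd)^2))
    key <- paste(a$chain[hisRows], a$resno[hisRows])
    dmin <- tapply(d, key, min)
    first <- !duplicated(key)
    nearbyHis <- data.frame(chain = a$chain[hisRows][first],
                            resno = a$resno[hisRows][first],
                            distance = as.numeric(dmin[key[first]]))
    nearbyHis <- nearbyHis[nearbyHis$distance <= hisRadius, , drop = FALSE]
    nearbyHis <- nearbyHis[order(nearbyHis$distance), , drop = FALSE]
    rownames(nearbyHis) <- NULL
  }
  selfFlag <- any(flags$flagged & flags$resno == metResno &
                    flags$chain == chain & flags$resid == "MET")
  otherSD <- which(a$resid == "MET" & a$name == "SD" &
                     !(a$resno == metResno & a$chain == chain))
  paired <- data.frame(chain = character(0), resno = integer(0),
                       distance = numeric(0))
  if (length(otherSD)) {
    d <- sqrt(colSums((t(xyz[otherSD, , drop = FALSE]) - sd)^2))
    flagOK <- mapply(function(ch, rn) any(flags$flagged & flags$resno == rn &
                                            flags$chain == ch),
                     a$chain[otherSD], a$resno[otherSD])
    keep <- d <= metPairRadius & flagOK
    paired <- data.frame(chain = a$chain[otherSD][keep],
                         resno = a$resno[otherSD][keep],
                         distance = d[keep])
    rownames(paired) <- NULL
  }
  list(his_catalysis = nrow(nearbyHis) > 0 && (selfFlag || nrow(paired) > 0),
       nearby_his = nearbyHis, paired_met = paired)
}

#' Structural aggregation-prone (STAP) hotspot filter
#'
#' Residues whose structure-corrected aggregation score (for example an
#' Aggrescan3D score) strictly exceeds the threshold, restricted to the
#' aggregation interface and excluding conserved residues:
#' `{r : score(r) > threshold}` intersected with `interface` minus
#' `conserved`.
#'
#' @param scores named numeric vector (names are residue numbers) or
#'   `data.frame` with columns `resno`, `score`.
#' @param interface integer residue numbers of the aggregation interface
#'   (for example from [aggregationInterface()]).
#' @param conserved integer residue numbers to exclude.
#' @param threshold score threshold (default 1.0, strict `>`).
#' @return Sorted integer residue numbers.
#' @export
#' @examples
#' stapFilter(c(`57` = 1.4, `58` = 1.2, `90` = 0.3),
#'            interface = c(57, 58), conserved = 58)
stapFilter <- function(scores, interface, conserved = integer(0),
                       threshold = 1.0) {
  if (is.data.frame(scores)) {
    v <- scores$score
    names(v) <- scores$resno
    scores <- v
  }
  hot <- as.integer(names(scores)[scores > threshold])
  sort(setdiff(intersect(hot, as.integer(interface)),
               as.integer(conserved)))
}

#' Binding-critical residues from an alanine scan
#'
#' Residues whose alanine substitution raises the antibody-antigen
#' binding free energy by strictly more than the threshold
#' (1.0 kcal/mol); these are never mutated.
#'
#' @param ddg named numeric vector or `data.frame` with columns `resno`,
#'   `ddg_kcal_mol`.
#' @param threshold kcal/mol (strict `>`).
#' @return Sorted integer residue numbers.
#' @export
bindingCritical <- function(ddg, threshold = 1.0) {
  if (is.data.frame(ddg)) {
    v <- ddg$ddg_kcal_mol
    names(v) <- ddg$resno
    ddg <- v
  }
  sort(as.integer(names(ddg)[ddg > threshold]))
}

#' Combined stability hotspot report
#'
#' Merges the evidence streams into one per-residue report: reduction-
#' prone interchain cysteines (reason `redox`), STAP residues on the
#' aggregation interface (`STAP-interface`), exposure- or catalysis-
#' flagged Met/Trp (`oxidation` / `oxidation-catalysis`). A residue is
#' mutable when it has at least one reason and is neither conserved nor
#' binding-critical.
#'
#' @param redox optional `data.frame` from [redoxTable()] with a `resno`
#'   column identifying the cysteine position of each bond.
#' @param oxidation optional `data.frame` from [oxidationRisk()];
#'   rows with `flagged == TRUE` contribute. A logical `his_catalysis`
#'   column (from [hisCatalysis()]) adds the catalysis reason.
#' @param stap integer residue numbers from [stapFilter()].
#' @param bindingCritical integer residue numbers from
#'   [bindingCritical()].
#' @param conserved integer residue numbers of conserved positions.
#' @param sequence optional parent sequence used to fill residue names.
#' @return A [HotspotReport-class].
#' @export
hotspotReport <- function(redox = NULL, oxidation = NULL,
                          stap = integer(0), bindingCritical = integer(0),
                          conserved = integer(0), sequence = NULL) {
  reasons <- list()
  resid <- character(0)
  addReason <- function(resno, reason, name = NA_character_) {
    key <- as.character(resno)
    reasons[[key]] <<- union(reasons[[key]], reason)
    if (!is.na(name)) resid[key] <<- name
  }
  if (!is.null(redox)) {
    if (!"resno" %in% names(redox))
      stop("redox table needs a resno column", call. = FALSE)
    for (i in which(redox$classification == "reduction-prone"))
      addReason(redox$resno[i], "redox", "CYS")
  }
  if (!is.null(oxidation) && nrow(oxidation)) {
    hasCat <- "his_catalysis" %in% names(oxidation)
    for (i in seq_len(nrow(oxidation))) {
      if (isTRUE(oxidation$flagged[i]))
        addReason(oxidation$resno[i], "oxidation", oxidation$resid[i])
      if (hasCat && isTRUE(oxidation$his_catalysis[i]))
        addReason(oxidation$resno[i], "oxidation-catalysis",
                  oxidation$resid[i])
    }
  }
  for (r in stap) addReason(r, "STAP-interface")
  resno <- sort(as.integer(names(reasons)))
  if (!is.null(sequence)) {
    s <- .seqLetters(sequence)
    fill <- resno[resno <= length(s)]
    resid[as.character(fill)] <- aa1to3(s[fill])
  }
  bindingCritical <- as.integer(bindingCritical)
  conserved <- as.integer(conserved)
  tab <- do.call(rbind, lapply(resno, function(r) {
    excl <- c(if (r %in% conserved) "conserved",
              if (r %in% bindingCritical) "binding-critical")
    data.frame(resno = r,
               resid = if (as.character(r) %in% names(resid))
                 resid[[as.character(r)]] else NA_character_,
               reasons = paste(sort(reasons[[as.character(r)]]),
                               collapse = ";"),
               excluded_because = paste(excl, collapse = ";"),
               mutable = length(excl) == 0L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    tab <- data.frame(resno = integer(0), resid = character(0),
                      reasons = character(0),
                      excluded_because = character(0), mutable = logical(0))
  rownames(tab) <- NULL
  new("HotspotReport", table = tab)
}

#' @rdname reportTable
#' @export
setMethod("reportTable", "HotspotReport", function(x) x@table)

setMethod("show", "HotspotReport", function(object) {
  tab <- object@table
  cat("HotspotReport:", nrow(tab), "flagged residue(s),",
      sum(tab$mutable), "mutable\n")
  if (nrow(tab)) print(tab, row.names = FALSE)
})

#' Mutable hotspot residues of a report
#'
#' @param report a [HotspotReport-class].
#' @return Integer residue numbers with `mutable == TRUE`.
#' @export
mutableHotspots <- function(report) {
  tab <- reportTable(report)
  tab$resno[tab$mutable]
}
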