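#' @include hotspots.R
NULL

# substitution options per wild-type residue (one-letter):
# Cys -> Ser (removes the labile thiol); Trp -> Phe (similar side chain,
# no oxidation risk); hydrophobics -> Lys or Asp (charged, aggregation-
# breaking). Option order K before D is part of the deterministic
# enumeration order.
.SITE_OPTIONS <- function(wt) {
  if (wt == "C") return("S")
  if (wt == "W") return("F")
  if (wt %in% c("A", "V", "L", "I", "F", "M", "Y")) return(c("K", "D"))
  character(0)
}

#' Enumerate candidate variants from mutable hotspots
#'
#' Rule-based enumeration: per-site options are Cys->S, Trp->F and
#' hydrophobic->K/D; all combinations of up to `maxSubstitutions` sites
#' are produced, each containing every always-on site (by default the
#' redox-flagged cysteines, mirroring the practice of carrying the
#' hinge Cys->Ser substitution in every variant). Binding-critical or
#' otherwise non-mutable residues are never mutated. Naming is
#' deterministic: `M1..Mn` in order of substitution count, then
#' ascending site numbers, then option order.
#'
#' @param report a [HotspotReport-class].
#' @param sequence parent one-letter sequence (position = residue
#'   number).
#' @param maxSubstitutions maximum substitutions per variant (default 3).
#' @param alwaysOn residue numbers present in every variant; default:
#'   mutable redox-flagged cysteines.
#' @return `data.frame`: `name`, `substitutions` (slash-joined, e.g.
#'   `"C130S/F57K"`), `n_subs`, list-column `subs` of per-substitution
#'   `data.frame`s (`resno`, `wt`, `mut`).
#' @export
enumerateVariants <- function(report, sequence, maxSubstitutions = 3L,
                              alwaysOn = NULL) {
  tab <- reportTable(report)
  s <- .seqLetters(sequence)
  mutable <- tab$resno[tab$mutable]
  if (!length(mutable)) stop("no mutable hotspot residues", call. = FALSE)
  if (any(mutable > length(s)))
    stop("hotspot residue beyond sequence length", call. = FALSE)
  if (is.null(alwaysOn))
    alwaysOn <- tab$resno[tab$mutable & grepl("redox", tab$reasons)]
  alwaysOn <- intersect(as.integer(alwaysOn), mutable)
  sites <- sort(mutable)
  opts <- lapply(sites, function(r) .SITE_OPTIONS(s[r]))
  names(opts) <- sites
  sites <- sites[lengths(opts) > 0]
  opts <- opts[lengths(opts) > 0]
  if (!length(sites)) stop("no substitution rules apply to the mutable set",
                           call. = FALSE)
  optional <- setdiff(sites, alwaysOn)
  kmax <- maxSubstitutions - length(alwaysOn)
  if (kmax < 0)
    stop("always-on sites exceed maxSubstitutions", call. = FALSE)
  siteSets <- list()
  for (k in 0:min(kmax, length(optional))) {
    combos <- if (k == 0) list(integer(0))
    else {
      cm <- utils::combn(optional, k)
      lapply(seq_len(ncol(cm)), function(j) cm[, j])
    }
    siteSets <- c(siteSets, lapply(combos, function(x)
      sort(c(alwaysOn, x))))
  }
  # order site sets: fewer substitutions first, then lexicographic sites
  keys <- vapply(siteSets, function(x)
    paste(length(x), paste(sprintf("%05d", x), collapse = ","))
  , character(1))
  siteSets <- siteSets[order(keys)]
  variants <- list()
  for (set in siteSets) {
    choice <- expand.grid(rev(lapply(as.character(set), function(r)
      opts[[r]])), stringsAsFactors = FALSE)
    choice <- choice[, rev(seq_along(set)), drop = FALSE]
    for (j in seq_len(nrow(choice))) {
      subs <- data.frame(resno = set, wt = s[set],
                         mut = as.character(unlist(choice[j, ])),
                         stringsAsFactors = FALSE)
      variants[[length(variants) + 1L]] <- subs
    }
  }
  labels <- vapply(variants, function(subs)
    paste(paste0(subs$wt, subs$resno, subs$mut), collapse = "/"),
    character(1))
  keep <- !duplicated(labels)
  variants <- variants[keep]
  labels <- labels[keep]
  data.frame(name = paste0("M", seq_along(variants)),
             substitutions = labels,
             n_subs = vapply(variants, nrow, integer(1)),
             subs = I(variants), stringsAsFactors = FALSE)
}

.parseSubstitutions <- function(variant) {
  if (is.data.frame(variant) && all(c("resno", "wt", "mut") %in%
                                      names(variant))) return(variant)
  if (is.list(variant) && !is.null(variant$subs)) return(variant$subs[[1]])
  parts <- strsplit(as.character(variant), "/", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
  if (any(lengths(m) != 4))
    stop("cannot parse substitution spec: ", variant, call. = FALSE)
  data.frame(resno = as.integer(vapply(m, `[`, character(1), 3)),
             wt = vapply(m, `[`, character(1), 2),
             mut = vapply(m, `[`, character(1), 4),
             stringsAsFactors = FALSE)
}

#' Apply a variant to a sequence or structure
#'
#' Sequences get their letters replaced after verifying the wild-type
#' letter at each position. Structures get the residue renamed and its
#' side chain truncated beyond the beta carbon (no rotamer building),
#' so downstream scoring uses the mutated identity with the wild-type
#' backbone geometry.
#'
#' @param x one-letter sequence string or [ProteinStructure-class].
#' @param variant substitution spec: `"C130S/W111F"`, a row of
#'   [enumerateVariants()] output, or a `data.frame` with `resno`, `wt`,
#'   `mut`.
#' @return Mutated object of the same class as `x`.
#' @export
#' @examples
#' applyVariant("ACDEF", "C2S")
applyVariant <- function(x, variant) {
  subs <- .parseSubstitutions(variant)
  if (anyDuplicated(subs$resno))
    stop("two substitutions at one position", call. = FALSE)
  if (is.character(x)) {
    s <- .seqLetters(x)
    for (i in seq_len(nrow(subs))) {
      r <- subs$resno[i]
      if (r > length(s) || s[r] != subs$wt[i])
        stop("wild-type mismatch at position ", r, ": expected ",
             subs$wt[i], ", found ", if (r <= length(s)) s[r] else "nothing",
             call. = FALSE)
      s[r] <- subs$mut[i]
    }
    return(paste(s, collapse = ""))
  }
  stopifnot(is(x, "ProteinStructure"))
  a <- x@atoms
  drop <- logical(nrow(a))
  for (i in seq_len(nrow(subs))) {
    r <- subs$resno[i]
    rows <- a$resno == r & a$type == "ATOM"
    if (!any(rows))
      stop("wild-type mismatch at position ", r, ": residue absent",
           call. = FALSE)
    wt3 <- aa1to3(subs$wt[i])
    if (!all(a$resid[rows] == wt3))
      stop("wild-type mismatch at position ", r, ": expected ", wt3,
           ", found ", a$resid[rows][1], call. = FALSE)
    a$resid[rows] <- aa1to3(subs$mut[i])
    drop <- drop | (rows & !(a$name %in% c(.BACKBONE_ATOMS, "CB")))
  }
  keep <- !drop
  a <- a[keep, , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  coords <- x@coords[keep, , , drop = FALSE]
  proteinStructure(a, coords)
}

#' Evaluate a variant against its parent
#'
#' Recomputes net charge, isoelectric point, SAP score and
#' developability index on the mutated sequence/structure and reports
#' the change relative to the parent, plus rule-based risk notes: two or
#' more aspartate substitutions trigger a colloidal-stability warning
#' (charge-mediated aggregation), and Trp->Phe substitutions are noted
#' as clearing the oxidation liability at that site.
#'
#' @param parent parent [ProteinStructure-class].
#' @param variant substitution spec (see [applyVariant()]).
#' @param cdr CDR ranges for the SAP score (see [sapScore()]).
#' @param pH working pH for the charge model (default 6.0).
#' @param profile optional precomputed parent [SASAProfile-class].
#' @param parentSAP optional precomputed parent [sapProfile()] output.
#' @param ... passed to [sapProfile()].
#' @return `data.frame` with parent/variant/delta values for
#'   `net_charge`, `pI`, `sap_score`, `di`, and a `warnings` attribute.
#' @export
evaluateVariant <- function(parent, variant, cdr, pH = 6.0,
                            profile = NULL, parentSAP = NULL, ...) {
  subs <- .parseSubstitutions(variant)
  mutant <- applyVariant(parent, subs)
  pseq <- as.character(chainSequences(parent)[[1]])
  mseq <- applyVariant(pseq, subs)
  if (is.null(profile)) profile <- shrakeRupley(parent)
  if (is.null(parentSAP))
    parentSAP <- sapProfile(parent, profile, ...)
  mutantSAP <- sapProfile(mutant, shrakeRupley(mutant), ...)
  p <- c(net_charge = netCharge(pseq, pH), pI = isoelectricPoint(pseq),
         sap_score = sapScore(parentSAP, cdr))
  v <- c(net_charge = netCharge(mseq, pH), pI = isoelectricPoint(mseq),
         sap_score = sapScore(mutantSAP, cdr))
  p["di"] <- developabilityIndex(p[["sap_score"]], p[["net_charge"]])
  v["di"] <- developabilityIndex(v[["sap_score"]], v[["net_charge"]])
  out <- data.frame(metric = names(p), parent = as.numeric(p),
                    variant = as.numeric(v),
                    delta = as.numeric(v - p), stringsAsFactors = FALSE)
  warnings <- character(0)
  if (sum(subs$mut == "D") >= 2)
    warnings <- c(warnings,
                  "colloidal-stability risk: two or more Asp substitutions")
  wf <- subs$wt == "W" & subs$mut == "F"
  if (any(wf))
    warnings <- c(warnings, paste0("oxidation liability cleared at W",
                                   subs$resno[wf], collapse = "; "))
  attr(out, "warnings") <- warnings
  out
}
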