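#' Per-week rate of change of a stability readout
#'
#' `(value at end - value at start) / weeks`; decreases give negative
#' rates.
#'
#' @param v0 value at day 0.
#' @param vEnd value at the end of the stress period (for example day
#'   28).
#' @param weeks duration in weeks (default 4).
#' @return Rate per week.
#' @export
#' @examples
#' rateOfChange(0.1, 1.7)  # 0.4 per week
rateOfChange <- function(v0, vEnd, weeks = 4) {
  if (any(weeks <= 0)) stop("weeks must be positive", call. = FALSE)
  (vEnd - v0) / weeks
}

#' Fold improvement of a degradation rate
#'
#' Ratio of the parent rate to the variant rate, reported to one
#' decimal. A zero variant rate means the improvement is not measurable
#' and returns `NA` (no error).
#'
#' @param parentRate,variantRate per-week rates on the same scale.
#' @return Fold improvement (1 decimal), or `NA` when the variant rate
#'   is zero.
#' @export
#' @examples
#' foldImprovement(38.2, 6.2)  # 6.2
foldImprovement <- function(parentRate, variantRate) {
  out <- ifelse(variantRate == 0, NA_real_,
                round(parentRate / variantRate, 1))
  out
}

.APPEARANCE_GRADES <- c("clear" = 9L, "slight-opalescent" = 7L,
                        "opalescent" = 5L, "turbid" = 3L, "particles" = 1L)

#' Grade sample appearance on the 5-level scale
#'
#' Maps the visual-inspection descriptor onto the 1/3/5/7/9 grading
#' (higher is better): clear 9, slight-opalescent 7, opalescent 5,
#' turbid 3, particles 1.
#'
#' @param descriptor character vector of descriptors.
#' @return Integer grades.
#' @export
#' @examples
#' gradeAppearance(c("clear", "particles"))
gradeAppearance <- function(descriptor) {
  out <- .APPEARANCE_GRADES[descriptor]
  if (anyNA(out))
    stop("unknown appearance descriptor: ",
         paste(descriptor[is.na(out)], collapse = ", "),
         "; expected one of ", paste(names(.APPEARANCE_GRADES),
                                     collapse = ", "), call. = FALSE)
  unname(out)
}

#' Feature-vs-attribute correlation screen
#'
#' Pearson correlation of every calculated structural feature against
#' every stability attribute over shared samples (pairwise complete
#' cases), with the two-sided p-value from the t statistic on n-2
#' degrees of freedom. A pair is flagged significant when `|r|` exceeds
#' `rThreshold` and `p` falls below `pThreshold` (defaults 0.5 / 0.1).
#' The absolute value is used because negative correlations are as
#' informative as positive ones. No multiple-testing correction enters
#' the flag; a Benjamini-Hochberg column is emitted as supplementary
#' output. Pairs with fewer than 3 complete cases are skipped with a
#' warning.
#'
#' @param features,attributes data.frames with samples as rows
#'   (matched by rownames when present, by position otherwise).
#' @param rThreshold,pThreshold significance rule thresholds.
#' @return Long-format `data.frame`: `feature`, `attribute`, `n`, `r`,
#'   `p`, `p_bh`, `significant`.
#' @export
#' @examples
#' tb <- makeStabilityTable(12, planted = data.frame(
#'   feature = "sap_score", attribute = "hmw_rate", rho = 0.9), seed = 1)
#' subset(correlationScreen(tb$features, tb$attributes), significant)
correlationScreen <- function(features, attributes, rThreshold = 0.5,
                              pThreshold = 0.1) {
  if (!is.null(rownames(features)) && !is.null(rownames(attributes))) {
    shared <- intersect(rownames(features), rownames(attributes))
    features <- features[shared, , drop = FALSE]
    attributes <- attributes[shared, , drop = FALSE]
  } else if (nrow(features) != nrow(attributes)) {
    stop("feature and attribute tables disagree on samples", call. = FALSE)
  }
  out <- list()
  for (ft in colnames(features)) for (at in colnames(attributes)) {
    x <- features[[ft]]; y <- attributes[[at]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) {
      warning("skipping ", ft, " vs ", at, ": fewer than 3 shared samples",
              call. = FALSE)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                          alternative = "two.sided")
    out[[length(out) + 1L]] <- data.frame(
      feature = ft, attribute = at, n = sum(ok),
      r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(feature = character(0), attribute = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0),
                      p_bh = numeric(0), significant = logical(0)))
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res$significant <- abs(res$r) > rThreshold & res$p < pThreshold
  rownames(res) <- NULL
  res
}
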