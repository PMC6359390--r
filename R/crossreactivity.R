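# Cross-reactivity arithmetic, log activities and specificity counts.

#' Cross-reactivity of an immunoassay to an alternate compound
#'
#' For a competitive assay calibrated on compound A (the immunizing
#' hapten), the cross-reactivity towards compound B is the IC50 ratio
#' `CR_B = IC50_A / IC50_B * 100` (percent): an analog that inhibits the
#' assay at a lower concentration than the reference has CR above 100.
#'
#' @param ic50_ref IC50 of the reference (immunizing) compound.
#' @param ic50_alt IC50 of the alternate compound, same units.
#' @return cross-reactivity in percent.
#' @examples
#' cross_reactivity(5, 10) # 50
#' @export
cross_reactivity <- function(ic50_ref, ic50_alt) {
  if (any(ic50_ref <= 0) || any(ic50_alt <= 0)) {
    stop("IC50 values must be positive", call. = FALSE)
  }
  ic50_ref / ic50_alt * 100
}

#' Convert a cross-reactivity table to log10 activities
#'
#' QSAR activities are `log10(CR)`.  Left-censored entries ("<LOD")
#' have no defined logarithm; they are either imputed at a fixed CR
#' value inside `(0, LOD]` (and flagged) or dropped.  Untested entries
#' are always dropped.
#'
#' @param table an `fq_crtable` from [load_cr_table()].
#' @param censor `"impute"` (default) or `"drop"`.
#' @param impute_cr CR percent assigned to censored entries under the
#'   impute policy; must lie in `(0, LOD]`.  The default 0.5 is the
#'   midpoint of the censoring interval for an LOD of 1 percent.
#' @return a named numeric vector of log10 activities with attribute
#'   `imputed` (logical mask of censored, imputed entries).
#' @export
log_activities <- function(table, censor = c("impute", "drop"),
                           impute_cr = 0.5) {
  censor <- match.arg(censor)
  stopifnot(inherits(table, "fq_crtable"))
  keep <- table$status != "not_tested"
  if (censor == "drop") keep <- keep & table$status == "measured"
  tab <- table[keep, , drop = FALSE]
  if (censor == "impute" && any(tab$status == "below_lod")) {
    lods <- tab$lod_percent[tab$status == "below_lod"]
    if (impute_cr <= 0 || any(impute_cr > lods)) {
      stop("impute_cr must lie in (0, LOD]", call. = FALSE)
    }
  }
  cr <- ifelse(tab$status == "measured", tab$cr_percent, impute_cr)
  y <- setNames(log10(cr), tab$compound_id)
  attr(y, "imputed") <- setNames(tab$status == "below_lod", tab$compound_id)
  y
}

#' Count compounds the assay is specific to
#'
#' Number of measured entries with cross-reactivity strictly greater
#' than a threshold.  Censored (below-LOD) entries never count.
#'
#' @param table an `fq_crtable`.
#' @param threshold_percent detection threshold in CR percent
#'   (default 1).
#' @return integer count.
#' @export
count_specific <- function(table, threshold_percent = 1) {
  stopifnot(threshold_percent >= 0)
  m <- table$status == "measured"
  sum(table$cr_percent[m] > threshold_percent)
}
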