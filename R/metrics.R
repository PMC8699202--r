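# Accuracy measures for CCS prediction: RMSE, MAE, MPE, MdPE, Delta90,
# R-squared and Pearson r, overall and stratified by charge or CCS range.

#' Absolute percentage errors
#'
#' @param pred Predicted CCS values.
#' @param ref Reference CCS values; must be strictly positive.
#' @return `100 * |pred - ref| / ref`, element-wise.
#' @export
percentage_errors <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref must have equal length")
  if (any(ref <= 0)) stop("reference CCS values must be positive")
  100 * abs(pred - ref) / ref
}

#' Evaluate CCS predictions
#'
#' Computes the seven standard accuracy measures: root mean square error and
#' mean absolute error (squared angstroms), mean and median absolute
#' percentage error, the 90th percentile of absolute percentage errors
#' (Delta90, the error bound that fits 90 percent of predictions), the
#' coefficient of determination `R2 = 1 - SSres/SStot`, and Pearson's r.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param pred,ref Predicted and reference CCS values (at least 2 records).
#' @return A one-row data.frame with columns `n`, `rmse`, `mae`, `mpe`,
#'   `mdpe`, `delta90`, `r2`, `r`.
#' @export
evaluate_ccs <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref must have equal length")
  if (length(ref) < 2L) stop("need at least 2 records")
  if (any(ref <= 0)) stop("reference CCS values must be positive")
  if (stats::var(ref) == 0)
    stop("reference values are constant; R2 and r are undefined")
  e <- pred - ref
  pe <- percentage_errors(pred, ref)
  data.frame(
    n = length(ref),
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    mpe = mean(pe),
    mdpe = stats::median(pe),
    delta90 = as.numeric(stats::quantile(pe, 0.9, type = 7)),
    r2 = 1 - sum(e^2) / sum((ref - mean(ref))^2),
    r = stats::cor(pred, ref)
  )
}

#' Evaluation stratified by a grouping factor
#'
#' @param pred,ref As in [evaluate_ccs()].
#' @param group Grouping vector (e.g. charge states or CCS range labels).
#' @return Data frame with one `overall` row followed by one row per group
#'   with at least 2 records; groups with fewer records are skipped with a
#'   warning.
#' @export
evaluate_ccs_by <- function(pred, ref, group) {
  out <- cbind(subset = "overall", evaluate_ccs(pred, ref))
  for (g in sort(unique(group))) {
    i <- group == g
    if (sum(i) < 2L || stats::var(ref[i]) == 0) {
      warning("group ", g, " has fewer than 2 usable records; skipped")
      next
    }
    out <- rbind(out, cbind(subset = as.character(g),
                            evaluate_ccs(pred[i], ref[i])))
  }
  out
}

#' Label CCS values by range
#'
#' Standard strata 0-400, 400-800 and 800-1200 squared angstroms used for
#' range-wise accuracy reporting.
#'
#' @param ccs CCS values.
#' @param breaks Range boundaries.
#' @return Character vector of range labels.
#' @export
ccs_range_labels <- function(ccs, breaks = c(0, 400, 800, 1200)) {
  as.character(cut(ccs, breaks = c(breaks, Inf),
                   labels = c(paste(utils::head(breaks, -1), breaks[-1], sep = "-"),
                              paste0(">", breaks[length(breaks)])),
                   right = TRUE, include.lowest = TRUE))
}
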