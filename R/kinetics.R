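#' Construct a scratch time series
#'
#' @param wellId label for the well.
#' @param times numeric vector of hours, strictly increasing; the first entry
#'   is T0.
#' @param masks list of [WoundMask-class] objects, one per time, all with
#'   identical frame dimensions (frames are assumed re-located fields of the
#'   same well; no registration is applied, and a dimension mismatch is a
#'   hard error).
#' @return a [ScratchSeries-class].
#' @export
scratchSeries <- function(wellId, times, masks) {
  new("ScratchSeries", wellId = as.character(wellId),
      times = as.numeric(times), masks = masks)
}

#' Percentage of the initial wound still open
#'
#' The method's reported quantity: every wound area is expressed relative to
#' the initial wound at T0, `openPct(t) = 100 * area(t) / area(T0)`, with
#' `closurePct = 100 - openPct`. Values above 100 (a wound that grew, e.g.
#' through detachment) are reported uncapped and flagged "EXPANDED" so the
#' supervisor sees the evidence rather than a silently clipped number.
#'
#' @param series a [ScratchSeries-class]; the T0 mask must have a non-zero
#'   wound area.
#' @return a [ClosureResult-class].
#' @examples
#' m1 <- new("WoundMask", pixels = matrix(rep(c(TRUE, FALSE), c(40, 60)), 10),
#'           nComponentsKept = 1L, overridden = FALSE)
#' m2 <- new("WoundMask", pixels = matrix(rep(c(TRUE, FALSE), c(20, 80)), 10),
#'           nComponentsKept = 1L, overridden = FALSE)
#' openWoundPercent(scratchSeries("w1", c(0, 24), list(m1, m2)))
#' @export
openWoundPercent <- function(series) {
  stopifnot(is(series, "ScratchSeries"))
  areas <- vapply(series@masks, woundArea, numeric(1))
  if (areas[1L] == 0)
    stop("no initial wound detected at T0; consider a manual override ",
         "(applyOverride) to supply the wound region")
  open <- 100 * areas / areas[1L]
  open[1L] <- 100  # exact by definition
  flags <- ifelse(open > 100, "EXPANDED", "")
  new("ClosureResult", wellId = series@wellId, times = series@times,
      openPct = open, closurePct = 100 - open, flags = flags)
}

#' Summarize closure results across replicate wells by condition
#'
#' @param results list of [ClosureResult-class] objects.
#' @param conditions character vector, one condition label per result.
#' @return a data.frame with one row per (condition, time): mean, sd and n of
#'   `open_pct`. A single replicate reports sd = 0 with n = 1.
#' @export
compareConditions <- function(results, conditions) {
  if (length(results) == 0L) stop("no results supplied")
  if (length(conditions) != length(results))
    stop("conditions must label each result (lengths differ)")
  if (!all(vapply(results, is, logical(1), class2 = "ClosureResult")))
    stop("results must be ClosureResult objects")
  long <- do.call(rbind, Map(function(res, cond) {
    data.frame(condition = cond, time_h = res@times, open_pct = res@openPct,
               stringsAsFactors = FALSE)
  }, results, conditions))
  agg <- do.call(rbind, lapply(
    split(long, list(long$condition, long$time_h), drop = TRUE),
    function(g) data.frame(
      condition = g$condition[1L], time_h = g$time_h[1L],
      mean_open_pct = mean(g$open_pct),
      sd_open_pct = if (nrow(g) > 1L) stats::sd(g$open_pct) else 0,
      n = nrow(g), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$condition, agg$time_h), ]
  rownames(agg) <- NULL
  agg
}
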