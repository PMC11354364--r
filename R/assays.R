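#' MTT viability percentage from dual-wavelength absorbances
#'
#' `100 * (T - Tc) / (C - Cc)`, where T / Tc are the treated well's 570 nm
#' signal and 630 nm background, and C / Cc the untreated control's. Growth
#' inhibition (%) is `100 - viability`. The result is invariant to adding a
#' constant to all four absorbances.
#'
#' @param T treated absorbance at 570 nm.
#' @param Tc treated background absorbance at 630 nm.
#' @param C control absorbance at 570 nm.
#' @param Cc control background absorbance at 630 nm.
#' @return viability as a percentage (vectorized over the treated pair).
#' @examples
#' viabilityPercent(0.8, 0.1, 0.8, 0.1)   # 100
#' viabilityPercent(0.45, 0.1, 0.8, 0.1)  # 50
#' @export
viabilityPercent <- function(T, Tc, C, Cc) {
  if (any(!is.finite(c(T, Tc, C, Cc)))) stop("absorbances must be finite")
  if (C - Cc <= 0) stop("control signal not above background (C - Cc <= 0)")
  100 * (T - Tc) / (C - Cc)
}

#' Growth-inhibition level concentration (GI50 / GI25 / GI10)
#'
#' The concentration causing `level` % growth inhibition, i.e. where
#' viability crosses `v* = 100 - level`. The curve is scanned along
#' increasing concentration for the first adjacent pair bracketing `v*` on a
#' non-increasing (viability-decreasing) segment, and the concentration is
#' interpolated linearly in log10(concentration) vs viability. A node hit
#' returns the node concentration exactly.
#'
#' Statuses instead of a number: `"above_range"` when even the highest tested
#' concentration leaves viability above `v*` (the level concentration lies
#' above the tested range), `"below_range"` when viability is already below
#' `v*` at the lowest concentration, and `"non_monotone_ambiguous"` when
#' `v*` is crossed only on a locally increasing segment.
#'
#' @param curve a data.frame with columns `concentration` (strictly
#'   increasing, positive) and `viability_pct`, e.g. from
#'   [doseResponseCurve()].
#' @param level inhibition level in percent (50, 25 or 10 in the assay
#'   design, but any level in (0, 100) is accepted).
#' @return a one-row data.frame with columns `level`, `concentration`
#'   (NA when not estimable) and `status` ("ok" or the status above).
#' @examples
#' curve <- data.frame(concentration = c(1, 10, 100),
#'                     viability_pct = c(100, 50, 0))
#' giLevel(curve, 50)  # 10 exactly
#' @export
giLevel <- function(curve, level) {
  stopifnot(is.data.frame(curve),
            all(c("concentration", "viability_pct") %in% names(curve)))
  conc <- curve$concentration
  viab <- curve$viability_pct
  if (length(conc) < 2L) stop("at least 2 dose-response points are required")
  if (any(conc <= 0) || is.unsorted(conc, strictly = TRUE))
    stop("concentrations must be positive and strictly increasing")
  vstar <- 100 - level
  res <- function(concentration, status)
    data.frame(level = level, concentration = concentration, status = status,
               stringsAsFactors = FALSE)
  # exact node hit first
  hit <- which(viab == vstar)
  if (length(hit)) return(res(conc[hit[1L]], "ok"))
  crossed <- FALSE
  for (i in seq_len(length(conc) - 1L)) {
    lo <- viab[i]; hi <- viab[i + 1L]
    if ((lo - vstar) * (hi - vstar) < 0) {
      crossed <- TRUE
      if (lo > hi) {  # decreasing segment: interpolate in log10(conc)
        lx <- log10(conc[i]) +
          (log10(conc[i + 1L]) - log10(conc[i])) * (lo - vstar) / (lo - hi)
        return(res(10^lx, "ok"))
      }
    }
  }
  if (crossed) return(res(NA_real_, "non_monotone_ambiguous"))
  if (all(viab > vstar)) return(res(NA_real_, "above_range"))
  res(NA_real_, "below_range")
}

#' Dual-dye fluorescence ratio
#'
#' The three stain readouts of the assay panel:
#' \describe{
#'   \item{AO_PI}{green / orange — acridine orange stains all cells green,
#'     propidium iodide enters membrane-compromised cells (orange); the ratio
#'     proxies viability.}
#'   \item{JC1}{orange / green — JC-1 aggregates shift emission green to
#'     orange at high mitochondrial membrane potential.}
#'   \item{NAO}{the mean green fluorescence passed through unchanged, as the
#'     proxy for total mitochondrial mass.}
#' }
#'
#' @param meanGreen mean green fluorescence (a.u., >= 0).
#' @param meanOrange mean orange fluorescence (a.u., >= 0).
#' @param stain "AO_PI", "JC1" or "NAO".
#' @return a one-row data.frame with columns `stain`, `value` and `status`
#'   ("ok", or "undefined_ratio" with `value = NA` when the denominator is
#'   zero).
#' @examples
#' fluorescenceRatio(120, 60, "JC1")$value  # 0.5
#' @export
fluorescenceRatio <- function(meanGreen, meanOrange, stain = c("AO_PI", "JC1", "NAO")) {
  stain <- match.arg(stain)
  if (meanGreen < 0 || meanOrange < 0) stop("intensities must be >= 0")
  val <- switch(stain,
    AO_PI = if (meanOrange > 0) meanGreen / meanOrange else NA_real_,
    JC1   = if (meanGreen > 0) meanOrange / meanGreen else NA_real_,
    NAO   = meanGreen)
  data.frame(stain = stain, value = val,
             status = if (is.na(val)) "undefined_ratio" else "ok",
             stringsAsFactors = FALSE)
}

#' Gene-expression fold change by the delta-delta-Cq method
#'
#' Replicate Cq values are averaged arithmetically per (gene, sample);
#' `dCq = Cq(target) - Cq(reference)` within each sample;
#' `ddCq = dCq(treated) - dCq(control)`; fold change = `2^(-ddCq)`
#' (100 % amplification efficiency assumed, the standard form of the method).
#'
#' @param cqTable data.frame with columns `gene`, `sample` ("treated" or
#'   "control") and `cq` (one row per replicate, Cq in (0, 50)).
#' @param targetGene gene to quantify.
#' @param referenceGene housekeeping reference (default "HPRT1").
#' @return the fold change (numeric scalar).
#' @examples
#' tab <- data.frame(gene = rep(c("HSP90A", "HPRT1"), each = 2),
#'                   sample = rep(c("treated", "control"), 2),
#'                   cq = c(25, 24, 20, 20))
#' ddcqFoldChange(tab, "HSP90A")  # 0.5
#' @export
ddcqFoldChange <- function(cqTable, targetGene, referenceGene = "HPRT1") {
  stopifnot(is.data.frame(cqTable),
            all(c("gene", "sample", "cq") %in% names(cqTable)))
  if (any(cqTable$cq <= 0 | cqTable$cq >= 50))
    stop("Cq values must lie in (0, 50)")
  meanCq <- function(gene, sample) {
    v <- cqTable$cq[cqTable$gene == gene & cqTable$sample == sample]
    if (length(v) == 0L)
      stop(sprintf("missing Cq cell: gene '%s', sample '%s'", gene, sample))
    mean(v)
  }
  dTreated <- meanCq(targetGene, "treated") - meanCq(referenceGene, "treated")
  dControl <- meanCq(targetGene, "control") - meanCq(referenceGene, "control")
  2^(-(dTreated - dControl))
}

#' Dose-response curve from a plate of well readings
#'
#' Averages the control wells' background-corrected signal and converts each
#' treated well to viability % via [viabilityPercent()]; replicate treated
#' wells at the same concentration are averaged.
#'
#' @param plate data.frame with columns `well`, `role` ("treated"/"control"),
#'   `concentration` (µM, NA for controls), `a570`, `a630`, e.g. from
#'   [simulatePlate()].
#' @return a data.frame with `concentration` (increasing) and
#'   `viability_pct`, ready for [giLevel()].
#' @export
doseResponseCurve <- function(plate) {
  stopifnot(is.data.frame(plate),
            all(c("role", "concentration", "a570", "a630") %in% names(plate)))
  ctl <- plate[plate$role == "control", ]
  if (nrow(ctl) == 0L) stop("plate has no control wells")
  C <- mean(ctl$a570); Cc <- mean(ctl$a630)
  trt <- plate[plate$role == "treated", ]
  if (nrow(trt) == 0L) stop("plate has no treated wells")
  viab <- vapply(seq_len(nrow(trt)), function(i)
    viabilityPercent(trt$a570[i], trt$a630[i], C, Cc), numeric(1))
  agg <- stats::aggregate(viab, list(concentration = trt$concentration), mean)
  names(agg)[2L] <- "viability_pct"
  agg[order(agg$concentration), , drop = FALSE]
}
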