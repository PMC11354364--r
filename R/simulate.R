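# run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# clipped ternary random walk used for ragged scratch edges
edgeWalk <- function(n, amplitude) {
  if (amplitude <= 0 || n == 0L) return(integer(n))
  w <- cumsum(sample(c(-1L, 0L, 1L), n, replace = TRUE))
  pmax(-amplitude, pmin(amplitude, w))
}

#' Simulate a scratched-monolayer micrograph with exact ground truth
#'
#' Emulates the texture contrast the entropy segmentation exploits: the cell
#' region is filled with high-entropy texture, the wound band with a flat
#' intensity (optionally plus Gaussian noise), and the band edges are
#' perturbed by a seeded, clipped random walk mimicking the ragged edge a
#' pipette tip leaves. The returned truth mask is the exact realized band, so
#' its area fraction is the realized (stored) ground truth, not the requested
#' target.
#'
#' @param width,height frame size in px.
#' @param woundFrac target wound fraction of the frame in \[0, 1); the band
#'   thickness is `round(woundFrac * extent)`.
#' @param orientation "vertical" (band spans all rows) or "horizontal".
#' @param edgeRoughness amplitude (px) of the edge random walk; 0 gives
#'   perfectly straight edges. Default 3.
#' @param cellTexture "iid_uniform" (iid uniform intensities on \[0, 255\],
#'   the maximal-entropy texture; default) or "speckle" (fraction `speckleP`
#'   of pixels uniform-random on a flat background).
#' @param speckleP speckle density in (0, 1\], used when
#'   `cellTexture = "speckle"`.
#' @param woundLevel flat wound intensity in \[0, 255\]. Default 140.
#' @param woundNoiseSd Gaussian noise sd (intensity units) inside the wound;
#'   default 0 (flat). Values > 0 raise the wound's entropy floor toward the
#'   threshold and enlarge the segmentation's edge offset.
#' @param seed integer seed; identical inputs give bitwise-identical output.
#' @return list with `image` (a [GrayImage-class]) and `truth`
#'   (a [WoundMask-class]).
#' @examples
#' sim <- simulateScratchImage(width = 200, height = 60, woundFrac = 0.3,
#'                             seed = 7)
#' areaFraction(sim$truth)
#' @export
simulateScratchImage <- function(width = 1600L, height = 480L, woundFrac = 0.35,
                                 orientation = c("vertical", "horizontal"),
                                 edgeRoughness = 3L,
                                 cellTexture = c("iid_uniform", "speckle"),
                                 speckleP = 0.3, woundLevel = 140L,
                                 woundNoiseSd = 0, seed = 1L) {
  orientation <- match.arg(orientation)
  cellTexture <- match.arg(cellTexture)
  if (woundFrac < 0 || woundFrac >= 1) stop("woundFrac must lie in [0, 1)")
  withSeed(seed, {
    # build in vertical-band frame (rows x cols), transpose at the end if needed
    H <- if (orientation == "vertical") height else width
    W <- if (orientation == "vertical") width else height
    tex <- if (cellTexture == "iid_uniform") {
      matrix(sample(0:255, H * W, replace = TRUE), H, W)
    } else {
      bg <- matrix(200L, H, W)
      sp <- matrix(stats::runif(H * W) < speckleP, H, W)
      bg[sp] <- sample(0:255, sum(sp), replace = TRUE)
      bg
    }
    truth <- matrix(FALSE, H, W)
    bandW <- as.integer(round(woundFrac * W))
    if (bandW > 0L) {
      c0 <- (W - bandW) %/% 2L + 1L
      wl <- edgeWalk(H, edgeRoughness)
      wr <- edgeWalk(H, edgeRoughness)
      for (y in seq_len(H)) {
        lo <- max(1L, c0 + wl[y])
        hi <- min(W, c0 + bandW - 1L + wr[y])
        if (hi >= lo) truth[y, lo:hi] <- TRUE
      }
      nW <- sum(truth)
      wvals <- rep(as.integer(woundLevel), nW)
      if (woundNoiseSd > 0)
        wvals <- pmax(0L, pmin(255L, as.integer(round(
          woundLevel + stats::rnorm(nW, 0, woundNoiseSd)))))
      tex[truth] <- wvals
    }
    if (orientation == "horizontal") {
      tex <- t(tex); truth <- t(truth)
    }
    list(image = grayImage(tex, sourceId = sprintf("synthetic-scratch-seed%d", seed)),
         truth = new("WoundMask", pixels = truth,
                     nComponentsKept = if (bandW > 0L) 1L else 0L,
                     overridden = FALSE))
  })
}

#' Simulate a wound-closure time series with exact ground truth
#'
#' Timepoint k reuses the T0 texture and edge walks (the same field imaged
#' again) but scales the wound band to `woundFrac * closureFracs[k]`,
#' centered at the same position. Truth masks are exact by construction.
#'
#' @inheritParams simulateScratchImage
#' @param closureFracs numeric vector in (0, 1\], first element exactly 1
#'   (T0); the fraction of the initial band thickness still open.
#' @param times numeric vector of hours, same length as `closureFracs`,
#'   strictly increasing.
#' @param wellId label for the simulated well.
#' @return list with `images` (list of [GrayImage-class]), `truthSeries`
#'   (a [ScratchSeries-class] of exact truth masks) and `times`.
#' @export
simulateScratchSeries <- function(width = 1600L, height = 480L,
                                  woundFrac = 0.35,
                                  closureFracs = c(1.0, 0.6, 0.1),
                                  times = c(0, 24, 48),
                                  edgeRoughness = 3L,
                                  cellTexture = c("iid_uniform", "speckle"),
                                  speckleP = 0.3, woundLevel = 140L,
                                  woundNoiseSd = 0, seed = 1L,
                                  wellId = "sim-well") {
  cellTexture <- match.arg(cellTexture)
  if (length(closureFracs) != length(times))
    stop("closureFracs and times must have equal length")
  if (abs(closureFracs[1L] - 1) > 1e-12)
    stop("closureFracs[1] must be 1.0 (the T0 reference)")
  if (any(closureFracs <= 0 | closureFracs > 1))
    stop("closureFracs must lie in (0, 1]")
  if (woundFrac < 0 || woundFrac >= 1) stop("woundFrac must lie in [0, 1)")
  withSeed(seed, {
    H <- height; W <- width
    tex0 <- if (cellTexture == "iid_uniform") {
      matrix(sample(0:255, H * W, replace = TRUE), H, W)
    } else {
      bg <- matrix(200L, H, W)
      sp <- matrix(stats::runif(H * W) < speckleP, H, W)
      bg[sp] <- sample(0:255, sum(sp), replace = TRUE)
      bg
    }
    bandW0 <- as.integer(round(woundFrac * W))
    mid <- (W + 1) / 2
    wl <- edgeWalk(H, edgeRoughness)
    wr <- edgeWalk(H, edgeRoughness)
    images <- vector("list", length(times))
    masks <- vector("list", length(times))
    for (k in seq_along(times)) {
      bandW <- as.integer(round(bandW0 * closureFracs[k]))
      truth <- matrix(FALSE, H, W)
      tex <- tex0
      if (bandW > 0L) {
        c0 <- as.integer(round(mid - bandW / 2))
        for (y in seq_len(H)) {
          lo <- max(1L, c0 + wl[y])
          hi <- min(W, c0 + bandW - 1L + wr[y])
          if (hi >= lo) truth[y, lo:hi] <- TRUE
        }
        nW <- sum(truth)
        wvals <- rep(as.integer(woundLevel), nW)
        if (woundNoiseSd > 0)
          wvals <- pmax(0L, pmin(255L, as.integer(round(
            woundLevel + stats::rnorm(nW, 0, woundNoiseSd)))))
        tex[truth] <- wvals
      }
      images[[k]] <- grayImage(tex, sourceId = sprintf(
        "synthetic-series-seed%d-t%g", seed, times[k]))
      masks[[k]] <- new("WoundMask", pixels = truth,
                        nComponentsKept = if (bandW > 0L) 1L else 0L,
                        overridden = FALSE)
    }
    list(images = images,
         truthSeries = scratchSeries(wellId, times, masks),
         times = times)
  })
}

#' Simulate an MTT dose-response plate
#'
#' Treated-well viability follows a four-parameter logistic in concentration,
#' `v(c) = bottom + (top - bottom) / (1 + (c / gi50True)^hill)`, so that at
#' `c = gi50True` (hill 1, top 100, bottom 0) viability is exactly 50 %.
#' Absorbances are `a570 = blank + v/100 * controlSignal + noise` for treated
#' wells, `blank + controlSignal + noise` for controls, and
#' `a630 = blank + noise` throughout.
#'
#' @param gi50True true GI50 in µM.
#' @param hill Hill slope (> 0; viability decreases with concentration).
#' @param top,bottom asymptotic viabilities in %.
#' @param dilutions concentration series in µM, strictly decreasing; default
#'   nine 2-fold dilutions from 200 µM (the assay's serial-dilution design).
#' @param noiseSd Gaussian absorbance noise sd (absorbance units).
#' @param blank blank absorbance offset.
#' @param controlSignal background-corrected control signal (absorbance).
#' @param nControl number of control wells.
#' @param seed integer seed.
#' @return a data.frame of wells: `well`, `role`, `concentration`, `a570`,
#'   `a630`, ready for [doseResponseCurve()].
#' @export
simulatePlate <- function(gi50True = 25, hill = 1, top = 100, bottom = 0,
                          dilutions = 200 / 2^(0:8), noiseSd = 0,
                          blank = 0.05, controlSignal = 1, nControl = 6L,
                          seed = 1L) {
  if (any(dilutions <= 0) || is.unsorted(rev(dilutions), strictly = TRUE))
    stop("dilutions must be positive and strictly decreasing")
  if (gi50True <= 0 || hill <= 0) stop("gi50True and hill must be positive")
  withSeed(seed, {
    v <- bottom + (top - bottom) / (1 + (dilutions / gi50True)^hill)
    nz <- function(n) if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else numeric(n)
    nt <- length(dilutions)
    treated <- data.frame(
      well = sprintf("T%02d", seq_len(nt)), role = "treated",
      concentration = dilutions,
      a570 = blank + v / 100 * controlSignal + nz(nt),
      a630 = blank + nz(nt), stringsAsFactors = FALSE)
    control <- data.frame(
      well = sprintf("C%02d", seq_len(nControl)), role = "control",
      concentration = NA_real_,
      a570 = blank + controlSignal + nz(nControl),
      a630 = blank + nz(nControl), stringsAsFactors = FALSE)
    rbind(treated, control)
  })
}

#' Simulate a qPCR Cq table with known true fold changes
#'
#' Per target gene, a control-sample delta-Cq (target minus reference) is
#' drawn, and the treated-sample delta-Cq is set to
#' `control dCq - log2(fold)`, so that the delta-delta-Cq method recovers the
#' requested fold exactly in the noiseless case. The reference gene's
#' underlying Cq is held equal across samples; replicate noise (sd in
#' cycles) is added to every replicate measurement.
#'
#' @param trueFolds named numeric vector, fold change per target gene (> 0).
#' @param noiseSd replicate noise sd in cycles (0 = exact).
#' @param nReplicates replicates per (gene, sample) cell.
#' @param referenceGene reference gene label (default "HPRT1").
#' @param referenceCq underlying reference-gene Cq (default 20).
#' @param seed integer seed.
#' @return a data.frame with columns `gene`, `sample`, `cq`, ready for
#'   [ddcqFoldChange()].
#' @examples
#' tab <- simulateCqTable(c(HSP90A = 3), seed = 2)
#' ddcqFoldChange(tab, "HSP90A")  # 3 exactly (noiseless)
#' @export
simulateCqTable <- function(trueFolds, noiseSd = 0, nReplicates = 3L,
                            referenceGene = "HPRT1", referenceCq = 20,
                            seed = 1L) {
  if (is.null(names(trueFolds)) || any(!nzchar(names(trueFolds))))
    stop("trueFolds must be a named vector (gene -> fold)")
  if (any(trueFolds <= 0)) stop("fold changes must be > 0")
  withSeed(seed, {
    rows <- list()
    nz <- function(n) if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else numeric(n)
    add <- function(gene, sample, base)
      data.frame(gene = gene, sample = sample,
                 cq = base + nz(nReplicates), stringsAsFactors = FALSE)
    for (g in names(trueFolds)) {
      dcqControl <- stats::runif(1, 2, 8)
      rows[[length(rows) + 1L]] <-
        add(g, "control", referenceCq + dcqControl)
      rows[[length(rows) + 1L]] <-
        add(g, "treated", referenceCq + dcqControl - log2(trueFolds[[g]]))
    }
    rows[[length(rows) + 1L]] <- add(referenceGene, "control", referenceCq)
    rows[[length(rows) + 1L]] <- add(referenceGene, "treated", referenceCq)
    do.call(rbind, rows)
  })
}
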