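#' Construct segmentation parameters
#'
#' @param discSize disk size in px for the entropy neighborhood (>= 1).
#' @param threshold integer in \[0, 255\]; pixels whose rescaled entropy is
#'   strictly below it are wound candidates.
#' @param entropyScale rescaling mode, see [rescaleEntropy()].
#' @param minComponentFrac discard connected components smaller than this
#'   fraction of the frame area (default 0.005). All surviving components are
#'   kept, not only the largest: near closure a wound fragments, and keeping
#'   the largest only would bias late timepoints low.
#' @param cleanupRadius disk radius for morphological closing-then-opening of
#'   the candidate mask; `NA` (default) means `ceiling(radius / 4)`, tying the
#'   cleanup scale to the texture scale.
#' @param connectivity pixel connectivity for component labeling, 8 (default)
#'   or 4.
#' @param discIsDiameter if TRUE interpret `discSize` as a diameter
#'   (radius = `floor(discSize / 2)`). The default FALSE (radius) follows the
#'   dominant rank-filter footprint convention.
#' @return a [SegmentationParams-class].
#' @seealso [cellLinePreset()] for the published per-cell-line settings.
#' @export
segmentationParams <- function(discSize = 20L, threshold = 92L,
                               entropyScale = c("per_image_max", "fixed_8bit"),
                               minComponentFrac = 0.005,
                               cleanupRadius = NA_integer_,
                               connectivity = 8L,
                               discIsDiameter = FALSE) {
  new("SegmentationParams",
      discSize = as.integer(discSize),
      discIsDiameter = isTRUE(discIsDiameter),
      threshold = as.integer(threshold),
      entropyScale = match.arg(entropyScale),
      minComponentFrac = as.numeric(minComponentFrac),
      cleanupRadius = as.integer(cleanupRadius),
      connectivity = as.integer(connectivity))
}

#' Published per-cell-line segmentation presets
#'
#' Disc size and threshold pairs used for the two ovarian carcinoma lines the
#' method was calibrated on: TOV-21G (disc 20, threshold 92) and SK-OV-3
#' (disc 50, threshold 92). The two lines differ in morphology, hence the
#' different texture scale.
#'
#' @param cellLine "tov21g" or "skov3" (case-insensitive).
#' @param ... overrides passed on to [segmentationParams()].
#' @return a [SegmentationParams-class].
#' @examples
#' cellLinePreset("tov21g")
#' @export
cellLinePreset <- function(cellLine = c("tov21g", "skov3"), ...) {
  cellLine <- match.arg(tolower(cellLine), c("tov21g", "skov3"))
  preset <- switch(cellLine,
    tov21g = list(discSize = 20L, threshold = 92L),
    skov3  = list(discSize = 50L, threshold = 92L))
  args <- utils::modifyList(preset, list(...))
  do.call(segmentationParams, args)
}

# effective entropy radius in px implied by the disc-size interpretation
entropyRadius <- function(params) {
  if (params@discIsDiameter) max(1L, params@discSize %/% 2L) else params@discSize
}

# effective cleanup radius (NA slot -> ceiling(radius/4) default)
cleanupRadius <- function(params) {
  if (is.na(params@cleanupRadius)) as.integer(ceiling(entropyRadius(params) / 4))
  else params@cleanupRadius
}

# closing-then-opening with a disk; erosion treats out-of-frame as foreground
binaryClose <- function(mask, radius) {
  if (radius == 0L) return(mask)
  !cpp_dilate_disk(!cpp_dilate_disk(mask, radius), radius)
}
binaryOpen <- function(mask, radius) {
  if (radius == 0L) return(mask)
  cpp_dilate_disk(!cpp_dilate_disk(!mask, radius), radius)
}

#' Segment the wound region of a scratched-monolayer micrograph
#'
#' The pipeline: local entropy over a disk neighborhood -> 8-bit rescale ->
#' threshold (wound candidate = rescaled entropy strictly below `threshold`,
#' i.e. the texture-poor, cell-free side) -> morphological closing then
#' opening with a disk of the cleanup radius -> connected-component labeling
#' -> discard components smaller than `minComponentFrac` of the frame ->
#' wound mask = union of all surviving components. Deterministic.
#'
#' A constant image has zero entropy everywhere, rescales to zero, and is
#' therefore classified entirely as wound: the cell-free-field limit.
#'
#' @param img a [GrayImage-class].
#' @param params a [SegmentationParams-class]; defaults to the TOV-21G preset.
#' @return a [WoundMask-class].
#' @examples
#' sim <- simulateScratchImage(width = 240, height = 72, woundFrac = 0.3,
#'                             seed = 1)
#' m <- segmentWound(sim$image, segmentationParams(discSize = 8))
#' areaFraction(m)
#' @export
segmentWound <- function(img, params = cellLinePreset("tov21g")) {
  stopifnot(is(img, "GrayImage"), is(params, "SegmentationParams"))
  r <- entropyRadius(params)
  if (min(dim(img)) < 3L * params@discSize)
    warning(sprintf("image is %d x %d px, smaller than 3 x disc size (%d); %s",
                    nrow(img@pixels), ncol(img@pixels), 3L * params@discSize,
                    "segmentation proceeds but may be unreliable"))
  em <- localEntropy(img, r)
  resc <- rescaleEntropy(em, params@entropyScale)
  cand <- resc@pixels < params@threshold
  cleaned <- binaryOpen(binaryClose(cand, cleanupRadius(params)),
                        cleanupRadius(params))
  lab <- cpp_label_components(cleaned, params@connectivity)
  nlab <- max(lab)
  keep <- matrix(FALSE, nrow(lab), ncol(lab))
  kept <- 0L
  if (nlab > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = nlab)
    minPix <- params@minComponentFrac * length(lab)
    for (k in seq_len(nlab)) {
      if (sizes[k] >= minPix) {
        keep[lab == k] <- TRUE
        kept <- kept + 1L
      }
    }
  }
  new("WoundMask", pixels = keep, nComponentsKept = kept, overridden = FALSE)
}

#' Apply a supervisor-supplied region override to a wound mask
#'
#' Human supervision of the automatic segmentation: replace, intersect or
#' union the mask with a region of interest. The ROI is either a logical
#' raster of the same dimensions or a polygon (two-column matrix of (row,
#' column) vertices, rasterized by even-odd point-in-polygon). Area fields
#' are recomputed and the `overridden` flag is set.
#'
#' @param mask a [WoundMask-class].
#' @param roi logical matrix of mask dimensions, or a polygon vertex matrix
#'   with columns (row, col) within frame bounds.
#' @param mode "replace" (default), "intersect" or "union".
#' @return a [WoundMask-class] with `overridden = TRUE`.
#' @export
applyOverride <- function(mask, roi, mode = c("replace", "intersect", "union")) {
  stopifnot(is(mask, "WoundMask"))
  mode <- match.arg(mode)
  dims <- dim(mask@pixels)
  if (is.logical(roi) && is.matrix(roi)) {
    if (!identical(dim(roi), dims))
      stop("raster ROI dimensions ", paste(dim(roi), collapse = " x "),
           " do not match frame ", paste(dims, collapse = " x "))
    rast <- roi
  } else if (is.numeric(roi) && is.matrix(roi) && ncol(roi) == 2L) {
    if (nrow(roi) > 0L &&
        (min(roi) < 1 || max(roi[, 1L]) > dims[1L] || max(roi[, 2L]) > dims[2L]))
      stop("polygon ROI vertices fall outside the frame bounds")
    rast <- rasterizePolygon(roi, dims)
  } else {
    stop("roi must be a logical raster matrix or a 2-column vertex matrix")
  }
  px <- switch(mode,
    replace   = rast,
    intersect = mask@pixels & rast,
    union     = mask@pixels | rast)
  lab <- cpp_label_components(px, 8L)
  new("WoundMask", pixels = px, nComponentsKept = max(lab), overridden = TRUE)
}

# even-odd scanline rasterization of a closed polygon given as (row, col)
# vertices; returns a logical matrix of the requested dimensions
rasterizePolygon <- function(verts, dims) {
  out <- matrix(FALSE, dims[1L], dims[2L])
  n <- nrow(verts)
  if (n < 3L) return(out)
  yy <- verts[, 1L]; xx <- verts[, 2L]
  for (row in seq_len(dims[1L])) {
    yc <- row  # test at pixel centers
    cross <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      y1 <- yy[j]; y2 <- yy[i]; x1 <- xx[j]; x2 <- xx[i]
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        cross <- c(cross, x1 + (yc - y1) / (y2 - y1) * (x2 - x1))
      }
      j <- i
    }
    cross <- sort(cross)
    k <- 1L
    while (k < length(cross) + 1L && k + 1L <= length(cross)) {
      lo <- ceiling(cross[k]); hi <- floor(cross[k + 1L])
      if (hi >= lo) out[row, max(1L, lo):min(dims[2L], hi)] <- TRUE
      k <- k + 2L
    }
  }
  out
}
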