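#' @useDynLib WoundEntropy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' GrayImage: an 8-bit grayscale micrograph
#'
#' The canonical image representation for segmentation: a matrix of integer
#' intensities in \[0, 255\] (rows = image rows, columns = image columns) plus
#' a free-text provenance label.
#'
#' @slot pixels integer matrix of intensities in \[0, 255\].
#' @slot sourceId character scalar, provenance label (e.g. the file path).
#'
#' @seealso [grayImage()], [readGrayImage()], [localEntropy()]
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", sourceId = "character"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric/integer matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
    if (anyNA(p)) return("pixels contain NA")
    if (any(p != as.integer(p))) return("pixels must be integers")
    if (min(p) < 0 || max(p) > 255) return("pixels must lie in [0, 255]")
    if (length(object@sourceId) != 1L) return("sourceId must be a single string")
    TRUE
  })

#' EntropyMap: local Shannon entropy of an image
#'
#' A per-pixel map of the Shannon entropy (in bits) of the 256-bin intensity
#' histogram within a disk neighborhood, as produced by [localEntropy()].
#' Values lie in \[0, min(8, log2(number of disk offsets))\].
#'
#' @slot values numeric matrix of entropies in bits, same dimensions as the
#'   source image.
#' @slot radiusUsed integer, disk radius (px) the map was computed with.
#' @export
setClass("EntropyMap",
  representation(values = "matrix", radiusUsed = "integer"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (anyNA(v)) return("entropy values contain NA")
    if (min(v) < 0) return("entropy values must be non-negative")
    r <- object@radiusUsed
    if (length(r) != 1L || r < 1L) return("radiusUsed must be a positive integer")
    bound <- min(8, log2(nrow(diskOffsets(r)))) + 1e-9
    if (max(v) > bound) return(sprintf("entropy exceeds bound %.6f bits", bound))
    TRUE
  })

#' WoundMask: a segmented wound region
#'
#' Boolean mask (TRUE = wound / cell-free region) with its component count and
#' an `overridden` flag recording manual supervision. Area quantities are
#' exposed through [woundArea()] and [areaFraction()] and are recomputed from
#' the pixels, never stored stale.
#'
#' @slot pixels logical matrix, TRUE where the frame is wound.
#' @slot nComponentsKept integer, connected components retained.
#' @slot overridden logical, TRUE after [applyOverride()].
#' @export
setClass("WoundMask",
  representation(pixels = "matrix", nComponentsKept = "integer",
                 overridden = "logical"),
  validity = function(object) {
    p <- object@pixels
    if (!is.logical(p)) return("mask pixels must be logical")
    if (nrow(p) < 1L || ncol(p) < 1L) return("mask must be at least 1 x 1")
    if (anyNA(p)) return("mask contains NA")
    if (length(object@overridden) != 1L) return("overridden must be a flag")
    if (length(object@nComponentsKept) != 1L || object@nComponentsKept < 0L)
      return("nComponentsKept must be a non-negative count")
    TRUE
  })

#' SegmentationParams: tunable parameters of wound segmentation
#'
#' Bundles the entropy-segmentation tuning: disk size, the 8-bit threshold
#' applied to the rescaled entropy map, the rescaling mode, morphological
#' cleanup radius, minimum component size and pixel connectivity. Cell-line
#' presets are available through [cellLinePreset()].
#'
#' @slot discSize integer, disk size (px) for the entropy neighborhood.
#' @slot discIsDiameter logical; if TRUE `discSize` is interpreted as a
#'   diameter (radius = floor(discSize / 2)), otherwise as the radius.
#' @slot threshold integer in \[0, 255\]; rescaled entropies strictly below it
#'   are wound candidates.
#' @slot entropyScale "per_image_max" or "fixed_8bit" (see [rescaleEntropy()]).
#' @slot minComponentFrac numeric in \[0, 1): components smaller than this
#'   fraction of the frame are discarded.
#' @slot cleanupRadius integer, disk radius for morphological closing/opening;
#'   `NA` means the default `ceiling(radius / 4)`.
#' @slot connectivity integer, 4 or 8.
#' @export
setClass("SegmentationParams",
  representation(discSize = "integer", discIsDiameter = "logical",
                 threshold = "integer", entropyScale = "character",
                 minComponentFrac = "numeric", cleanupRadius = "integer",
                 connectivity = "integer"),
  validity = function(object) {
    if (object@discSize < 1L) return("discSize must be >= 1")
    if (object@threshold < 0L || object@threshold > 255L)
      return("threshold must lie in [0, 255]")
    if (!object@entropyScale %in% c("per_image_max", "fixed_8bit"))
      return("entropyScale must be 'per_image_max' or 'fixed_8bit'")
    if (object@minComponentFrac < 0 || object@minComponentFrac >= 1)
      return("minComponentFrac must lie in [0, 1)")
    if (!is.na(object@cleanupRadius) && object@cleanupRadius < 0L)
      return("cleanupRadius must be >= 0")
    if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
    TRUE
  })

#' ScratchSeries: a wound time course for one well
#'
#' Ordered timepoints (hours, strictly increasing) with one [WoundMask-class]
#' per timepoint; all masks must share frame dimensions. T0 is the first
#' (minimum-time) entry.
#'
#' @slot wellId character label.
#' @slot times numeric vector of hours, strictly increasing.
#' @slot masks list of [WoundMask-class] objects, one per time.
#' @export
setClass("ScratchSeries",
  representation(wellId = "character", times = "numeric", masks = "list"),
  validity = function(object) {
    if (length(object@times) < 1L) return("series needs at least one timepoint")
    if (length(object@times) != length(object@masks))
      return("times and masks differ in length")
    if (is.unsorted(object@times, strictly = TRUE))
      return("times must be strictly increasing")
    if (!all(vapply(object@masks, is, logical(1), class2 = "WoundMask")))
      return("masks must all be WoundMask objects")
    dims <- vapply(object@masks, function(m) dim(m@pixels), integer(2))
    if (length(object@masks) > 1L && any(dims != dims[, 1]))
      return("all masks must share identical frame dimensions")
    TRUE
  })

#' ClosureResult: wound closure relative to T0
#'
#' Per-timepoint percentage of the initial (T0) wound still open,
#' `openPct(t) = 100 * area(t) / area(T0)`, its complement `closurePct`, and
#' per-timepoint flags ("EXPANDED" when the wound grew beyond its T0 area).
#'
#' @slot wellId character label.
#' @slot times numeric vector of hours.
#' @slot openPct numeric vector, % of the T0 wound area (100 at T0, uncapped).
#' @slot closurePct numeric vector, `100 - openPct`.
#' @slot flags character vector, "" or comma-separated flags per timepoint.
#' @export
setClass("ClosureResult",
  representation(wellId = "character", times = "numeric", openPct = "numeric",
                 closurePct = "numeric", flags = "character"),
  validity = function(object) {
    n <- length(object@times)
    if (length(object@openPct) != n || length(object@closurePct) != n ||
        length(object@flags) != n)
      return("times, openPct, closurePct and flags must have equal length")
    if (abs(object@openPct[1L] - 100) > 1e-12)
      return("openPct at T0 must equal 100 exactly")
    if (max(abs(object@openPct + object@closurePct - 100)) > 1e-9)
      return("openPct + closurePct must equal 100")
    TRUE
  })
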