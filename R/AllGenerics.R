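#' Pixel data of an image-like object
#'
#' @param x a [GrayImage-class], [EntropyMap-class] or [WoundMask-class].
#' @return the underlying matrix (integer intensities, entropies in bits, or
#'   a logical wound mask respectively).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Wound area in pixels
#' @param x a [WoundMask-class].
#' @return integer count of TRUE (wound) pixels.
#' @export
setGeneric("woundArea", function(x) standardGeneric("woundArea"))

#' Wound area as a fraction of the frame
#' @param x a [WoundMask-class].
#' @return numeric in \[0, 1\].
#' @export
setGeneric("areaFraction", function(x) standardGeneric("areaFraction"))

#' @export
#' @rdname pixels
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @export
#' @rdname pixels
setMethod("pixels", "EntropyMap", function(x) x@values)

#' @export
#' @rdname pixels
setMethod("pixels", "WoundMask", function(x) x@pixels)

#' @export
#' @rdname woundArea
setMethod("woundArea", "WoundMask", function(x) sum(x@pixels))

#' @export
#' @rdname areaFraction
setMethod("areaFraction", "WoundMask", function(x) sum(x@pixels) / length(x@pixels))

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @export
setMethod("dim", "EntropyMap", function(x) dim(x@values))

#' @export
setMethod("dim", "WoundMask", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d px, intensities [%d, %d], source '%s'\n",
              nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels), object@sourceId))
})

setMethod("show", "EntropyMap", function(object) {
  cat(sprintf("EntropyMap %d x %d px, radius %d, range [%.3f, %.3f] bits\n",
              nrow(object@values), ncol(object@values), object@radiusUsed,
              min(object@values), max(object@values)))
})

setMethod("show", "WoundMask", function(object) {
  cat(sprintf(
    "WoundMask %d x %d px: area %d px (%.3f of frame), %d component(s)%s\n",
    nrow(object@pixels), ncol(object@pixels), woundArea(object),
    areaFraction(object), object@nComponentsKept,
    if (object@overridden) ", manually overridden" else ""))
})

setMethod("show", "SegmentationParams", function(object) {
  r <- entropyRadius(object)
  cat(sprintf(paste0(
    "SegmentationParams: disc %d (as %s; entropy radius %d px), threshold %d,\n",
    "  scale %s, min component %.4f of frame, cleanup radius %d, %d-connectivity\n"),
    object@discSize, if (object@discIsDiameter) "diameter" else "radius", r,
    object@threshold, object@entropyScale, object@minComponentFrac,
    cleanupRadius(object), object@connectivity))
})

setMethod("show", "ScratchSeries", function(object) {
  cat(sprintf("ScratchSeries '%s': %d timepoint(s) at %s h, frame %d x %d px\n",
              object@wellId, length(object@times),
              paste(object@times, collapse = ", "),
              nrow(object@masks[[1L]]@pixels), ncol(object@masks[[1L]]@pixels)))
})

setMethod("show", "ClosureResult", function(object) {
  cat(sprintf("ClosureResult '%s' (%% of T0 wound still open):\n", object@wellId))
  print(as.data.frame(object))
})

#' @export
as.data.frame.ClosureResult <- function(x, ...) {
  data.frame(well_id = x@wellId, time_h = x@times, open_pct = x@openPct,
             closure_pct = x@closurePct, flags = x@flags,
             stringsAsFactors = FALSE)
}
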