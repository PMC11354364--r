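#' Construct a GrayImage from a matrix
#'
#' @param pixels numeric or integer matrix with values in \[0, 255\].
#' @param sourceId provenance label stored with the image.
#' @return a [GrayImage-class].
#' @examples
#' img <- grayImage(matrix(0:255, 16, 16))
#' dim(img)
#' @export
grayImage <- function(pixels, sourceId = "in-memory") {
  storage.mode(pixels) <- "integer"
  new("GrayImage", pixels = pixels, sourceId = as.character(sourceId))
}

#' Lattice offsets of a disk neighborhood
#'
#' All integer offsets (dy, dx) with dy^2 + dx^2 <= radius^2 — the footprint
#' over which local entropy is computed. The set always contains (0, 0) and is
#' centrosymmetric.
#'
#' @param radius integer disk radius in px, >= 1.
#' @return a two-column integer matrix of (dy, dx) offsets.
#' @examples
#' nrow(diskOffsets(1))  # 5
#' @export
diskOffsets <- function(radius) {
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 1L)
    stop("radius must be a single integer >= 1")
  d <- seq.int(-radius, radius)
  g <- expand.grid(dy = d, dx = d)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, ]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("dy", "dx"))
  m
}

#' Local Shannon entropy over a disk neighborhood
#'
#' For every pixel, the Shannon entropy (bits) of the 256-bin histogram of the
#' 8-bit intensities inside the disk of the given radius centered on that
#' pixel. Positions falling outside the frame are filled by reflect padding
#' (edge row/column mirrored), which avoids the spurious low-entropy rim a
#' zero-padded border would create and that would be misread as wound.
#'
#' A texture-rich cell monolayer scores high (up to min(8, log2(disk size))
#' bits); a flat cell-free wound scores near zero, which is what makes the
#' entropy map separable by a single threshold.
#'
#' @param img a [GrayImage-class].
#' @param radius disk radius in px (>= 1).
#' @return an [EntropyMap-class] of the same dimensions.
#' @examples
#' img <- grayImage(matrix(sample(0:255, 400, TRUE), 20, 20))
#' em <- localEntropy(img, radius = 2)
#' range(pixels(em))
#' @export
localEntropy <- function(img, radius) {
  stopifnot(is(img, "GrayImage"))
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 1L)
    stop("radius must be a single integer >= 1")
  v <- cpp_local_entropy(img@pixels, radius)
  new("EntropyMap", values = v, radiusUsed = radius)
}

#' Rescale an entropy map to an 8-bit image
#'
#' Makes an integer threshold in \[0, 255\] applicable to the (real-valued,
#' bits-scaled) entropy map. Two modes:
#' \describe{
#'   \item{per_image_max}{`v -> round(255 * v / max(map))`; an all-zero map
#'     yields an all-zero image. The default: it adapts the threshold to each
#'     image's entropy range.}
#'   \item{fixed_8bit}{`v -> round(255 * v / 8)`, clipped to \[0, 255\];
#'     comparable across images since 8 bits is the ceiling for 8-bit data.}
#' }
#'
#' @param map an [EntropyMap-class].
#' @param mode "per_image_max" (default) or "fixed_8bit".
#' @return a [GrayImage-class] of rescaled entropies.
#' @export
rescaleEntropy <- function(map, mode = c("per_image_max", "fixed_8bit")) {
  stopifnot(is(map, "EntropyMap"))
  mode <- match.arg(mode)
  v <- map@values
  if (mode == "per_image_max") {
    mx <- max(v)
    out <- if (mx == 0) array(0L, dim(v)) else as.integer(round(255 * v / mx))
  } else {
    out <- as.integer(pmin(255, pmax(0, round(255 * v / 8))))
  }
  grayImage(matrix(out, nrow(v), ncol(v)),
            sourceId = sprintf("entropy[%s]", mode))
}
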