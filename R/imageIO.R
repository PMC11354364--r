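#' Read a micrograph into a canonical 8-bit GrayImage
#'
#' Reads a PNG or TIFF raster, collapses RGB to luminance (integer-rounded
#' Rec.601: `round(0.299 R + 0.587 G + 0.114 B)` on the native integer
#' values), and maps 16-bit data to \[0, 255\]:
#' \describe{
#'   \item{minmax}{linear stretch, minimum -> 0 and maximum -> 255. A
#'     zero-dynamic-range image maps to all zeros with a warning (microscope
#'     exports rarely fill the 16-bit range, so this is the default).}
#'   \item{fixed_shift}{`value %/% 256` (a right shift by 8 bits), comparable
#'     across images.}
#' }
#' 8-bit input passes through unchanged.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param bitPolicy 16-bit conversion policy, "minmax" (default) or
#'   "fixed_shift".
#' @return a [GrayImage-class] with `sourceId = path`.
#' @seealso [writeMask()], [writeReport()]
#' @export
readGrayImage <- function(path, bitPolicy = c("minmax", "fixed_shift")) {
  bitPolicy <- match.arg(bitPolicy)
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    scale <- 2^depth - 1
    vals <- round(raw * scale)  # readPNG returns [0,1] doubles
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- attr(raw, "bits.per.sample")
    if (is.null(depth)) depth <- if (max(raw) > 255) 16L else 8L
    vals <- raw
  } else {
    stop("unsupported image format '", ext, "' for '", path,
         "' (PNG and TIFF are supported)")
  }
  # collapse RGB(A) to luminance on native integer values
  if (length(dim(vals)) == 3L) {
    if (dim(vals)[3L] >= 3L) {
      vals <- round(0.299 * vals[, , 1L] + 0.587 * vals[, , 2L] +
                    0.114 * vals[, , 3L])
    } else {
      vals <- vals[, , 1L]
    }
  }
  vals <- matrix(as.numeric(vals), nrow = nrow(vals), ncol = ncol(vals))
  if (depth > 8L) {
    if (bitPolicy == "minmax") {
      lo <- min(vals); hi <- max(vals)
      if (hi == lo) {
        warning("zero dynamic range in 16-bit image '", path,
                "'; all pixels map to 0 under minmax")
        vals[] <- 0
      } else {
        vals <- round(255 * (vals - lo) / (hi - lo))
      }
    } else {
      vals <- vals %/% 256
    }
  }
  grayImage(vals, sourceId = path)
}

#' Write a wound mask as a lossless binary PNG
#'
#' Wound pixels are written as 255, monolayer as 0, single channel, 8-bit.
#' The round trip through [readMask()] reproduces the mask exactly.
#'
#' @param mask a [WoundMask-class].
#' @param path output path (`.png`).
#' @return invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "WoundMask"))
  ok <- try(png::writePNG(ifelse(mask@pixels, 1, 0), path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write mask to '", path, "'")
  invisible(path)
}

#' Read a binary mask PNG back into a WoundMask
#'
#' @param path path to a mask written by [writeMask()] (any pixel > 127 is
#'   treated as wound).
#' @return a [WoundMask-class] (components are not re-derived;
#'   `nComponentsKept` is set to `NA_integer_`-free 1 if any wound pixel
#'   exists, else 0).
#' @export
readMask <- function(path) {
  img <- readGrayImage(path)
  px <- img@pixels > 127L
  new("WoundMask", pixels = px,
      nComponentsKept = if (any(px)) 1L else 0L, overridden = FALSE)
}

#' Write labeled measurement records as CSV
#'
#' All rows must share one schema (identical field names). Numeric fields are
#' serialized at full precision (>= 6 significant digits), '.' decimal
#' separator, UTF-8, with a header row.
#'
#' @param rows a data.frame, or a list of named lists/vectors sharing one
#'   schema. An empty list (or 0-row data.frame) yields a header-only file;
#'   for an empty list the header comes from `schema`.
#' @param path output CSV path.
#' @param schema character vector of field names, used only when `rows` is an
#'   empty list.
#' @return invisibly, `path`.
#' @export
writeReport <- function(rows, path, schema = character(0)) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (is.list(rows)) {
    if (length(rows) == 0L) {
      df <- as.data.frame(stats::setNames(
        replicate(length(schema), character(0), simplify = FALSE), schema))
      utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
      return(invisible(path))
    }
    schemas <- lapply(rows, names)
    ref <- schemas[[1L]]
    bad <- which(!vapply(schemas, identical, logical(1), y = ref))
    if (length(bad))
      stop("inconsistent report schemas at row(s) ", paste(bad, collapse = ", "),
           ": expected fields {", paste(ref, collapse = ", "), "}, got {",
           paste(unique(unlist(schemas[bad])), collapse = ", "), "}")
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(as.list(r), stringsAsFactors = FALSE)))
  } else {
    stop("rows must be a data.frame or a list of named records")
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
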