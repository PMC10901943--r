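#' RGB tile objects
#'
#' An `rgb_tile` is the atomic unit of all processing in stainshift: an
#' 8-bit RGB raster stored as an `H x W x 3` numeric array of integer
#' intensities in `[0, 255]`, with a `microns_per_pixel` attribute carrying
#' the physical resolution (histology tiles are commonly sampled at
#' 1 micron per pixel).
#'
#' @param pixels `H x W x 3` array of intensities in `[0, 255]`.
#' @param microns_per_pixel Positive physical pixel size in microns.
#'
#' @return An object of class `rgb_tile`.
#' @examples
#' t <- rgb_tile(array(200, dim = c(4, 4, 3)))
#' dim(t)
#' @export
rgb_tile <- function(pixels, microns_per_pixel = 1.0) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array (RGB).", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("tile must have H >= 1 and W >= 1.", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("tile intensities must lie in [0, 255].", call. = FALSE)
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a positive scalar.", call. = FALSE)
  }
  structure(round(pixels), microns_per_pixel = microns_per_pixel,
            class = "rgb_tile")
}

#' @export
print.rgb_tile <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_tile %d x %d px, %.3g um/px, mean intensity %.1f>\n",
              d[1], d[2], attr(x, "microns_per_pixel"), mean(x)))
  invisible(x)
}

is_rgb_tile <- function(x) inherits(x, "rgb_tile")

assert_tile <- function(x, arg = "tile") {
  if (!is_rgb_tile(x)) {
    if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) {
      return(rgb_tile(x))
    }
    stop(sprintf("`%s` must be an rgb_tile or an H x W x 3 array.", arg),
         call. = FALSE)
  }
  x
}

#' Convert an RGB tile to optical density (Beer-Lambert)
#'
#' Transmitted-light microscopy obeys the Beer-Lambert law: stain
#' concentrations combine linearly in optical-density (OD) space, not in
#' RGB space, so OD conversion is the first step of every stain-separation
#' method. Each channel is mapped as `OD = log10(I0 / max(I, 1))`, where
#' `I0` is the per-channel background (blank glass) intensity; intensities
#' are clamped at 1 to keep the OD finite.
#'
#' @param tile An [rgb_tile()].
#' @param background Per-channel background intensities `I0`, each in
#'   `[1, 255]`. Default assumes saturated white glass.
#'
#' @return An `od_image`: an `H x W x 3` nonnegative array with a
#'   `background` attribute.
#' @seealso [od_to_rgb()] for the inverse.
#' @examples
#' t <- rgb_tile(array(128, dim = c(2, 2, 3)))
#' od <- rgb_to_od(t)
#' range(od)
#' @export
rgb_to_od <- function(tile, background = c(255, 255, 255)) {
  tile <- assert_tile(tile)
  if (length(background) != 3L || any(background < 1) || any(background > 255)) {
    stop("`background` must be 3 intensities in [1, 255].", call. = FALSE)
  }
  d <- dim(tile)
  bg <- array(rep(background, each = d[1] * d[2]), dim = d)
  od <- log10(bg / pmax(unclass(tile), 1))
  od[od < 0] <- 0  # pixels brighter than background carry no stain
  structure(od, background = background, class = "od_image")
}

#' Convert an optical-density image back to RGB
#'
#' Inverts [rgb_to_od()]: `I = round(I0 * 10^(-OD))`, clipped to
#' `[0, 255]`. Together the pair round-trips any tile to within one
#' intensity level (for pixels >= 1, which the OD clamp maps exactly).
#'
#' @param od An `od_image`, or a nonnegative `H x W x 3` array.
#' @param background Per-channel `I0`; defaults to the `background`
#'   attribute of `od` when present.
#' @param microns_per_pixel Pixel size to attach to the output tile.
#'
#' @return An [rgb_tile()].
#' @export
od_to_rgb <- function(od, background = NULL, microns_per_pixel = 1.0) {
  if (is.null(background)) background <- attr(od, "background")
  if (is.null(background)) background <- c(255, 255, 255)
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L) {
    stop("`od` must be an H x W x 3 array.", call. = FALSE)
  }
  if (anyNA(od) || any(!is.finite(od)) || min(od) < 0) {
    stop("optical densities must be finite and nonnegative.", call. = FALSE)
  }
  d <- dim(od)
  bg <- array(rep(background, each = d[1] * d[2]), dim = d)
  px <- round(bg * 10^(-unclass(od)))
  px[px < 0] <- 0
  px[px > 255] <- 255
  rgb_tile(px, microns_per_pixel = microns_per_pixel)
}

#' Read and write 8-bit RGB tiles
#'
#' Thin wrappers over the png/tiff codecs that return/accept [rgb_tile()]
#' objects. Grayscale or RGBA rasters are promoted/truncated to RGB.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param microns_per_pixel Resolution metadata to attach on read.
#' @return `read_tile()` returns an [rgb_tile()]; `write_tile()` returns
#'   `path` invisibly.
#' @export
read_tile <- function(path, microns_per_pixel = 1.0) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported tile format '.%s' (use png or tiff).", ext),
         call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  rgb_tile(round(raw * 255), microns_per_pixel = microns_per_pixel)
}

#' @rdname read_tile
#' @param tile An [rgb_tile()] to write.
#' @export
write_tile <- function(tile, path) {
  tile <- assert_tile(tile)
  img <- unclass(tile) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop(sprintf("unsupported tile format '.%s' (use png or tiff).", ext),
         call. = FALSE)
  )
  invisible(path)
}
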