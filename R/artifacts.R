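#' Artifact specifications
#'
#' Scanner/processing artifacts are described by a family and a single
#' strength with a family-specific meaning: `blur` is a Gaussian sigma in
#' pixels (an out-of-focus scanner), `jpeg` is a codec quality in
#' `[1, 100]` (slide compression), `brightness` is an additive intensity
#' offset, and `contrast` a multiplicative factor about mid-gray 128
#' (slide/scanner illumination differences).
#'
#' @param family One of `"blur"`, `"jpeg"`, `"brightness"`, `"contrast"`.
#' @param strength Family-specific strength (see above).
#'
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(family, strength) {
  families <- c("blur", "jpeg", "brightness", "contrast")
  if (!is.character(family) || length(family) != 1L ||
      !family %in% families) {
    stop(sprintf("unknown artifact family '%s' (use %s).",
                 paste(family, collapse = ","),
                 paste(families, collapse = ", ")), call. = FALSE)
  }
  stopifnot(is.numeric(strength), length(strength) == 1L,
            is.finite(strength))
  switch(family,
    blur = if (strength < 0)
      stop("blur sigma must be >= 0.", call. = FALSE),
    jpeg = if (strength != round(strength) || strength < 1 || strength > 100)
      stop("jpeg quality must be an integer in [1, 100].", call. = FALSE),
    contrast = if (strength <= 0)
      stop("contrast factor must be > 0.", call. = FALSE),
    brightness = invisible(NULL)
  )
  structure(list(family = family, strength = strength),
            class = "artifact_spec")
}

#' @export
print.artifact_spec <- function(x, ...) {
  cat(sprintf("<artifact_spec %s, strength %g>\n", x$family, x$strength))
  invisible(x)
}

#' Apply an artifact to a tile
#'
#' Dispatches on the spec's family: Gaussian blur (kernel radius
#' `ceiling(3 sigma)`, reflective borders), JPEG encode/decode at the
#' given quality, additive brightness with clipping, or linear contrast
#' about mid-gray with clipping. Every family is the identity at its
#' neutral strength (sigma 0, offset 0, factor 1; quality 100 up to codec
#' tolerance), and the output is deterministic for a given tile and spec.
#'
#' @param tile An [rgb_tile()].
#' @param spec An [artifact_spec()].
#'
#' @return An [rgb_tile()] of the same dimensions.
#' @examples
#' t <- generate_tile(0, default_domain_styles()$A, seed = 1)
#' blurred <- apply_artifact(t, artifact_spec("blur", 2))
#' @export
apply_artifact <- function(tile, spec) {
  tile <- assert_tile(tile)
  if (!inherits(spec, "artifact_spec")) {
    stop("`spec` must be an artifact_spec.", call. = FALSE)
  }
  switch(spec$family,
    blur = gaussian_blur_tile(tile, spec$strength),
    jpeg = jpeg_roundtrip_tile(tile, spec$strength),
    brightness = {
      px <- pmin(pmax(unclass(tile) + spec$strength, 0), 255)
      rgb_tile(px, microns_per_pixel = attr(tile, "microns_per_pixel"))
    },
    contrast = {
      px <- round(spec$strength * (unclass(tile) - 128) + 128)
      px <- pmin(pmax(px, 0), 255)
      rgb_tile(px, microns_per_pixel = attr(tile, "microns_per_pixel"))
    }
  )
}

# Separable Gaussian convolution with reflective borders; sigma = 0 is an
# exact identity.
gaussian_blur_tile <- function(tile, sigma) {
  if (sigma == 0) return(tile)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  px <- unclass(tile)
  d <- dim(px)
  out <- px
  for (ch in 1:3) {
    out[, , ch] <- conv_sep(px[, , ch], k, r)
  }
  rgb_tile(pmin(pmax(round(out), 0), 255),
           microns_per_pixel = attr(tile, "microns_per_pixel"))
}

conv_sep <- function(m, k, r) {
  m <- conv_cols(m, k, r)        # along rows (vertical)
  t(conv_cols(t(m), k, r))       # along columns (horizontal)
}

# Convolve each column of m with kernel k, reflecting at the borders.
conv_cols <- function(m, k, r) {
  n <- nrow(m)
  idx <- reflect_index(seq_len(n + 2L * r) - r, n)
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# Reflect out-of-range indices into [1, n] (mirror without repeating the
# edge sample's neighbor order: 0 -> 1, -1 -> 2, n+1 -> n, ...).
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  pmin(pmax(i, 1L), n)
}

jpeg_roundtrip_tile <- function(tile, quality) {
  img <- unclass(tile) / 255
  # libjpeg emits an informational caution about coarse quantization
  # tables at very low quality; that is the intended regime here
  raw <- withCallingHandlers(
    jpeg::writeJPEG(img, raw(), quality = quality / 100),
    warning = function(w) {
      if (grepl("quantization tables", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  back <- jpeg::readJPEG(raw)
  if (length(dim(back)) == 2L) back <- array(back, dim = c(dim(back), 3L))
  rgb_tile(round(back * 255),
           microns_per_pixel = attr(tile, "microns_per_pixel"))
}

#' PSNR of a JPEG compress/decompress round trip
#'
#' Peak signal-to-noise ratio between a tile and its JPEG round trip at
#' the given quality: `10 log10(255^2 / MSE)` in dB. Distortion grows as
#' quality drops, so PSNR is (non-strictly) decreasing along a quality
#' sweep. A distortion-free round trip (e.g. a constant-color tile) has
#' infinite PSNR and is reported as the capped sentinel `psnr_cap`.
#'
#' @param tile An [rgb_tile()].
#' @param quality Integer JPEG quality in `[1, 100]`.
#' @param psnr_cap Sentinel (dB) reported when the round trip is
#'   lossless (default 100).
#'
#' @return PSNR in dB.
#' @export
jpeg_roundtrip_distortion <- function(tile, quality, psnr_cap = 100) {
  tile <- assert_tile(tile)
  spec <- artifact_spec("jpeg", quality)
  back <- apply_artifact(tile, spec)
  mse <- mean((unclass(tile) - unclass(back))^2)
  if (mse == 0) return(psnr_cap)
  min(10 * log10(255^2 / mse), psnr_cap)
}

#' Build an ordered strength sweep for one artifact family
#'
#' @param family Artifact family (see [artifact_spec()]).
#' @param strengths Nonempty vector of strengths, validated per family.
#'
#' @return A list of [artifact_spec()]s, one per strength, in order.
#' @examples
#' artifact_sweep("blur", c(0, 1, 2, 4))
#' @export
artifact_sweep <- function(family, strengths) {
  if (length(strengths) == 0) {
    stop("`strengths` must be nonempty.", call. = FALSE)
  }
  purrr::map(strengths, function(s) artifact_spec(family, s))
}
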