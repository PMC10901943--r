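#' Domain styles: the colorimetric identity of a virtual institute
#'
#' A `domain_style` captures everything that differs between virtual
#' scanning sites in the synthetic generator: the stain matrix used to
#' render concentrations, the background glass intensity, and a global
#' brightness offset, contrast factor and pixel noise. Class signal never
#' enters a style — domains differ only in color, which is exactly the
#' kind of inter-institute shift stain normalization is meant to remove.
#'
#' @param stain_matrix `3 x 2` nonnegative matrix (columns normalized to
#'   unit length): hematoxylin-like and eosin-like absorption vectors.
#' @param background Per-channel background intensity, each in
#'   `[200, 255]`.
#' @param brightness_offset Additive intensity offset applied after
#'   rendering.
#' @param contrast_factor Multiplicative contrast about mid-gray 128.
#' @param pixel_noise_sd Standard deviation of additive Gaussian pixel
#'   noise (intensity levels).
#'
#' @return An object of class `domain_style`.
#' @export
domain_style <- function(stain_matrix,
                         background = c(252, 252, 252),
                         brightness_offset = 0,
                         contrast_factor = 1,
                         pixel_noise_sd = 2) {
  stain_matrix <- as.matrix(stain_matrix)
  stopifnot(all(dim(stain_matrix) == c(3L, 2L)), min(stain_matrix) >= 0,
            length(background) == 3L, all(background >= 200),
            all(background <= 255), contrast_factor > 0, pixel_noise_sd >= 0)
  stain_matrix <- sweep(stain_matrix, 2, sqrt(colSums(stain_matrix^2)), "/")
  structure(list(stain_matrix = stain_matrix,
                 background = as.numeric(background),
                 brightness_offset = brightness_offset,
                 contrast_factor = contrast_factor,
                 pixel_noise_sd = pixel_noise_sd),
            class = "domain_style")
}

#' Class morphologies: the structural identity of a tile class
#'
#' Class signal in the generator is purely morphological: dark
#' hematoxylin-rich nuclei are placed as random disks at a class-specific
#' density and radius over a smooth eosin background texture. Two classes
#' that differ in `nucleus_density` are separable by structure alone, in
#' any color scheme.
#'
#' @param nucleus_density Expected nuclei per 100 x 100 px area.
#' @param nucleus_radius_range Length-2 positive range of disk radii (px).
#' @param eosin_texture_scale Amplitude of the smooth eosin background
#'   concentration field.
#'
#' @return An object of class `class_morphology`.
#' @export
class_morphology <- function(nucleus_density,
                             nucleus_radius_range = c(3, 6),
                             eosin_texture_scale = 0.35) {
  stopifnot(nucleus_density >= 0, length(nucleus_radius_range) == 2L,
            all(nucleus_radius_range > 0),
            nucleus_radius_range[1] <= nucleus_radius_range[2],
            eosin_texture_scale >= 0)
  structure(list(nucleus_density = nucleus_density,
                 nucleus_radius_range = as.numeric(nucleus_radius_range),
                 eosin_texture_scale = eosin_texture_scale),
            class = "class_morphology")
}

#' Default two-domain, two-class study conditions
#'
#' `default_domain_styles()` returns two virtual institutes: domain `A`
#' renders with the classic H&E absorption vectors
#' `h = (0.65, 0.70, 0.29)`, `e = (0.07, 0.99, 0.11)` (normalized);
#' domain `B` rotates both stain vectors by 15 degrees about the gray
#' diagonal in RGB-OD space (then re-projects to the nonnegative unit
#' sphere) and adds brightness +10 and contrast 1.1 — a shift large
#' enough to open a measurable transfer gap for a color-sensitive
#' classifier, small enough that normalization to a shared reference
#' closes it. `default_class_morphologies()` returns the two classes,
#' separated by nucleus density alone (6 vs 22 nuclei per 100 x 100 px:
#' sparse normal-like cellularity against dense tumor-like cellularity,
#' far enough apart that Poisson tile-to-tile variation and the patient
#' effect leave the classes separable within one domain).
#'
#' @return A named list of [domain_style()]s / [class_morphology()]s.
#' @export
default_domain_styles <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  W_a <- cbind(h / sqrt(sum(h^2)), e / sqrt(sum(e^2)))
  R <- rotation_about_axis(c(1, 1, 1) / sqrt(3), 15 * pi / 180)
  W_b <- pmax(R %*% W_a, 0)
  W_b <- sweep(W_b, 2, sqrt(colSums(W_b^2)), "/")
  list(
    A = domain_style(W_a),
    B = domain_style(W_b, brightness_offset = 10, contrast_factor = 1.1)
  )
}

#' @rdname default_domain_styles
#' @export
default_class_morphologies <- function() {
  list(
    `0` = class_morphology(nucleus_density = 6),
    `1` = class_morphology(nucleus_density = 22)
  )
}

# Rodrigues rotation matrix about a unit axis.
rotation_about_axis <- function(axis, theta) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), nrow = 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate one synthetic H&E-like tile
#'
#' Renders a two-stain tile: random hematoxylin disks ("nuclei") at the
#' class's density and radius, a smooth eosin background field, Beer-
#' Lambert rendering through the style's stain matrix, then the style's
#' contrast, brightness and Gaussian pixel noise. Fully deterministic
#' given `seed`.
#'
#' @param label Class label, 0 or 1.
#' @param style A [domain_style()].
#' @param morph_by_class Named list (`"0"`, `"1"`) of
#'   [class_morphology()]s; classes must differ or a warning is issued
#'   (the task would be unlearnable).
#' @param size Tile side length in pixels (default 96 for desk-scale
#'   runs; use 299 to mirror full-resolution histology tiles).
#' @param seed Optional integer seed (RNG-state preserving). `NULL` uses
#'   the current RNG stream.
#' @param microns_per_pixel Resolution metadata.
#'
#' @return An [rgb_tile()].
#' @examples
#' tile <- generate_tile(1, default_domain_styles()$A, seed = 1)
#' tile
#' @export
generate_tile <- function(label, style,
                          morph_by_class = default_class_morphologies(),
                          size = 96, seed = NULL, microns_per_pixel = 1.0) {
  stopifnot(label %in% c(0, 1), inherits(style, "domain_style"), size >= 8)
  if (identical(morph_by_class[["0"]], morph_by_class[["1"]])) {
    warning("class morphologies are identical: classes are unlearnable.",
            call. = FALSE)
  }
  morph <- morph_by_class[[as.character(label)]]
  gen <- function() render_tile(style, morph, size, microns_per_pixel)
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

render_tile <- function(style, morph, size, microns_per_pixel) {
  # hematoxylin concentration: random nucleus disks
  cH <- matrix(0, size, size)
  n_disks <- stats::rpois(1, morph$nucleus_density * size^2 / 1e4)
  if (n_disks > 0) {
    cx <- stats::runif(n_disks, 1, size)
    cy <- stats::runif(n_disks, 1, size)
    rr <- stats::runif(n_disks, morph$nucleus_radius_range[1],
                       morph$nucleus_radius_range[2])
    amp <- stats::runif(n_disks, 0.7, 1.1)
    for (k in seq_len(n_disks)) {
      i0 <- max(1, floor(cy[k] - rr[k])); i1 <- min(size, ceiling(cy[k] + rr[k]))
      j0 <- max(1, floor(cx[k] - rr[k])); j1 <- min(size, ceiling(cx[k] + rr[k]))
      ii <- i0:i1; jj <- j0:j1
      dst2 <- outer((ii - cy[k])^2, (jj - cx[k])^2, "+")
      patch <- amp[k] * (dst2 <= rr[k]^2)
      cH[ii, jj] <- pmax(cH[ii, jj], patch)
    }
  }
  # eosin concentration: smooth low-frequency field + base level
  grid_n <- 6L
  coarse <- matrix(stats::runif(grid_n^2), grid_n, grid_n)
  cE <- 0.25 + morph$eosin_texture_scale * bilinear_upsample(coarse, size)
  # nuclei displace cytoplasm: damp eosin inside disks
  cE <- cE * (1 - 0.5 * (cH > 0))

  W <- style$stain_matrix
  Cm <- rbind(as.vector(cH), as.vector(cE))
  od <- array(t(W %*% Cm), dim = c(size, size, 3L))
  px <- unclass(od_to_rgb(od, background = style$background,
                          microns_per_pixel = microns_per_pixel))
  px <- style$contrast_factor * (px - 128) + 128 + style$brightness_offset
  if (style$pixel_noise_sd > 0) {
    px <- px + stats::rnorm(length(px), 0, style$pixel_noise_sd)
  }
  px <- round(pmin(pmax(px, 0), 255))
  rgb_tile(px, microns_per_pixel = microns_per_pixel)
}

# Bilinear upsampling of a small square matrix to size x size.
bilinear_upsample <- function(m, size) {
  n <- nrow(m)
  pos <- seq(1, n, length.out = size)
  i0 <- pmin(floor(pos), n - 1L); fi <- pos - i0
  row_interp <- m[i0, , drop = FALSE] * (1 - fi) + m[i0 + 1L, , drop = FALSE] * fi
  col0 <- row_interp[, i0, drop = FALSE]
  col1 <- row_interp[, i0 + 1L, drop = FALSE]
  col0 * matrix(1 - fi, size, size, byrow = TRUE) +
    col1 * matrix(fi, size, size, byrow = TRUE)
}

#' Generate a synthetic multi-domain cohort
#'
#' Builds a cohort tibble of in-memory tiles: patients are dealt
#' round-robin across the supplied domains, each patient receives a small
#' lognormal perturbation of the class morphologies (a patient effect on
#' nucleus density only, so the domain signal stays purely colorimetric),
#' and labels are balanced within every patient. Each patient maps to one
#' case. Fully deterministic under `seed`.
#'
#' @param n_patients Total number of patients across all domains (at
#'   least 2 per domain).
#' @param tiles_per_patient_per_class Tiles generated per patient and
#'   class (must be >= 1).
#' @param styles Named list of [domain_style()]s, one per domain.
#' @param morph_by_class Named list of [class_morphology()]s.
#' @param patient_effect_sd SD of the lognormal patient effect on nucleus
#'   density (default 0.1).
#' @param size Tile side length in pixels.
#' @param seed Integer seed.
#'
#' @return A cohort tibble with columns `tile_id`, `tile` (list of
#'   [rgb_tile()]), `patient_id`, `case_id`, `label`, `domain`.
#' @examples
#' co <- generate_cohort(4, 2, seed = 1)
#' dplyr::count(co, domain, label)
#' @export
generate_cohort <- function(n_patients,
                            tiles_per_patient_per_class = 8,
                            styles = default_domain_styles(),
                            morph_by_class = default_class_morphologies(),
                            patient_effect_sd = 0.1,
                            size = 96,
                            seed = 1L) {
  stopifnot(tiles_per_patient_per_class >= 1, length(styles) >= 1)
  domains <- names(styles)
  if (is.null(domains)) stop("`styles` must be a named list.", call. = FALSE)
  if (n_patients < 2 * length(styles)) {
    stop("need at least 2 patients per domain.", call. = FALSE)
  }
  with_local_seed(seed, {
    rows <- purrr::map(seq_len(n_patients), function(p) {
      dom <- domains[((p - 1L) %% length(domains)) + 1L]
      pid <- sprintf("%s_p%02d", dom, p)
      eff <- exp(stats::rnorm(1, 0, patient_effect_sd))
      morph_p <- purrr::map(morph_by_class, function(m) {
        class_morphology(m$nucleus_density * eff, m$nucleus_radius_range,
                         m$eosin_texture_scale)
      })
      purrr::map(c(0L, 1L), function(lab) {
        purrr::map(seq_len(tiles_per_patient_per_class), function(k) {
          tibble::tibble(
            tile_id = sprintf("%s_c%d_t%03d", pid, lab, k),
            tile = list(generate_tile(lab, styles[[dom]], morph_p,
                                      size = size)),
            patient_id = pid,
            case_id = pid,
            label = lab,
            domain = dom
          )
        })
      })
    })
    as_cohort(dplyr::bind_rows(purrr::flatten(purrr::flatten(rows))))
  })
}
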