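#' Configuration for sparse stain-matrix estimation
#'
#' Hyperparameters of the sparse nonnegative factorization used by
#' [estimate_stain_profile()]. Vahadane-style stain separation factorizes
#' the optical densities of tissue pixels as `OD ~ W C` with two
#' nonnegative unit-norm stain vectors (columns of `W`) and sparse
#' nonnegative per-pixel concentrations `C`.
#'
#' @param sparsity_penalty Nonnegative l1 penalty on concentrations
#'   (default 0.1, the common dictionary-learning setting).
#' @param od_tissue_threshold Pixels whose maximum-channel OD is at or
#'   below this value count as background glass and are excluded from the
#'   fit (default 0.15, standard Vahadane/Macenko practice).
#' @param max_pixels_for_fit Upper bound on the number of tissue pixels
#'   used for the dictionary fit; larger tiles are subsampled (default
#'   10000).
#' @param min_tissue_pixels Minimum tissue-pixel count below which the
#'   tile is rejected as "insufficient tissue" (default 100).
#' @param max_iter,tol Outer alternating iterations and relative
#'   convergence tolerance on the stain matrix.
#' @param seed Integer seed for the pixel subsample, making the fit
#'   deterministic.
#'
#' @return A list of class `stain_fit_config`.
#' @export
stain_fit_config <- function(sparsity_penalty = 0.1,
                             od_tissue_threshold = 0.15,
                             max_pixels_for_fit = 10000L,
                             min_tissue_pixels = 100L,
                             max_iter = 60L,
                             tol = 1e-6,
                             seed = 1L) {
  stopifnot(sparsity_penalty >= 0, od_tissue_threshold >= 0,
            max_pixels_for_fit >= 1, min_tissue_pixels >= 1, max_iter >= 1)
  structure(list(sparsity_penalty = sparsity_penalty,
                 od_tissue_threshold = od_tissue_threshold,
                 max_pixels_for_fit = as.integer(max_pixels_for_fit),
                 min_tissue_pixels = as.integer(min_tissue_pixels),
                 max_iter = as.integer(max_iter),
                 tol = tol,
                 seed = as.integer(seed)),
            class = "stain_fit_config")
}

#' Stain profile objects
#'
#' A `stain_profile` holds the estimated stain matrix — a `3 x 2` matrix
#' whose columns are unit-norm nonnegative RGB-OD absorption vectors,
#' column 1 hematoxylin-like, column 2 eosin-like — together with a
#' per-stain robust maximum concentration (the 99th percentile over tissue
#' pixels). Normalization transfers a reference profile onto a source tile
#' by rescaling concentrations with the ratio of these scales and
#' re-rendering with the reference matrix.
#'
#' @param stain_matrix `3 x 2` nonnegative matrix; columns are normalized
#'   to unit Euclidean length.
#' @param concentration_scale Positive length-2 vector of robust maximum
#'   concentrations.
#' @param background Per-channel background intensities the profile was
#'   estimated under.
#'
#' @return An object of class `stain_profile`.
#' @export
stain_profile <- function(stain_matrix, concentration_scale,
                          background = c(255, 255, 255)) {
  stain_matrix <- as.matrix(stain_matrix)
  if (!all(dim(stain_matrix) == c(3L, 2L))) {
    stop("`stain_matrix` must be 3 x 2.", call. = FALSE)
  }
  if (min(stain_matrix) < 0) {
    stop("stain vectors must be nonnegative in OD space.", call. = FALSE)
  }
  nrm <- sqrt(colSums(stain_matrix^2))
  if (any(nrm <= 0)) stop("stain vectors must be nonzero.", call. = FALSE)
  stain_matrix <- sweep(stain_matrix, 2, nrm, "/")
  if (length(concentration_scale) != 2L || any(concentration_scale <= 0)) {
    stop("`concentration_scale` must be 2 positive values.", call. = FALSE)
  }
  dimnames(stain_matrix) <- list(c("R", "G", "B"),
                                 c("hematoxylin", "eosin"))
  structure(list(stain_matrix = stain_matrix,
                 concentration_scale = as.numeric(concentration_scale),
                 background = as.numeric(background)),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile>\n")
  print(round(x$stain_matrix, 4))
  cat(sprintf("concentration scale (p99): H = %.3f, E = %.3f\n",
              x$concentration_scale[1], x$concentration_scale[2]))
  invisible(x)
}

# Flatten an od_image into a 3 x n pixel matrix.
od_pixel_matrix <- function(od) {
  d <- dim(od)
  t(matrix(unclass(od), nrow = d[1] * d[2], ncol = 3L))
}

# Hematoxylin absorbs red+blue more strongly than eosin (which is
# green-dominated); order columns so column 1 is the hematoxylin-like one.
order_stain_columns <- function(W) {
  score <- W[1, ] + W[3, ] + 1e-9 * W[3, ]  # tie broken by blue
  W[, order(score, decreasing = TRUE), drop = FALSE]
}

# Exact nonnegative least squares for the 2-column case, vectorized over
# pixels: solve min ||x - W c||^2 (+ lambda |c|_1) with c >= 0. With two
# variables the active sets are enumerable, so the lambda = 0 solution is
# exact; lambda > 0 enters through the standard shifted normal equations.
nnls2 <- function(W, X, lambda = 0) {
  G <- crossprod(W)                      # 2 x 2 Gram
  det_g <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (det_g < 1e-10 * G[1, 1] * G[2, 2] || det_g <= 0) {
    stop("stain matrix is rank-deficient (parallel stain vectors).",
         call. = FALSE)
  }
  B <- crossprod(W, X) - lambda          # 2 x n shifted correlations
  # unconstrained solution of G c = B
  c1 <- (G[2, 2] * B[1, ] - G[1, 2] * B[2, ]) / det_g
  c2 <- (G[1, 1] * B[2, ] - G[1, 2] * B[1, ]) / det_g
  neg <- c1 < 0 | c2 < 0
  if (any(neg)) {
    # candidate with c1 = 0: c2 = max(0, b2 / g22), and vice versa
    a2 <- pmax(0, B[2, neg] / G[2, 2])
    a1 <- pmax(0, B[1, neg] / G[1, 1])
    Xn <- X[, neg, drop = FALSE]
    # objective up to the constant ||x||^2: -2 b'c + c'Gc (+ 2 lambda 1'c
    # already folded into B)
    obj_a <- -2 * B[2, neg] * a2 + G[2, 2] * a2^2
    obj_b <- -2 * B[1, neg] * a1 + G[1, 1] * a1^2
    use_a <- obj_a <= obj_b
    c1[neg] <- ifelse(use_a, 0, a1)
    c2[neg] <- ifelse(use_a, a2, 0)
  }
  rbind(pmax(c1, 0), pmax(c2, 0))
}

# Macenko-style angular initialization: project tissue OD onto the top-2
# principal plane and take robust extreme-angle directions.
init_stain_matrix <- function(X) {
  sv <- svd(X, nu = 2, nv = 0)
  V <- sv$u[, 1:2, drop = FALSE]
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  proj <- crossprod(V, X)
  ang <- atan2(proj[2, ], proj[1, ])
  qs <- stats::quantile(ang, c(0.01, 0.99), names = FALSE)
  w1 <- V %*% c(cos(qs[1]), sin(qs[1]))
  w2 <- V %*% c(cos(qs[2]), sin(qs[2]))
  W <- cbind(pmax(w1, 1e-6), pmax(w2, 1e-6))
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

#' Estimate a tile's stain profile by sparse nonnegative factorization
#'
#' Converts the tile to optical density, masks out background glass
#' (maximum-channel OD at or below `od_tissue_threshold`), and fits a
#' two-component sparse nonnegative factorization `OD ~ W C` by
#' alternating exact nonnegative least squares on the concentrations
#' (with l1 shrinkage) and a projected least-squares update of the stain
#' dictionary, initialized from the principal-plane angular extremes.
#' Columns of `W` are unit-normalized and ordered hematoxylin first.
#'
#' @param tile An [rgb_tile()] with enough tissue (see
#'   `min_tissue_pixels` in [stain_fit_config()]).
#' @param config A [stain_fit_config()].
#' @param background Per-channel background intensities for the OD
#'   transform.
#'
#' @return A [stain_profile()]. The concentration scale is the per-stain
#'   99th percentile of fitted concentrations over all tissue pixels.
#' @examples
#' style <- default_domain_styles()$A
#' tile <- generate_tile(1, style, seed = 7)
#' estimate_stain_profile(tile)
#' @export
estimate_stain_profile <- function(tile, config = stain_fit_config(),
                                   background = c(255, 255, 255)) {
  tile <- assert_tile(tile)
  od <- rgb_to_od(tile, background)
  X_all <- od_pixel_matrix(od)
  tissue <- apply(X_all, 2, max) > config$od_tissue_threshold
  n_tissue <- sum(tissue)
  if (n_tissue < config$min_tissue_pixels) {
    stop(structure(class = c("stainshift_insufficient_tissue",
                             "error", "condition"),
                   list(message = sprintf(
                     "insufficient tissue: %d pixels above OD %.3g (need >= %d).",
                     n_tissue, config$od_tissue_threshold,
                     config$min_tissue_pixels),
                     call = NULL)))
  }
  X_t <- X_all[, tissue, drop = FALSE]
  if (n_tissue > config$max_pixels_for_fit) {
    idx <- local_sample(n_tissue, config$max_pixels_for_fit, config$seed)
    X_fit <- X_t[, idx, drop = FALSE]
  } else {
    X_fit <- X_t
  }

  W <- init_stain_matrix(X_fit)
  lambda <- config$sparsity_penalty
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    C <- nnls2(W, X_fit, lambda)
    CtC <- tcrossprod(C)
    det_c <- CtC[1, 1] * CtC[2, 2] - CtC[1, 2]^2
    if (det_c <= 1e-12) {
      stop(sprintf(paste0(
        "stain factorization did not converge: concentration matrix ",
        "collapsed at iteration %d (Gram determinant %.3g)."), it, det_c),
        call. = FALSE)
    }
    W_new <- tcrossprod(X_fit, C) %*% solve(CtC)
    W_new <- pmax(W_new, 0)
    nrm <- sqrt(colSums(W_new^2))
    if (any(nrm <= 1e-12)) {
      stop("stain factorization did not converge: a stain vector vanished.",
           call. = FALSE)
    }
    W_new <- sweep(W_new, 2, nrm, "/")
    delta <- max(abs(W_new - W))
    W <- W_new
    if (delta < config$tol) { converged <- TRUE; break }
  }
  W <- order_stain_columns(W)
  # scale statistics use the exact (unpenalized) solve so that transfer
  # ratios and re-rendering are consistent and shrinkage-free
  C_all <- nnls2(W, X_t, 0)
  scale99 <- apply(C_all, 1, stats::quantile, probs = 0.99, names = FALSE)
  scale99 <- pmax(scale99, 1e-6)
  stain_profile(W, scale99, background = background)
}

# Seed-local uniform subsample that leaves the caller's RNG untouched.
local_sample <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n, k)
}

#' Solve per-pixel stain concentrations
#'
#' Given a stain matrix `W` (3 x 2, unit-norm nonnegative columns) and an
#' optical-density image, solves the per-pixel nonnegative
#' (optionally l1-regularized) least-squares problem `od ~ W c`. With two
#' stains the nonnegative solution is computed exactly by active-set
#' enumeration, so with `sparsity_penalty = 0` an OD image constructed as
#' `W c` is recovered to machine precision.
#'
#' @param od An `od_image` (or nonnegative `H x W x 3` array).
#' @param stain_matrix `3 x 2` matrix with nonnegative unit-norm columns.
#' @param sparsity_penalty Nonnegative l1 shrinkage on concentrations.
#'
#' @return An `H x W x 2` nonnegative array of class `concentration_map`.
#' @export
compute_concentrations <- function(od, stain_matrix, sparsity_penalty = 0) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L) {
    stop("`od` must be an H x W x 3 array.", call. = FALSE)
  }
  W <- as.matrix(stain_matrix)
  stopifnot(all(dim(W) == c(3L, 2L)))
  if (min(W) < -1e-9) stop("stain matrix must be nonnegative.", call. = FALSE)
  nrm <- sqrt(colSums(W^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("stain matrix columns must be unit norm.", call. = FALSE)
  }
  d <- dim(od)
  C <- nnls2(W, od_pixel_matrix(od), sparsity_penalty)
  structure(array(t(C), dim = c(d[1], d[2], 2L)),
            class = "concentration_map")
}

#' Normalize a tile's stain colors to a reference profile
#'
#' Vahadane-style stain normalization: the tile's own stain profile is
#' estimated, its per-pixel concentrations are rescaled stain-wise by
#' `reference_scale / source_scale` (99th-percentile robust maxima), and
#' the tile is re-rendered through the reference stain matrix. This
#' removes laboratory/scanner color variation while preserving the
#' morphological content carried by the concentrations.
#'
#' @param tile An [rgb_tile()].
#' @param reference A [stain_profile()], typically from
#'   [estimate_stain_profile()] on a chosen reference tile.
#' @param config A [stain_fit_config()] used to estimate the source
#'   profile.
#' @param pass_through If `TRUE` (the default, so batch runs never abort
#'   mid-cohort), tiles with insufficient tissue are returned unchanged
#'   with a warning instead of erroring.
#'
#' @return An [rgb_tile()] with the same dimensions as the input.
#' @examples
#' styles <- default_domain_styles()
#' ref  <- generate_tile(1, styles$A, seed = 1)
#' tile <- generate_tile(1, styles$B, seed = 2)
#' norm <- normalize_to_reference(tile, estimate_stain_profile(ref))
#' @export
normalize_to_reference <- function(tile, reference,
                                   config = stain_fit_config(),
                                   pass_through = TRUE) {
  tile <- assert_tile(tile)
  if (!inherits(reference, "stain_profile")) {
    stop("`reference` must be a stain_profile.", call. = FALSE)
  }
  src <- tryCatch(
    estimate_stain_profile(tile, config, background = reference$background),
    stainshift_insufficient_tissue = function(e) {
      if (pass_through) {
        warning("tile has insufficient tissue; passed through unchanged.",
                call. = FALSE)
        NULL
      } else stop(e)
    })
  if (is.null(src)) return(tile)
  od <- rgb_to_od(tile, reference$background)
  C <- compute_concentrations(od, src$stain_matrix, sparsity_penalty = 0)
  scale_ratio <- reference$concentration_scale / src$concentration_scale
  d <- dim(tile)
  Cm <- t(matrix(unclass(C), nrow = d[1] * d[2], ncol = 2L)) * scale_ratio
  od_new <- array(t(reference$stain_matrix %*% Cm), dim = d)
  od_to_rgb(od_new, background = reference$background,
            microns_per_pixel = attr(tile, "microns_per_pixel"))
}

#' Random HSV color augmentation
#'
#' Train-time color augmentation: the tile is converted to
#' hue/saturation/value space, a uniform hue offset (a fraction of the hue
#' circle, wrapping modulo 1) is added, saturation and value are
#' multiplied by uniform factors and clipped to `[0, 1]`, and the result
#' is converted back to RGB. One (hue, saturation, value) perturbation is
#' drawn per call and applied to the whole tile, emulating a scanner-level
#' color-scheme change.
#'
#' @param tile An [rgb_tile()].
#' @param hue_shift Length-2 range of the hue offset in fractions of the
#'   circle (default +/- 0.1).
#' @param sat_factor,val_factor Length-2 ranges of the multiplicative
#'   saturation and value factors (default `[0.8, 1.25]`).
#' @param seed Optional integer seed; when supplied the draw is
#'   deterministic and the caller's RNG state is untouched. With
#'   `seed = NULL` the current RNG stream is used.
#'
#' @return An [rgb_tile()] of the same dimensions.
#' @export
hsv_augment <- function(tile, hue_shift = c(-0.1, 0.1),
                        sat_factor = c(0.8, 1.25),
                        val_factor = c(0.8, 1.25),
                        seed = NULL) {
  tile <- assert_tile(tile)
  stopifnot(length(hue_shift) == 2L, length(sat_factor) == 2L,
            length(val_factor) == 2L, all(is.finite(c(hue_shift, sat_factor,
                                                      val_factor))))
  draw <- function() c(stats::runif(1, hue_shift[1], hue_shift[2]),
                       stats::runif(1, sat_factor[1], sat_factor[2]),
                       stats::runif(1, val_factor[1], val_factor[2]))
  pars <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  shift_hsv(tile, pars[1], pars[2], pars[3])
}

# Deterministic HSV shift shared by hsv_augment and tests.
shift_hsv <- function(tile, dh, fs, fv) {
  d <- dim(tile)
  px <- t(matrix(unclass(tile), nrow = d[1] * d[2], ncol = 3L))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  h <- (hsv[1, ] + dh) %% 1
  s <- pmin(pmax(hsv[2, ] * fs, 0), 1)
  v <- pmin(pmax(hsv[3, ] * fv, 0), 1)
  rgb_tile(array(t(hsv_to_rgb_matrix(h, s, v)), dim = d),
           microns_per_pixel = attr(tile, "microns_per_pixel"))
}

# Vectorized HSV -> RGB on [0,1] inputs, returning 3 x n intensities in
# [0, 255] (grDevices::hsv() goes through hex strings, too slow per pixel).
hsv_to_rgb_matrix <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  round(rbind(r, g, b) * 255)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize and restore stain profiles as JSON
#'
#' The stain matrix is stored row-major with the concentration scale and
#' background so a reference profile can be shared between runs and
#' audited.
#'
#' @param profile A [stain_profile()].
#' @param path JSON file path.
#' @return `write_stain_profile()` returns `path` invisibly;
#'   `read_stain_profile()` returns a [stain_profile()].
#' @export
write_stain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stain_profile"))
  jsonlite::write_json(list(
    stain_matrix = matrix(profile$stain_matrix, nrow = 3),
    concentration_scale = profile$concentration_scale,
    background = profile$background
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_profile(matrix(unlist(x$stain_matrix), nrow = 3),
                x$concentration_scale, x$background)
}
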