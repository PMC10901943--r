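truth_matrix <- function() default_domain_styles()$A$stain_matrix

test_that("stain vectors are recovered from tiles with known matrices", {
  style <- default_domain_styles()$A  # pure stain rendering, noise sd 2
  for (s in c(3, 17)) {
    tile <- generate_tile(1, style, seed = s)
    prof <- estimate_stain_profile(tile)
    cosines <- diag(crossprod(prof$stain_matrix, truth_matrix()))
    expect_true(all(cosines >= 0.99))
    expect_equal(sqrt(colSums(prof$stain_matrix^2)), c(1, 1),
                 ignore_attr = TRUE, tolerance = 1e-6)
    expect_true(all(prof$stain_matrix >= 0))
    expect_true(all(prof$concentration_scale > 0))
  }
})

test_that("tissue-free tiles are rejected and estimation is deterministic", {
  white <- flat_tile(250, 250, 250, n = 64)
  expect_error(estimate_stain_profile(white), "insufficient tissue",
               class = "stainshift_insufficient_tissue")
  tile <- generate_tile(0, default_domain_styles()$A, seed = 9)
  p1 <- estimate_stain_profile(tile)
  p2 <- estimate_stain_profile(tile)
  expect_identical(p1, p2)
})

test_that("concentration solver inverts exact constructions", {
  W <- truth_matrix()
  set.seed(2)
  C <- array(stats::runif(18 * 18 * 2, 0, 1.5), dim = c(18, 18, 2))
  od <- array(t(W %*% t(matrix(C, 18 * 18, 2))), dim = c(18, 18, 3))
  Ch <- compute_concentrations(od, W, sparsity_penalty = 0)
  expect_lt(max(abs(unclass(Ch) - C)), 1e-6)

  zero <- compute_concentrations(array(0, dim = c(4, 4, 3)), W)
  expect_equal(max(abs(zero)), 0)

  # nonnegativity holds for arbitrary valid OD input
  od_r <- array(stats::runif(10 * 10 * 3, 0, 2), dim = c(10, 10, 3))
  expect_gte(min(compute_concentrations(od_r, W, 0.1)), 0)

  W_par <- cbind(W[, 1], W[, 1])
  expect_error(compute_concentrations(od_r, W_par), "rank-deficient")
})

test_that("normalizing a tile to its own profile is nearly idempotent", {
  tile <- generate_tile(1, default_domain_styles()$A, seed = 3)
  prof <- estimate_stain_profile(tile)
  norm <- normalize_to_reference(tile, prof)
  expect_lte(mean(abs(unclass(norm) - unclass(tile))), 2)
  expect_identical(dim(norm), dim(tile))
  norm2 <- normalize_to_reference(norm, prof)
  expect_lte(mean(abs(unclass(norm2) - unclass(norm))), 2)
})

test_that("two renderings of one concentration field converge under a shared reference", {
  # construction oracle: same concentrations, two stain matrices
  styles <- default_domain_styles()
  W_a <- styles$A$stain_matrix
  W_b <- styles$B$stain_matrix
  set.seed(4)
  tpl <- generate_tile(1, styles$A, seed = 21)
  odA <- rgb_to_od(tpl)
  C <- compute_concentrations(odA, W_a, 0)
  Cm <- t(matrix(unclass(C), 96 * 96, 2))
  render <- function(W) od_to_rgb(array(t(W %*% Cm), dim = c(96, 96, 3)))
  ta <- render(W_a)
  tb <- render(W_b)
  ref <- estimate_stain_profile(ta)
  na_ <- normalize_to_reference(ta, ref)
  nb_ <- normalize_to_reference(tb, ref)
  expect_lte(mean(abs(unclass(na_) - unclass(nb_))), 2)
})

test_that("tissue-free tiles pass through normalization with a warning", {
  ref <- estimate_stain_profile(generate_tile(1, default_domain_styles()$A,
                                              seed = 3))
  white <- flat_tile(250, 250, 250, n = 64)
  expect_warning(out <- normalize_to_reference(white, ref), "insufficient")
  expect_identical(unclass(out), unclass(white))
  expect_error(normalize_to_reference(white, ref, pass_through = FALSE),
               class = "stainshift_insufficient_tissue")
})

test_that("normalization to a shared reference reduces the domain color gap", {
  # two domains that differ ONLY in stain matrix
  styles <- default_domain_styles()
  sa <- styles$A
  sb <- domain_style(styles$B$stain_matrix)
  hist_rgb <- function(tiles) {
    h <- sapply(tiles, function(t) {
      px <- unclass(t)
      c(tabulate(pmin(px[, , 1] %/% 16 + 1, 16), 16),
        tabulate(pmin(px[, , 2] %/% 16 + 1, 16), 16),
        tabulate(pmin(px[, , 3] %/% 16 + 1, 16), 16)) / length(px[, , 1])
    })
    rowMeans(h)
  }
  ta <- lapply(1:4, function(s) generate_tile(s %% 2, sa, seed = s))
  tb <- lapply(1:4, function(s) generate_tile(s %% 2, sb, seed = 10 + s))
  ref <- estimate_stain_profile(ta[[1]])
  na_ <- lapply(ta, normalize_to_reference, reference = ref)
  nb_ <- lapply(tb, normalize_to_reference, reference = ref)
  d_before <- sum(abs(hist_rgb(ta) - hist_rgb(tb)))
  d_after <- sum(abs(hist_rgb(na_) - hist_rgb(nb_)))
  expect_lt(d_after, d_before)
})

test_that("HSV augmentation is identity at degenerate ranges and seed-stable", {
  tile <- generate_tile(0, default_domain_styles()$A, size = 48, seed = 2)
  ident <- hsv_augment(tile, hue_shift = c(0, 0), sat_factor = c(1, 1),
                       val_factor = c(1, 1), seed = 1)
  expect_lte(max(abs(unclass(ident) - unclass(tile))), 1)
  a <- hsv_augment(tile, seed = 42)
  b <- hsv_augment(tile, seed = 42)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a),
                         unclass(hsv_augment(tile, seed = 43))))
})

test_that("a half-circle hue shift maps red to cyan", {
  red <- flat_tile(255, 0, 0, n = 4)
  out <- hsv_augment(red, hue_shift = c(0.5, 0.5), sat_factor = c(1, 1),
                     val_factor = c(1, 1), seed = 1)
  px <- unclass(out)[1, 1, ]
  expect_equal(px, c(0, 255, 255), ignore_attr = TRUE)
})

test_that("stain profiles round-trip through JSON", {
  prof <- estimate_stain_profile(generate_tile(1, default_domain_styles()$A,
                                               seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_stain_profile(prof, path)
  back <- read_stain_profile(path)
  expect_equal(back$stain_matrix, prof$stain_matrix, tolerance = 1e-12)
  expect_equal(back$concentration_scale, prof$concentration_scale,
               tolerance = 1e-12)
})
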