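# fraction of pixels carrying nucleus-level hematoxylin, judged by
# projecting the tile's OD onto the generating stain matrix
disk_fraction <- function(tile, style) {
  C <- compute_concentrations(rgb_to_od(tile, style$background),
                              style$stain_matrix, 0)
  mean(C[, , 1] > 0.35)
}

test_that("tile generation is deterministic under seed", {
  style <- default_domain_styles()$A
  a <- generate_tile(1, style, seed = 5)
  b <- generate_tile(1, style, seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(generate_tile(1, style,
                                                           seed = 6))))
})

test_that("doubling nucleus density raises the disk-pixel fraction", {
  style <- default_domain_styles()$A
  lo <- class_morphology(8)
  hi <- class_morphology(16)
  morph <- list(`0` = lo, `1` = hi)
  fr <- sapply(1:20, function(s) {
    c(disk_fraction(generate_tile(0, style, morph, seed = s), style),
      disk_fraction(generate_tile(1, style, morph, seed = 100 + s), style))
  })
  expect_gt(mean(fr[2, ]), mean(fr[1, ]))
})

test_that("stain-matrix changes move color but not morphology", {
  styles <- default_domain_styles()
  sa <- styles$A
  sb <- domain_style(styles$B$stain_matrix)  # differs only in stain matrix
  mean_diff <- frac <- matrix(NA_real_, 2, 10)
  for (s in 1:10) {
    ta <- generate_tile(1, sa, seed = s)
    tb <- generate_tile(1, sb, seed = s)
    mean_diff[, s] <- c(mean(unclass(ta)[, , 1]) - mean(unclass(tb)[, , 1]),
                        mean(unclass(ta)[, , 3]) - mean(unclass(tb)[, , 3]))
    frac[, s] <- c(disk_fraction(ta, sa), disk_fraction(tb, sb))
  }
  expect_gt(max(abs(rowMeans(mean_diff))), 2)      # color moved
  expect_lt(max(abs(frac[1, ] - frac[2, ])), 0.01) # morphology intact
})

test_that("cohort generation yields the expected record grid", {
  co <- generate_cohort(10, 8, size = 32, seed = 3)
  expect_equal(nrow(co), 10 * 8 * 2)
  expect_equal(dplyr::n_distinct(co$patient_id), 10)
  # all records of one patient share one domain
  pd <- dplyr::distinct(co, .data$patient_id, .data$domain)
  expect_equal(anyDuplicated(pd$patient_id), 0)
  # labels balanced per patient
  bal <- dplyr::count(co, .data$patient_id, .data$label)
  expect_true(all(bal$n == 8))
  expect_identical(co$tile_id,
                   generate_cohort(10, 8, size = 32, seed = 3)$tile_id)
  expect_error(generate_cohort(2, 4, seed = 1), "2 patients per domain")
  expect_error(generate_cohort(10, 0, seed = 1), ">= 1")
})

test_that("identical class morphologies trigger an unlearnability warning", {
  m <- default_class_morphologies()
  m$`1` <- m$`0`
  expect_warning(generate_tile(1, default_domain_styles()$A, m, seed = 1),
                 "unlearnable")
})

test_that("the engineered domain gap opens and is closed by normalization", {
  # pinned study conditions: 20 patients per domain, default styles
  co <- generate_cohort(40, 8, seed = 11)
  int <- dplyr::filter(co, .data$domain == "A")
  ext <- dplyr::filter(co, .data$domain == "B")
  sp <- patient_stratified_split(int, seed = 6)
  clf <- fit(reference_classifier(), sp$train)
  acc <- function(co) {
    accuracy(as.integer(predict_proba(clf, co) >= 0.5), co$label)
  }
  acc_int <- acc(sp$test)
  acc_ext <- acc(ext)
  expect_gte(acc_int, 0.9)
  expect_gte(acc_int - acc_ext, 0.05)
})
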