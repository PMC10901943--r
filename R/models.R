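#' Training configuration for tile classifiers
#'
#' Mirrors the standard tile-classification training recipe: 25 epochs of
#' an AdaMax-type adaptive-gradient optimizer at learning rate 0.001
#' under binary cross-entropy. The reference classifier interprets one
#' epoch as `steps_per_epoch` full-batch gradient steps; wrapped external
#' models are free to map the fields onto their own training loop.
#'
#' @param epochs Training epochs (>= 1, default 25).
#' @param learning_rate Positive learning rate (default 0.001).
#' @param optimizer_name,loss_name Documentation strings for the report
#'   metadata.
#' @param steps_per_epoch Full-batch gradient steps per epoch for the
#'   reference classifier (default 60, enough for the AdaMax iterates to
#'   reach the regularized optimum on desk-scale feature matrices).
#' @param l2 Ridge penalty on the reference classifier's weights.
#' @param seed Integer seed.
#'
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 25L, learning_rate = 0.001,
                            optimizer_name = "adamax",
                            loss_name = "binary_cross_entropy",
                            steps_per_epoch = 60L, l2 = 1e-3, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, steps_per_epoch >= 1, l2 >= 0)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name,
                 loss_name = loss_name,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 l2 = l2, seed = as.integer(seed)),
            class = "training_config")
}

#' @importFrom generics fit
#' @export
generics::fit

#' Predict per-tile class-1 probabilities
#'
#' The second half of the tile-classifier contract: given a cohort,
#' return one probability in `[0, 1]` per row. See
#' [check_classifier_contract()] for the conformance suite any
#' user-supplied classifier can be run against.
#'
#' @param object A fitted classifier.
#' @param cohort A cohort tibble.
#' @param ... Passed to methods.
#' @return Numeric vector of class-1 probabilities, one per tile.
#' @export
predict_proba <- function(object, cohort, ...) {
  UseMethod("predict_proba")
}

# ---- fixed image features -------------------------------------------------

# Deterministic tile descriptor: block-averaged downsampled pixels per
# channel (morphology + color), per-channel intensity histograms (color
# distribution), and a gradient-energy texture summary. The grid is kept
# coarse (4 x 4): finer grids mostly encode random object positions,
# which inflates the capacity available for fitting label noise without
# adding class signal.
tile_features <- function(tile, grid = 4L, hist_bins = 8L) {
  px <- unclass(tile) / 255
  d <- dim(px)
  down <- vapply(1:3, function(ch) {
    as.vector(block_mean(px[, , ch], grid))
  }, numeric(grid * grid))
  hists <- vapply(1:3, function(ch) {
    h <- tabulate(pmin(floor(px[, , ch] * hist_bins) + 1L, hist_bins),
                  nbins = hist_bins)
    h / (d[1] * d[2])
  }, numeric(hist_bins))
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  gx <- gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE]
  gy <- gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE]
  grad_energy <- mean(gx^2) + mean(gy^2)
  c(as.vector(down), as.vector(hists), grad_energy)
}

block_mean <- function(m, grid) {
  n <- nrow(m); p <- ncol(m)
  ri <- ceiling(seq_len(n) / (n / grid))
  ci <- ceiling(seq_len(p) / (p / grid))
  sums <- rowsum(m, ri)
  sums <- t(rowsum(t(sums), ci))
  counts <- tabulate(ri, grid) %o% tabulate(ci, grid)
  sums / counts
}

cohort_feature_matrix <- function(cohort) {
  t(vapply(seq_len(nrow(cohort)),
           function(i) tile_features(cohort_tile(cohort, i)),
           tile_features(cohort_tile(cohort, 1))))
}

# ---- reference classifier -------------------------------------------------

#' A tiny deterministic reference tile classifier
#'
#' A desk-scale stand-in for the deep networks used in production tile
#' classification: fixed image features (downsampled pixels, channel
#' histograms, gradient energy) feeding a ridge-regularized logistic
#' decision rule trained by full-batch AdaMax gradient steps under binary
#' cross-entropy. It carries no external weights, trains in well under a
#' second on desk-scale cohorts, and is fully deterministic given its
#' seed — but it is *not* equivalent to a CNN or ViT; it exists so the
#' protocols around the model (normalization, artifacts, ensembles) can
#' be exercised and tested quickly.
#'
#' @param config A [training_config()].
#'
#' @return An unfitted classifier of class `ref_classifier`; train with
#'   [fit()] and predict with [predict_proba()].
#' @examples
#' co <- generate_cohort(6, 4, styles = default_domain_styles()["A"],
#'                       seed = 1)
#' clf <- fit(reference_classifier(), co)
#' head(predict_proba(clf, co))
#' @export
reference_classifier <- function(config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  structure(list(config = config, fitted = FALSE), class = "ref_classifier")
}

#' @rdname reference_classifier
#' @param object A `ref_classifier`.
#' @param cohort Training cohort tibble with materialized labels.
#' @param ... Unused.
#' @export
fit.ref_classifier <- function(object, cohort, ...) {
  check_cohort(cohort)
  X <- cohort_feature_matrix(cohort)
  y <- cohort$label
  mu <- colMeans(X)
  sd_ <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")

  cfg <- object$config
  p <- ncol(Xs)
  w <- numeric(p); b <- 0
  # AdaMax state (infinity-norm variant of Adam)
  m1 <- numeric(p + 1); u <- numeric(p + 1)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)
  steps <- cfg$epochs * cfg$steps_per_epoch
  for (t_ in seq_len(steps)) {
    eta <- 1 / (1 + exp(-(Xs %*% w + b)))
    resid <- as.vector(eta) - y
    g <- c(crossprod(Xs, resid) / n + cfg$l2 * w, mean(resid))
    m1 <- beta1 * m1 + (1 - beta1) * g
    u <- pmax(beta2 * u, abs(g))
    step <- (cfg$learning_rate / (1 - beta1^t_)) * m1 / (u + eps)
    w <- w - step[seq_len(p)]
    b <- b - step[p + 1]
  }
  structure(list(config = cfg, fitted = TRUE, w = w, b = b,
                 mu = mu, sd = sd_),
            class = "ref_classifier")
}

#' @rdname reference_classifier
#' @export
predict_proba.ref_classifier <- function(object, cohort, ...) {
  if (!isTRUE(object$fitted)) {
    stop("classifier has not been fitted; call fit() first.", call. = FALSE)
  }
  check_cohort(cohort)
  X <- cohort_feature_matrix(cohort)
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  as.vector(1 / (1 + exp(-(Xs %*% object$w + object$b))))
}

#' @export
print.ref_classifier <- function(x, ...) {
  cat(sprintf("<ref_classifier (%s)>\n",
              if (isTRUE(x$fitted)) "fitted" else "unfitted"))
  invisible(x)
}

#' Train one classifier per ensemble member plan
#'
#' Materializes each member's training cohort via [apply_member_plan()],
#' applies the configured train-time augmentation chain (HSV and/or
#' artifact injectors — augmentations touch training tiles only), and
#' fits one classifier per member. Failures are re-thrown with the member
#' index attached.
#'
#' @param classifier_factory Zero-argument function returning an unfitted
#'   classifier honoring the [fit()]/[predict_proba()] contract.
#' @param cohort Training cohort tibble.
#' @param plan An `ensemble_plan` from [make_ensemble_plan()].
#' @param augmentations List of `function(tile) -> tile` transforms
#'   applied in order to every member training tile.
#' @param seed Seed for the augmentation draws (member streams derived
#'   from it).
#'
#' @return List of fitted classifiers, one per member.
#' @export
train_with_plan <- function(classifier_factory, cohort, plan,
                            augmentations = list(), seed = 1L) {
  check_cohort(cohort)
  stopifnot(inherits(plan, "ensemble_plan"))
  aug_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, plan$n_members))
  purrr::map(seq_along(plan$members), function(m) {
    tryCatch({
      data_m <- apply_member_plan(cohort, plan$members[[m]])
      if (length(augmentations) > 0) {
        data_m <- with_local_seed(aug_seeds[m], map_cohort_tiles(
          data_m, function(tile) {
            for (f in augmentations) tile <- f(tile)
            tile
          }))
      }
      fit(classifier_factory(), data_m)
    }, error = function(e) {
      stop(sprintf("ensemble member %d failed: %s", m, conditionMessage(e)),
           call. = FALSE)
    })
  })
}

#' Conformance suite for the tile-classifier contract
#'
#' Runs any user-supplied classifier factory through the behavioral
#' contract every stainshift experiment relies on: `predict_proba()`
#' returns one value per input tile, all values lie in `[0, 1]`, and
#' training plus prediction are deterministic given the same data and
#' seed. Returns a tibble of named checks so wrapped external models
#' (CNNs, ViTs, anything satisfying fit/predict_proba) can be validated
#' before being plugged into an experiment.
#'
#' @param classifier_factory Zero-argument function returning an unfitted
#'   classifier.
#' @param train_cohort,test_cohort Cohort tibbles used for the probe.
#'
#' @return A tibble with columns `check`, `pass`, `detail`; attribute
#'   `conformant` is `TRUE` iff all checks pass.
#' @examples
#' co <- generate_cohort(4, 3, styles = default_domain_styles()["A"],
#'                       seed = 2)
#' res <- check_classifier_contract(reference_classifier, co, co)
#' attr(res, "conformant")
#' @export
check_classifier_contract <- function(classifier_factory, train_cohort,
                                      test_cohort) {
  check_cohort(train_cohort); check_cohort(test_cohort)
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = name, pass = isTRUE(pass), detail = detail)
  }
  probs <- try({
    clf <- fit(classifier_factory(), train_cohort)
    predict_proba(clf, test_cohort)
  }, silent = TRUE)
  if (inherits(probs, "try-error")) {
    add("fit_and_predict", FALSE, as.character(probs))
  } else {
    add("fit_and_predict", TRUE)
    add("output_length", length(probs) == nrow(test_cohort),
        sprintf("%d probabilities for %d tiles", length(probs),
                nrow(test_cohort)))
    add("probability_bounds",
        is.numeric(probs) && !anyNA(probs) &&
          min(probs) >= 0 && max(probs) <= 1,
        sprintf("range [%.3g, %.3g]",
                suppressWarnings(min(probs)),
                suppressWarnings(max(probs))))
    probs2 <- try({
      clf2 <- fit(classifier_factory(), train_cohort)
      predict_proba(clf2, test_cohort)
    }, silent = TRUE)
    add("determinism_under_seed",
        !inherits(probs2, "try-error") && identical(length(probs2),
                                                    length(probs)) &&
          isTRUE(all(probs2 == probs)),
        "refit on identical data reproduces predictions exactly")
  }
  out <- dplyr::bind_rows(checks)
  attr(out, "conformant") <- all(out$pass)
  out
}
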