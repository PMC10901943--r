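#' Tile-level classification accuracy
#'
#' Fraction of exact matches between predicted and true binary labels —
#' the tile-level accuracy used throughout internal/external transfer
#' reporting.
#'
#' @param predicted,truth Equal-length nonempty label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0 || length(truth) == 0) {
    stop("labels must be nonempty.", call. = FALSE)
  }
  if (length(predicted) != length(truth)) {
    stop(sprintf("length mismatch: %d predictions vs %d labels.",
                 length(predicted), length(truth)), call. = FALSE)
  }
  mean(predicted == truth)
}

#' Performance gain from training with an artifact
#'
#' The delta statistic of artifact-robustness analysis:
#' `delta = accuracy_with_artifact_in_training -
#' accuracy_without_artifact_in_training`, both evaluated on
#' artifact-bearing test tiles. Positive delta means training-time
#' exposure to the artifact preserved performance.
#'
#' @param acc_with,acc_without Accuracies in `[0, 1]`.
#' @return Signed difference in `[-1, 1]`.
#' @export
delta_performance <- function(acc_with, acc_without) {
  stopifnot(acc_with >= 0, acc_with <= 1, acc_without >= 0,
            acc_without <= 1)
  acc_with - acc_without
}

#' Exact binomial sign test over paired seeds
#'
#' All experiment protocols share seeds across their arms, so per-seed
#' accuracy differences are paired; with a handful of seeds an exact
#' binomial sign test on the signs of the nonzero differences is the
#' appropriate significance probe.
#'
#' @param differences Vector of paired per-seed differences.
#' @return A tibble with `n_positive`, `n_nonzero`, `p_value` (two-sided
#'   exact binomial).
#' @export
paired_sign_test <- function(differences) {
  nz <- differences[differences != 0]
  if (length(nz) == 0) {
    return(tibble::tibble(n_positive = 0L, n_nonzero = 0L, p_value = 1))
  }
  ht <- stats::binom.test(sum(nz > 0), length(nz))
  tibble::tibble(n_positive = sum(nz > 0), n_nonzero = length(nz),
                 p_value = ht$p.value)
}

# ---- shared harness internals --------------------------------------------

assert_disjoint_domains <- function(internal, external) {
  check_cohort(internal); check_cohort(external)
  overlap <- intersect(unique(internal$patient_id),
                       unique(external$patient_id))
  if (length(overlap) > 0) {
    stop(sprintf("internal and external cohorts share patient(s): %s.",
                 paste(utils::head(overlap, 3), collapse = ", ")),
         call. = FALSE)
  }
  if (length(intersect(unique(internal$domain),
                       unique(external$domain))) > 0) {
    stop("external cohort must come from a different domain.",
         call. = FALSE)
  }
}

experiment_seeds <- function(n_seeds, seed) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n_seeds))
}

fit_and_eval <- function(classifier_factory, train, tests, config) {
  clf <- fit(classifier_factory(config), train)
  purrr::imap_dfr(tests, function(co, nm) {
    pr <- predict_proba(clf, co)
    tibble::tibble(dataset = nm,
                   accuracy = accuracy(as.integer(pr >= 0.5), co$label))
  })
}

summarize_runs <- function(runs, by) {
  runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     n_seeds = dplyr::n(), .groups = "drop")
}

new_experiment_report <- function(runs, summary, meta, subclass) {
  structure(list(runs = runs, summary = summary, meta = meta),
            class = c(subclass, "stainshift_report"))
}

#' @export
print.stainshift_report <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  print(x$summary, n = Inf)
  invisible(x)
}

# ---- experiment 1: stain normalization / HSV ------------------------------

#' Internal-vs-external evaluation under color-handling modes
#'
#' The stain-normalization experiment: train a classifier on internal
#' tiles and evaluate on an internal held-out test and an external-domain
#' test, under three color-handling modes — `raw` (no color handling),
#' `stain_normalized` (Vahadane-style normalization of *training and
#' test* tiles to a shared reference) and `hsv_augmented` (random HSV
#' color augmentation of *training tiles only*). The internal cohort is
#' re-split patient-stratified per seed and the seeds are shared across
#' modes, so per-seed accuracy differences between modes are paired.
#'
#' @param internal Internal-domain cohort tibble (will be split per
#'   seed).
#' @param external External-domain cohort tibble (test only); must share
#'   no patients or domain tag with `internal`.
#' @param modes Subset of `c("raw", "stain_normalized", "hsv_augmented")`.
#' @param classifier_factory Function of one argument (a
#'   [training_config()]) returning an unfitted classifier.
#' @param n_seeds Number of paired seeds (default 5).
#' @param seed Master seed from which per-run seeds are derived.
#' @param reference_tile Reference [rgb_tile()] for normalization;
#'   default: the first internal tile.
#' @param stain_config A [stain_fit_config()].
#' @param split_fractions Patient-level train/val/test fractions for the
#'   internal resplit.
#' @param config A [training_config()] passed to the factory.
#'
#' @return A `normalization_experiment` report: `$runs` (mode x dataset x
#'   seed accuracies), `$summary` (mean +/- sd), `$meta`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
run_normalization_experiment <- function(internal, external,
                                         modes = c("raw",
                                                   "stain_normalized",
                                                   "hsv_augmented"),
                                         classifier_factory =
                                           reference_classifier,
                                         n_seeds = 5L, seed = 1L,
                                         reference_tile = NULL,
                                         stain_config = stain_fit_config(),
                                         split_fractions = c(0.6, 0.2, 0.2),
                                         config = training_config()) {
  assert_disjoint_domains(internal, external)
  modes <- match.arg(modes, several.ok = TRUE)
  seeds <- experiment_seeds(n_seeds, seed)

  cohorts <- list(internal = internal, external = external)
  if ("stain_normalized" %in% modes) {
    if (is.null(reference_tile)) reference_tile <- cohort_tile(internal, 1)
    ref_profile <- estimate_stain_profile(reference_tile, stain_config)
    normalize_all <- function(co) map_cohort_tiles(co, function(t) {
      normalize_to_reference(t, ref_profile, stain_config)
    })
    cohorts$internal_fn <- normalize_all(internal)
    cohorts$external_fn <- normalize_all(external)
  }

  runs <- purrr::map_dfr(seq_along(seeds), function(si) {
    s <- seeds[si]
    idx_splits <- patient_stratified_split(internal, stats::setNames(
      split_fractions, c("train", "val", "test")), seed = s)
    train_pids <- unique(idx_splits$train$patient_id)
    test_pids <- unique(idx_splits$test$patient_id)
    purrr::map_dfr(modes, function(mode) {
      if (mode == "stain_normalized") {
        tr <- cohorts$internal_fn[cohorts$internal_fn$patient_id %in%
                                    train_pids, ]
        tests <- list(
          internal = cohorts$internal_fn[cohorts$internal_fn$patient_id %in%
                                           test_pids, ],
          external = cohorts$external_fn)
      } else {
        tr <- internal[internal$patient_id %in% train_pids, ]
        tests <- list(
          internal = internal[internal$patient_id %in% test_pids, ],
          external = external)
        if (mode == "hsv_augmented") {
          tr <- with_local_seed(s + 1L,
            map_cohort_tiles(tr, function(t) hsv_augment(t)))
        }
      }
      out <- fit_and_eval(classifier_factory, tr, tests, config)
      out$mode <- mode
      out$seed_index <- si
      out
    })
  })
  summary <- summarize_runs(runs, c("mode", "dataset"))
  new_experiment_report(runs, summary,
                        list(n_seeds = n_seeds, seed = seed, modes = modes),
                        "normalization_experiment")
}

# ---- experiment 2: artifact robustness ------------------------------------

#' Artifact-robustness curves with and without training-time exposure
#'
#' For each artifact strength, both arms are evaluated on
#' artifact-bearing test tiles (internal and external): the `without` arm
#' is trained on clean tiles, the `with` arm on tiles carrying the same
#' artifact. The per-strength performance gain is
#' `delta = accuracy_with - accuracy_without` (see
#' [delta_performance()]). The internal cohort is re-split per seed;
#' seeds are shared between arms and strengths, so curves are paired.
#'
#' @inheritParams run_normalization_experiment
#' @param family Artifact family (see [artifact_spec()]).
#' @param strengths Nonempty vector of strengths, swept in order.
#'
#' @return An `artifact_experiment` report whose `$summary` holds the
#'   per-dataset robustness curve (`strength`, `acc_with`, `acc_without`,
#'   `delta`).
#' @export
run_artifact_experiment <- function(internal, external,
                                    family = "blur",
                                    strengths = c(0, 0.5, 1, 2),
                                    classifier_factory =
                                      reference_classifier,
                                    n_seeds = 5L, seed = 1L,
                                    split_fractions = c(0.6, 0.2, 0.2),
                                    config = training_config()) {
  assert_disjoint_domains(internal, external)
  specs <- artifact_sweep(family, strengths)
  seeds <- experiment_seeds(n_seeds, seed)

  # artifact injection is deterministic: corrupt each cohort once per
  # strength and index the per-seed splits into the corrupted tiles
  corrupt <- function(co, spec) map_cohort_tiles(co, function(t) {
    apply_artifact(t, spec)
  })
  internal_c <- purrr::map(specs, function(sp) corrupt(internal, sp))
  external_c <- purrr::map(specs, function(sp) corrupt(external, sp))

  runs <- purrr::map_dfr(seq_along(seeds), function(si) {
    s <- seeds[si]
    sp <- patient_stratified_split(internal, stats::setNames(
      split_fractions, c("train", "val", "test")), seed = s)
    train_pids <- unique(sp$train$patient_id)
    test_pids <- unique(sp$test$patient_id)
    clean_clf <- fit(classifier_factory(config),
                     internal[internal$patient_id %in% train_pids, ])
    purrr::map_dfr(seq_along(specs), function(k) {
      tests <- list(
        internal = internal_c[[k]][internal_c[[k]]$patient_id %in%
                                     test_pids, ],
        external = external_c[[k]])
      art_clf <- fit(classifier_factory(config),
                     internal_c[[k]][internal_c[[k]]$patient_id %in%
                                       train_pids, ])
      purrr::imap_dfr(tests, function(co, nm) {
        p_wo <- predict_proba(clean_clf, co)
        p_wi <- predict_proba(art_clf, co)
        acc_wo <- accuracy(as.integer(p_wo >= 0.5), co$label)
        acc_wi <- accuracy(as.integer(p_wi >= 0.5), co$label)
        tibble::tibble(family = family, strength = strengths[k],
                       dataset = nm, seed_index = si,
                       acc_without = acc_wo, acc_with = acc_wi,
                       delta = delta_performance(acc_wi, acc_wo))
      })
    })
  })
  summary <- runs |>
    dplyr::group_by(.data$family, .data$dataset, .data$strength) |>
    dplyr::summarise(acc_with = mean(.data$acc_with),
                     acc_without = mean(.data$acc_without),
                     delta = mean(.data$delta),
                     n_seeds = dplyr::n(), .groups = "drop")
  new_experiment_report(runs, summary,
                        list(family = family, strengths = strengths,
                             n_seeds = n_seeds, seed = seed),
                        "artifact_experiment")
}

# ---- experiment 3: single / bagging / noisy ensemble ----------------------

#' Single model vs bagging vs NoisyEnsemble
#'
#' The ensemble-comparison protocol: per seed, train (i) a single
#' classifier on the full internal training split, (ii) a bagging
#' ensemble (member plans with zero label noise), and (iii) a
#' NoisyEnsemble (same plans plus single-class-per-patient label flips at
#' the target rate), then evaluate all three on internal and external
#' tests. Seeds are shared across modes so differences are paired.
#'
#' @inheritParams run_normalization_experiment
#' @param n_members Ensemble size (default 15).
#' @param subset_fraction Patient fraction per member (default 0.8).
#' @param target_noise_rate NoisyEnsemble label-noise target (default
#'   0.15).
#'
#' @return An `ensemble_experiment` report (`$runs`, `$summary`,
#'   `$paired` with per-seed mode differences and sign tests).
#' @export
run_ensemble_experiment <- function(internal, external,
                                    classifier_factory =
                                      reference_classifier,
                                    n_members = 15L,
                                    subset_fraction = 0.8,
                                    target_noise_rate = 0.15,
                                    n_seeds = 5L, seed = 1L,
                                    split_fractions = c(0.6, 0.2, 0.2),
                                    config = training_config()) {
  assert_disjoint_domains(internal, external)
  seeds <- experiment_seeds(n_seeds, seed)

  runs <- purrr::map_dfr(seq_along(seeds), function(si) {
    s <- seeds[si]
    sp <- patient_stratified_split(internal, stats::setNames(
      split_fractions, c("train", "val", "test")), seed = s)
    train <- internal[internal$patient_id %in%
                        unique(sp$train$patient_id), ]
    tests <- list(
      internal = internal[internal$patient_id %in%
                            unique(sp$test$patient_id), ],
      external = external)

    eval_members <- function(members) {
      purrr::imap_dfr(tests, function(co, nm) {
        probs <- purrr::map(members, function(clf) {
          predict_proba(clf, co)
        })
        agg <- aggregate_members(probs)
        tibble::tibble(dataset = nm,
                       accuracy = accuracy(agg$label, co$label))
      })
    }

    single <- fit_and_eval(classifier_factory, train, tests, config)
    single$mode <- "single"

    factory0 <- function() classifier_factory(config)
    plan_bag <- make_ensemble_plan(train, n_members, subset_fraction,
                                   target_noise_rate = 0, seed = s)
    bag <- eval_members(train_with_plan(factory0, train, plan_bag,
                                        seed = s))
    bag$mode <- "bagging"

    plan_noisy <- make_ensemble_plan(train, n_members, subset_fraction,
                                     target_noise_rate = target_noise_rate,
                                     seed = s)
    noisy <- eval_members(train_with_plan(factory0, train, plan_noisy,
                                          seed = s))
    noisy$mode <- "noisy"

    out <- dplyr::bind_rows(single, bag, noisy)
    out$seed_index <- si
    out
  })

  summary <- summarize_runs(runs, c("mode", "dataset"))
  wide <- tidyr::pivot_wider(runs, names_from = "mode",
                             values_from = "accuracy")
  paired <- wide |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      bagging_minus_single = mean(.data$bagging - .data$single),
      noisy_minus_bagging = mean(.data$noisy - .data$bagging),
      seeds_bagging_ge_single = sum(.data$bagging >= .data$single),
      seeds_noisy_ge_bagging = sum(.data$noisy >= .data$bagging),
      sign_p_noisy_vs_bagging =
        paired_sign_test(.data$noisy - .data$bagging)$p_value,
      .groups = "drop")
  rep <- new_experiment_report(runs, summary,
                               list(n_members = n_members,
                                    subset_fraction = subset_fraction,
                                    target_noise_rate = target_noise_rate,
                                    n_seeds = n_seeds, seed = seed),
                               "ensemble_experiment")
  rep$paired <- paired
  rep
}

#' Write an experiment report to JSON and CSV
#'
#' @param report A `stainshift_report`.
#' @param path_json,path_csv Output paths (`NULL` to skip one format).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path_json = NULL, path_csv = NULL) {
  stopifnot(inherits(report, "stainshift_report"))
  if (!is.null(path_json)) {
    jsonlite::write_json(list(kind = class(report)[1],
                              meta = report$meta,
                              summary = report$summary,
                              runs = report$runs,
                              paired = report$paired),
                         path_json, digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(path_csv)) readr::write_csv(report$summary, path_csv)
  invisible(report)
}
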