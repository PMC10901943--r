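#' Build one ensemble member's training plan
#'
#' A member plan is the unit of bagging and of the NoisyEnsemble method:
#' a patient subset (default: `ceiling(subset_fraction * n_patients)`
#' patients drawn without replacement) plus, when `target_noise_rate > 0`,
#' a set of label flips. Noise is structured: for each selected patient
#' exactly one class is drawn uniformly — the patient's noise group — and
#' groups are visited in random order, flipping *all* tile labels in a
#' group, stopping at the group boundary whose cumulative flipped
#' fraction is closest to the target. A group is never split, so the
#' realized rate deviates from the target by at most one group; it is
#' recorded in the plan for audit. With `target_noise_rate = 0` the plan
#' is exactly the plain bagging plan at the same seed.
#'
#' @param cohort A cohort tibble (the member's training pool).
#' @param subset_fraction Fraction of patients per member in `(0, 1]`
#'   (default 0.8).
#' @param target_noise_rate Target fraction of flipped training labels in
#'   `[0, 0.5)` (default 0.15).
#' @param seed Optional integer seed.
#' @param replace Draw the patient subset with replacement (classical
#'   bootstrap) instead of without (default `FALSE`; duplicates are
#'   collapsed, so `replace = TRUE` yields smaller effective subsets).
#' @param member_index Index recorded in the plan.
#'
#' @return An object of class `member_plan`: `member_index`,
#'   `patient_subset`, `noise_groups` (tibble of `patient_id`,
#'   `noised_class`), `flipped_tiles` (tile ids), `n_train`,
#'   `realized_noise_rate`.
#' @export
make_member_plan <- function(cohort, subset_fraction = 0.8,
                             target_noise_rate = 0.15, seed = NULL,
                             replace = FALSE, member_index = 1L) {
  check_cohort(cohort)
  stopifnot(subset_fraction > 0, subset_fraction <= 1,
            target_noise_rate >= 0, target_noise_rate < 0.5)
  run <- function() {
    patients <- unique(cohort$patient_id)
    n_sel <- ceiling(subset_fraction * length(patients))
    subset <- if (replace) {
      unique(sample(patients, n_sel, replace = TRUE))
    } else {
      sample(patients, n_sel)
    }
    member <- cohort[cohort$patient_id %in% subset, ]
    n_train <- nrow(member)

    if (target_noise_rate == 0) {
      return(structure(list(
        member_index = as.integer(member_index),
        patient_subset = sort(subset),
        noise_groups = tibble::tibble(patient_id = character(),
                                      noised_class = integer()),
        flipped_tiles = character(),
        n_train = n_train,
        realized_noise_rate = 0
      ), class = "member_plan"))
    }

    noised_class <- sample(c(0L, 1L), length(subset), replace = TRUE)
    groups <- tibble::tibble(patient_id = subset,
                             noised_class = noised_class)
    group_tiles <- purrr::map(seq_len(nrow(groups)), function(g) {
      member$tile_id[member$patient_id == groups$patient_id[g] &
                       member$label == groups$noised_class[g]]
    })
    order_idx <- sample.int(nrow(groups))
    sizes <- purrr::map_int(group_tiles, length)[order_idx]
    target_count <- target_noise_rate * n_train
    cum <- cumsum(sizes)
    dist <- abs(c(0, cum) - target_count)   # prefix of 0..n groups
    k <- which.min(dist) - 1L
    if (min(dist) > 2 * max(sizes, 1)) {
      stop(sprintf(paste0(
        "noise target %.2f unreachable: best achievable flipped count ",
        "differs from target %.1f by %.1f (> 2x the largest group)."),
        target_noise_rate, target_count, min(dist)), call. = FALSE)
    }
    chosen <- order_idx[seq_len(k)]
    flipped <- unlist(group_tiles[chosen], use.names = FALSE)
    structure(list(
      member_index = as.integer(member_index),
      patient_subset = sort(subset),
      noise_groups = groups[sort(chosen), ],
      flipped_tiles = flipped,
      n_train = n_train,
      realized_noise_rate = length(flipped) / n_train
    ), class = "member_plan")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' @export
print.member_plan <- function(x, ...) {
  cat(sprintf(paste0("<member_plan #%d: %d patients, %d training tiles, ",
                     "%d flips (realized noise %.3f)>\n"),
              x$member_index, length(x$patient_subset), x$n_train,
              length(x$flipped_tiles), x$realized_noise_rate))
  invisible(x)
}

#' Build a full ensemble training plan
#'
#' Draws `n_members` member plans (default 15, the usual bagging ensemble
#' size) from independent seed-derived streams, so the whole plan is
#' reproducible from a single seed. `target_noise_rate = 0` gives the
#' plain bagging plan; the default 0.15 gives the NoisyEnsemble plan with
#' 15 % of training labels flipped.
#'
#' @inheritParams make_member_plan
#' @param n_members Number of ensemble members (>= 1).
#' @param seed Integer seed (required: the plan is a reproducibility
#'   artifact).
#'
#' @return An object of class `ensemble_plan` with fields `members` (list
#'   of [make_member_plan()] results), `target_noise_rate`,
#'   `subset_fraction`, `seed`.
#' @examples
#' co <- generate_cohort(6, 4, seed = 1)
#' plan <- make_ensemble_plan(co, n_members = 3, seed = 7)
#' plan$members[[1]]
#' @export
make_ensemble_plan <- function(cohort, n_members = 15L,
                               subset_fraction = 0.8,
                               target_noise_rate = 0.15,
                               seed = 1L, replace = FALSE) {
  stopifnot(n_members >= 1)
  member_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_members))
  members <- purrr::map(seq_len(n_members), function(m) {
    make_member_plan(cohort, subset_fraction, target_noise_rate,
                     seed = member_seeds[m], replace = replace,
                     member_index = m)
  })
  structure(list(members = members,
                 n_members = as.integer(n_members),
                 subset_fraction = subset_fraction,
                 target_noise_rate = target_noise_rate,
                 seed = as.integer(seed)),
            class = "ensemble_plan")
}

#' @export
print.ensemble_plan <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_plan: %d members, subset fraction %.2f, ",
                     "target noise %.2f, seed %d>\n"),
              x$n_members, x$subset_fraction, x$target_noise_rate, x$seed))
  cat(sprintf("mean realized noise rate: %.3f\n",
              mean(purrr::map_dbl(x$members, "realized_noise_rate"))))
  invisible(x)
}

#' Materialize a member's training cohort
#'
#' Restricts the cohort to the plan's patient subset and inverts the
#' labels of the plan's flipped tiles (0 <-> 1). The input cohort is
#' untouched; applying the same plan to an already-applied cohort
#' restores the original labels (flipping is an involution).
#'
#' @param cohort A cohort tibble.
#' @param plan A `member_plan`.
#'
#' @return The member's training cohort tibble.
#' @export
apply_member_plan <- function(cohort, plan) {
  check_cohort(cohort)
  if (!inherits(plan, "member_plan")) {
    stop("`plan` must be a member_plan.", call. = FALSE)
  }
  unknown <- setdiff(plan$patient_subset, unique(cohort$patient_id))
  if (length(unknown) > 0) {
    stop(sprintf("plan references patient(s) absent from cohort: %s.",
                 paste(utils::head(unknown, 3), collapse = ", ")),
         call. = FALSE)
  }
  out <- cohort[cohort$patient_id %in% plan$patient_subset, ]
  flip <- out$tile_id %in% plan$flipped_tiles
  out$label[flip] <- 1L - out$label[flip]
  out
}

#' Aggregate ensemble member predictions
#'
#' Unweighted mean of the members' per-tile class-1 probabilities (the
#' standard bagging aggregation), with the hard label 1 iff the mean
#' probability is at least 0.5 (ties go to class 1). A majority vote over
#' the members' hard labels is available as an option.
#'
#' @param member_probs List (or matrix, members in rows) of per-tile
#'   class-1 probability vectors, all the same length, values in
#'   `[0, 1]`.
#' @param method `"mean"` (default) or `"vote"`.
#'
#' @return A tibble with columns `prob` (aggregated probability) and
#'   `label` (hard 0/1 call).
#' @examples
#' aggregate_members(list(c(0.2, 0.9), c(0.6, 0.8), c(1.0, 0.1)))
#' @export
aggregate_members <- function(member_probs, method = c("mean", "vote")) {
  method <- match.arg(method)
  if (is.matrix(member_probs)) {
    member_probs <- asplit(member_probs, 1)
  }
  if (length(member_probs) < 1) {
    stop("need at least one member.", call. = FALSE)
  }
  lens <- purrr::map_int(member_probs, length)
  if (length(unique(lens)) != 1L) {
    stop("member probability vectors differ in length.", call. = FALSE)
  }
  P <- do.call(rbind, lapply(member_probs, as.numeric))
  if (anyNA(P) || min(P) < 0 || max(P) > 1) {
    stop("probabilities must lie in [0, 1].", call. = FALSE)
  }
  prob <- colMeans(P)
  label <- if (method == "mean") {
    as.integer(prob >= 0.5)
  } else {
    as.integer(colMeans(P >= 0.5) >= 0.5)
  }
  tibble::tibble(prob = prob, label = label)
}

#' Serialize and restore ensemble plans as JSON
#'
#' The full plan (seeds, subsets, noise groups, flipped tile references)
#' is written so a training run is reproducible and auditable.
#'
#' @param plan An `ensemble_plan`.
#' @param path JSON file path.
#' @return `write_ensemble_plan()` returns `path` invisibly;
#'   `read_ensemble_plan()` returns an `ensemble_plan`.
#' @export
write_ensemble_plan <- function(plan, path) {
  stopifnot(inherits(plan, "ensemble_plan"))
  jsonlite::write_json(list(
    n_members = plan$n_members,
    subset_fraction = plan$subset_fraction,
    target_noise_rate = plan$target_noise_rate,
    seed = plan$seed,
    members = purrr::map(plan$members, function(m) list(
      member_index = m$member_index,
      patient_subset = m$patient_subset,
      noise_groups = m$noise_groups,
      flipped_tiles = m$flipped_tiles,
      n_train = m$n_train,
      realized_noise_rate = m$realized_noise_rate
    ))
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ensemble_plan
#' @export
read_ensemble_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- purrr::map(seq_len(x$n_members), function(i) {
    m <- if (is.data.frame(x$members)) as.list(x$members[i, ]) else x$members[[i]]
    ng <- m$noise_groups
    if (is.list(ng) && !is.data.frame(ng)) ng <- as.data.frame(ng)
    if (length(ng) == 0 || nrow(as.data.frame(ng)) == 0) {
      ng <- tibble::tibble(patient_id = character(), noised_class = integer())
    }
    structure(list(
      member_index = as.integer(m$member_index),
      patient_subset = unlist(m$patient_subset),
      noise_groups = tibble::as_tibble(ng),
      flipped_tiles = as.character(unlist(m$flipped_tiles)),
      n_train = as.integer(m$n_train),
      realized_noise_rate = as.numeric(m$realized_noise_rate)
    ), class = "member_plan")
  })
  structure(list(members = members,
                 n_members = as.integer(x$n_members),
                 subset_fraction = x$subset_fraction,
                 target_noise_rate = x$target_noise_rate,
                 seed = as.integer(x$seed)),
            class = "ensemble_plan")
}
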