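#' Cohort tibbles
#'
#' A cohort is a tibble with one row per tile and columns `tile_id`
#' (unique reference), `patient_id`, `case_id` (slide of origin), `label`
#' (binary 0/1) and `domain` (institute tag), plus either a `tile`
#' list-column of in-memory [rgb_tile()]s or a `tile_path` column of file
#' paths (or both). All stainshift operations accept and return plain
#' tibbles so cohorts compose with dplyr verbs.
#'
#' @param x A data frame with the columns above.
#' @return `as_cohort()` returns the validated tibble; `check_cohort()`
#'   is called for its side effect and returns the input invisibly.
#' @export
as_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  check_cohort(x)
  x
}

#' @rdname as_cohort
#' @export
check_cohort <- function(x) {
  required <- c("tile_id", "patient_id", "case_id", "label", "domain")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(sprintf("cohort is missing column(s): %s.",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!any(c("tile", "tile_path") %in% names(x))) {
    stop("cohort needs a `tile` list-column or a `tile_path` column.",
         call. = FALSE)
  }
  if (nrow(x) == 0) stop("cohort is empty.", call. = FALSE)
  if (any(is.na(x$patient_id)) || any(!nzchar(x$patient_id))) {
    stop("patient_id must be nonempty for every tile.", call. = FALSE)
  }
  bad <- which(!(x$label %in% c(0L, 1L)))
  if (length(bad) > 0) {
    stop(sprintf("labels must be binary 0/1; offending row(s): %s.",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$tile_id)) {
    dup <- x$tile_id[duplicated(x$tile_id)][1]
    stop(sprintf("duplicate tile reference: '%s'.", dup), call. = FALSE)
  }
  invisible(x)
}

#' Read and write cohort manifests
#'
#' The manifest is a CSV with header columns `tile_path`, `patient_id`,
#' `label`, `domain`, `case_id` (plus an optional `split` column written
#' back by splitting). Labels must parse as binary integers; a
#' schema/value violation errors with the offending column or row.
#'
#' @param path Manifest CSV path.
#' @return A cohort tibble (the `tile_id` is the tile path).
#' @export
load_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  required <- c("tile_path", "patient_id", "label", "domain", "case_id")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop(sprintf("manifest is missing column(s): %s.",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lab <- suppressWarnings(as.integer(m$label))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad) > 0) {
    stop(sprintf("manifest label must be 0 or 1; got '%s' at row %d.",
                 m$label[bad[1]], bad[1]), call. = FALSE)
  }
  m$label <- lab
  m$patient_id <- as.character(m$patient_id)
  m$case_id <- as.character(m$case_id)
  m$domain <- as.character(m$domain)
  if (anyDuplicated(m$tile_path)) {
    dup <- m$tile_path[duplicated(m$tile_path)][1]
    stop(sprintf("duplicated tile_path in manifest: '%s'.", dup),
         call. = FALSE)
  }
  m$tile_id <- m$tile_path
  as_cohort(m)
}

#' @rdname load_manifest
#' @param cohort A cohort tibble; in-memory `tile` columns are dropped on
#'   write (only path-backed cohorts round-trip through CSV).
#' @export
write_manifest <- function(cohort, path) {
  check_cohort(cohort)
  cols <- intersect(c("tile_path", "patient_id", "label", "domain",
                      "case_id", "split"), names(cohort))
  if (!"tile_path" %in% cols) {
    stop("cohort has no `tile_path` column; write tiles to disk first.",
         call. = FALSE)
  }
  readr::write_csv(cohort[cols], path)
  invisible(path)
}

#' Patient-stratified train/validation/test split
#'
#' Partitions a cohort at the patient level: all tiles of a patient land
#' in exactly one split, so no patient leaks between training and test.
#' Patient counts follow `fractions` by largest remainder; the draw is
#' redone (up to `max_retries`) until every split's class balance is
#' within `balance_tol` of the whole cohort's, which keeps small cohorts
#' usable.
#'
#' @param cohort A cohort tibble.
#' @param fractions Positive length-3 `(train, val, test)` fractions
#'   summing to 1.
#' @param seed Optional integer seed.
#' @param balance_tol Maximum allowed absolute deviation of each split's
#'   class-1 tile fraction from the cohort's (default 0.1).
#' @param max_retries Redraw cap before the best draw so far is returned
#'   with a warning.
#'
#' @return A named list of three cohort tibbles (`train`, `val`, `test`),
#'   each with a `split` column added.
#' @export
patient_stratified_split <- function(cohort,
                                     fractions = c(train = 0.6, val = 0.2,
                                                   test = 0.2),
                                     seed = NULL,
                                     balance_tol = 0.1,
                                     max_retries = 25L) {
  check_cohort(cohort)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be 3 positive values summing to 1.",
         call. = FALSE)
  }
  pd <- dplyr::distinct(cohort, .data$patient_id, .data$domain)
  if (anyDuplicated(pd$patient_id) > 0) {
    stop("a patient has tiles in multiple domains; split is ambiguous.",
         call. = FALSE)
  }
  patients <- unique(cohort$patient_id)
  n <- length(patients)
  if (n < 3L) stop("fewer patients than splits.", call. = FALSE)
  counts <- largest_remainder(fractions, n)
  overall <- mean(cohort$label == 1L)

  draw_once <- function() {
    perm <- sample(patients)
    assign <- rep(c("train", "val", "test"), counts)
    split(perm, factor(assign, levels = c("train", "val", "test")))
  }
  one_attempt <- function() {
    parts <- draw_once()
    splits <- purrr::imap(parts, function(pids, nm) {
      out <- dplyr::filter(cohort, .data$patient_id %in% pids)
      out$split <- nm
      out
    })
    dev <- max(purrr::map_dbl(splits, function(s) {
      if (nrow(s) == 0) return(Inf)
      abs(mean(s$label == 1L) - overall)
    }))
    list(splits = splits, dev = dev)
  }
  run <- function() {
    best <- NULL
    for (i in seq_len(max_retries)) {
      att <- one_attempt()
      if (is.null(best) || att$dev < best$dev) best <- att
      if (att$dev <= balance_tol) return(att$splits)
    }
    warning(sprintf(paste0(
      "class balance tolerance %.2f not met after %d redraws; ",
      "returning the best draw (deviation %.3f)."),
      balance_tol, max_retries, best$dev), call. = FALSE)
    best$splits
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Sample a fixed number of tiles per case and class
#'
#' For every (case, class) pair, uniformly samples without replacement
#' `min(n_per_class, available)` tiles — the standard per-slide sampling
#' that caps each case's contribution (e.g. 80 tiles per class per slide
#' in typical tile-classification studies).
#'
#' @param cohort A cohort tibble.
#' @param n_per_class Tiles to keep per case and class (>= 1).
#' @param seed Optional integer seed.
#'
#' @return The subsampled cohort tibble.
#' @export
sample_tiles_per_case <- function(cohort, n_per_class, seed = NULL) {
  check_cohort(cohort)
  stopifnot(n_per_class >= 1)
  run <- function() {
    cohort |>
      dplyr::group_by(.data$case_id, .data$label) |>
      dplyr::slice_sample(n = n_per_class) |>
      dplyr::ungroup()
  }
  out <- if (is.null(seed)) run() else with_local_seed(seed, run())
  out[order(match(out$tile_id, cohort$tile_id)), ]
}

# Materialize the pixel data of one cohort row.
cohort_tile <- function(cohort, i) {
  if ("tile" %in% names(cohort) && !is.null(cohort$tile[[i]])) {
    return(cohort$tile[[i]])
  }
  read_tile(cohort$tile_path[i])
}

# Apply a tile -> tile function to every tile, returning an in-memory
# cohort. Used by normalization and artifact pipelines.
map_cohort_tiles <- function(cohort, f) {
  check_cohort(cohort)
  tiles <- purrr::map(seq_len(nrow(cohort)), function(i) {
    f(cohort_tile(cohort, i))
  })
  out <- cohort
  out$tile <- tiles
  out
}
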