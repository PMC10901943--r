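# Shared in-code fixtures. Everything is generated at test time; nothing
# is read from disk.

# Pixel-free cohort for planner/split logic: tiles are dummy path refs.
flat_cohort <- function(n_patients = 20, tiles_per_class = 10,
                        domains = "A", one_class_patients = FALSE) {
  rows <- lapply(seq_len(n_patients), function(p) {
    dom <- domains[((p - 1) %% length(domains)) + 1]
    pid <- sprintf("%s_p%02d", dom, p)
    labs <- if (one_class_patients) rep(p %% 2, 2 * tiles_per_class) else {
      rep(c(0L, 1L), each = tiles_per_class)
    }
    tibble::tibble(
      tile_id = sprintf("%s_t%03d", pid, seq_along(labs)),
      tile_path = sprintf("%s_t%03d.png", pid, seq_along(labs)),
      patient_id = pid, case_id = pid,
      label = as.integer(labs), domain = dom
    )
  })
  as_cohort(dplyr::bind_rows(rows))
}

# Small single-domain image cohort, built once per test run.
local_image_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- generate_cohort(8, 3, styles = default_domain_styles()["A"],
                               size = 64, seed = 101)
    }
    memo
  }
})

# Quick training config for smoke-scale experiment tests.
fast_config <- function() training_config(epochs = 5, steps_per_epoch = 40)

# Noiseless flat-color test tile.
flat_tile <- function(r, g, b, n = 16) {
  rgb_tile(array(rep(c(r, g, b), each = n * n), dim = c(n, n, 3)))
}
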