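# Shared fixtures: small fast fields for unit tests.

tiny_config <- function(n_cells = 30, seed = 7, ...) {
  sim_config(n_cells = n_cells, seed = seed,
             field_shape = c(300L, 300L), ...)
}

# Switch off every stochastic imaging stage: the rendered images are then
# exactly the piecewise-constant scenes.
noise_free <- function(cfg) {
  cfg$noise <- list(background = 0, gradient = 0, read_sd = 0, shot = FALSE)
  cfg$bleach_carryover <- 0
  cfg$shift_px_sd <- 0
  cfg$reseal_fail_prob <- 0
  validate_sim_config(cfg)
}

# Ground-truth index matched to each measured cell by nearest centroid.
match_truth <- function(cells, truth) {
  vapply(seq_len(nrow(cells)), function(i)
    which.min((truth$row - cells$row[i])^2 +
                (truth$col - cells$col[i])^2), 1L)
}

# Minimal image_set wrapper around plain matrices for measurement tests.
fake_image_set <- function(channels, nuclear = "dapi") {
  structure(list(rounds = list(list(channels = channels,
                                    true_shift = c(0, 0))),
                 pixel_um = 1, nuclear_channel = nuclear,
                 field_id = "fake", seed = 0L),
            class = "image_set")
}
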