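# Shared fixtures: compact generator configurations used across tests.
# Sizes are chosen so each synthetic session runs in well under a second
# while preserving the task structure (four-image lists, both phases,
# all three conditions).

tiny_config <- function(...) {
  sim_config(n_lists = 2, n_channels = c(PT = 2, MTL = 2),
             encoding_dur = 2, ...)
}

two_region_config <- function(...) {
  # lag-recovery testbed: two regions, no condition effect or alpha
  # coupling so the only inter-regional structure is the envelope lag
  sim_config(n_lists = 8, n_channels = c(PT = 3, MTL = 3),
             effect_amp = 0, alpha_amp = 0, ...)
}

# One-channel recording with pure pink noise (no injections), for artifact
# and filtering tests.
noise_recording <- function(n_s = 30, fs = 1000, seed = 1) {
  set.seed(seed)
  traces <- matrix(pink_noise(n_s * fs) * 10, ncol = 1)
  meta <- data.frame(label = "PT1", region = "PT", grid_id = "s", grid_row = 1L,
                     grid_col = 1L, is_depth = FALSE)
  new_recording(traces, fs, meta, session_id = "noise")
}

# Grid metadata for montage tests.
grid_meta <- function(nrow_g, ncol_g, region = "PT", grid_id = "g1") {
  idx <- expand.grid(grid_row = seq_len(nrow_g), grid_col = seq_len(ncol_g))
  data.frame(label = sprintf("%s_%d_%d", grid_id, idx$grid_row, idx$grid_col),
             region = region, grid_id = grid_id,
             grid_row = idx$grid_row, grid_col = idx$grid_col,
             is_depth = FALSE)
}
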