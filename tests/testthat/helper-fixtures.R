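# Shared fixtures, created lazily and cached for the whole test run.
# Three scales are used:
#   gt_full : the paper-scale default dataset (60 x 1000 x 173) - generated
#             once, used by the acceptance criteria on epoch geometry/GMFA.
#   gt_small: 60 x 200 x 30 at 1000 Hz - module-level cleaning tests.
#   gt_tiny : 60 x 100 x 20 at 500 Hz  - the 121-condition ordering grid.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, create) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- create()
  .fixtures[[name]]
}

gt_full <- function() fixture("gt_full", function()
  generate_ground_truth(ground_truth_config()))

gt_small_config <- function() ground_truth_config(n_trials = 30, fs = 1000,
                                                  seed = 7)

gt_small <- function() fixture("gt_small", function()
  generate_ground_truth(gt_small_config()))

gt_tiny <- function() fixture("gt_tiny", function()
  generate_ground_truth(ground_truth_config(n_trials = 20, fs = 500,
                                            seed = 11)))

# artifact realization matched to an epoched dataset's geometry
artifact_for <- function(gt, alpha, contrast, amplitude_uv = 250,
                         source_index = 1, seed = 1L) {
  simulate_artifact(alpha, contrast, amplitude_uv, source_index,
                    n_trials = dim(gt$data)[3], fs = gt$fs,
                    t_start_ms = gt$times[1],
                    t_end_ms = gt$times[1] +
                      dim(gt$data)[2] * 1000 / gt$fs,
                    seed = seed)
}

# dense full-sphere "montage" for spatial-frequency measurements
dense_montage <- function(n = 400) fixture("dense_montage", function() {
  P <- fibonacci_sphere_points(n)
  m <- data.frame(label = paste0("d", seq_len(nrow(P))),
                  x = P[, 1], y = P[, 2], z = P[, 3])
  class(m) <- c("eeg_montage", "data.frame")
  m
})
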