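# Small configurations used across the suite: behavioral-only datasets are
# cheap; BOLD datasets use reduced regions/voxel counts where the check does
# not depend on them.

small_cfg <- function(seed = 1, ...) {
  args <- list(
    n_participants = 6L, n_trs = 400L,
    n_intervals_2min = 12L, n_intervals_6min = 6L,
    roi_specs = tibble::tibble(
      label = c("drift", "null", "wm", "csf"),
      n_voxels = c(30L, 30L, 20L, 20L),
      drift_rate = c(1, 0, 0, 0),
      noise_sd = 1,
      compartment = c("grey", "grey", "white", "csf")
    ),
    seed = seed
  )
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# deterministic reports table built by hand (no RNG)
toy_reports <- function(n_participants = 4, n_intervals = 6,
                        fn = function(p, i) 100 + 10 * p + 5 * i) {
  tidyr::crossing(participant_id = seq_len(n_participants),
                  interval_id = seq_len(n_intervals)) |>
    dplyr::mutate(estimate_s = mapply(fn, participant_id, interval_id))
}

# schedule with evenly spaced 2-min intervals, fixed clip length
toy_schedule <- function(n_intervals = 6, gap_s = 120, tr = 1.5,
                         duration_s = 6, spacing_s = 30, start_s = 12) {
  mid_a <- start_s + spacing_s * (seq_len(n_intervals) - 1)
  mid_b <- mid_a + gap_s
  clips <- tibble::tibble(
    clip_id = seq_len(2 * n_intervals),
    onset_s = c(mid_a, mid_b)[order(c(mid_a, mid_b))] - duration_s / 2,
    duration_s = duration_s
  )
  ord <- order(c(mid_a, mid_b))
  pos_of <- match(seq_len(2 * n_intervals), ord)
  intervals <- tibble::tibble(
    interval_id = seq_len(n_intervals),
    clip_a = pos_of[seq_len(n_intervals)],
    clip_b = pos_of[n_intervals + seq_len(n_intervals)],
    true_gap_s = gap_s,
    position_s = (mid_a + mid_b) / 2
  )
  n_trs <- as.integer(ceiling((max(mid_b) + 60) / tr))
  structure(list(clips = clips, intervals = intervals, tr_seconds = tr,
                 n_trs = n_trs), class = "clip_schedule")
}
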