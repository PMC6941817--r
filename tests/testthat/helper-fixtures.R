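# Shared fixtures, built once per test session and memoized. All datasets
# are generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# short fast-worm video for module tests (48 frames); the higher speed keeps
# every pixel worm-free often enough for background estimation despite the
# short duration (a default-speed worm needs ~10 s of video for that)
tiny_dataset <- function() {
  memo("tiny", generate_dataset(worm_kinematics(duration = 4, speed = 450,
                                                seed = 11L)))
}

tiny_track <- function() {
  memo("tiny_track", track_video(tiny_dataset()))
}

# straight worm translating head-first, no noise sources (oracle conditions)
straight_kin <- function(duration = 12, speed = 130, seed = 21L) {
  worm_kinematics(undulation_amplitude = 0, head_jitter_std = 0,
                  heading_drift_std = 0, undulation_frequency = 0,
                  duration = duration, speed = speed, seed = seed)
}

straight_dataset <- function() {
  memo("straight", generate_dataset(straight_kin()))
}

# one full-length default video + track, shared across deeper tests
default_dataset <- function() {
  memo("default", generate_dataset(worm_kinematics(seed = 3L)))
}

default_track <- function() {
  memo("default_track", track_video(default_dataset()))
}

# fleet of eight seeded default videos (frames dropped after tracking);
# backbone of the acceptance-level property checks
fleet <- function(n = 8L) {
  memo("fleet", lapply(seq_len(n), function(sd) {
    ds <- generate_dataset(worm_kinematics(seed = sd))
    tr <- track_video(ds)
    ds$frames <- NULL
    ds$background <- NULL
    list(dataset = ds, track = tr)
  }))
}

fleet_datasets <- function() lapply(fleet(), `[[`, "dataset")
fleet_tracks <- function() lapply(fleet(), `[[`, "track")

# 4-slice x 10-horizon x 2-mode paradigm grid over the fleet
fleet_grid <- function() {
  memo("fleet_grid",
       simulation_horizon(fleet_datasets(), fleet_tracks(),
                          s_values = c(0.1, 0.3, 0.5, 0.9), horizons = 1:10))
}

# single-slice horizon sweep (s = 0.52) over the fleet
fleet_h52 <- function() {
  memo("fleet_h52",
       simulation_horizon(fleet_datasets(), fleet_tracks(),
                          s_values = 0.52, horizons = 1:10))
}

# direct double-sum evaluation of the centered 2-D DFT (independent oracle
# for the encoding contract; no fft call)
brute_dft <- function(img) {
  N <- nrow(img)
  idx <- (seq_len(N) - 1) - N / 2
  W <- exp(-2i * pi * (idx %o% idx) / N)
  W %*% img %*% t(W)
}
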