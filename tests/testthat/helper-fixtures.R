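# Shared fixtures for the test-suite: everything is built in code.

# geometry with round numbers: 38.4 px/cm at 60 cm, stimulus == screen
test_geometry <- function() {
  screen_geometry(screen_w_px = 1920, screen_h_px = 1080, screen_w_cm = 50,
                  viewing_distance_cm = 60, stimulus_w_px = 1920,
                  stimulus_h_px = 1080)
}

# regular 60 Hz sample stream at a fixed position (exact sample count)
stationary_stream <- function(t0_ms, duration_ms, x, y, rate_hz = 60) {
  n <- round(duration_ms * rate_hz / 1000)
  ts <- t0_ms + (seq_len(n) - 1) * 1000 / rate_hz
  data.frame(t_ms = ts, x_px = x, y_px = y, valid = TRUE)
}

small_fix <- function(start_ms, end_ms, cx, cy, n_samples = 2) {
  data.frame(start_ms = start_ms, end_ms = end_ms,
             duration_ms = end_ms - start_ms, cx_px = cx, cy_px = cy,
             n_samples = n_samples)
}

# cohort used by several classifier tests: planted, perfectly separable
planted_features <- function(n_per_class = 6, C = 4, offset = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * C), 2 * n_per_class, C)
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] + offset
  list(X = X, labels = rep(c("ASD", "TD"), each = n_per_class))
}
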