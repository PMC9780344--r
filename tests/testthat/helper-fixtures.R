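# Shared fixture builders. Everything is generated in code at test time.

fs_std <- 250
n_samp_std <- 751   # -1000..2000 ms at 250 Hz
onset_std <- 251

std_times <- function(n = n_samp_std, onset = onset_std, fs = fs_std) {
  (seq_len(n) - onset) * 1000 / fs
}

# epoch set with constant voltage everywhere
const_epochs <- function(value = 0, n_tr = 1,
                         channels = c("POz", "VEOG", "HEOG"),
                         n = n_samp_std) {
  epoch_set(array(value, c(n_tr, length(channels), n)), fs_std, onset_std,
            channels, blank_trials(n_tr))
}

# epoch set from a trials x samples matrix replicated over channels
epochs_from_traces <- function(traces, channels = c("POz", "VEOG", "HEOG")) {
  n_tr <- nrow(traces)
  dat <- array(0, c(n_tr, length(channels), ncol(traces)))
  for (c in seq_along(channels)) dat[, c, ] <- traces
  epoch_set(dat, fs_std, onset_std, channels, blank_trials(n_tr))
}

# 10 Hz cosine with phase phi at -250 ms (the generator/spectral convention)
alpha_trace <- function(phi, amp = 1, f0 = 10, t_ms = std_times()) {
  amp * cos(2 * pi * f0 * (t_ms + 250) / 1000 + phi)
}

# feature-level simulator: draws trial features straight from the structural
# generative model (no waveforms), for fast model-layer tests
make_features <- function(n_participants, n_per, b1 = 0, c_cos = 0,
                          c_sin = 0, c3 = 0, c4 = 0, resid_sd = 1,
                          a1 = 0, a2 = 0, b0 = -0.3, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_participants), function(p) {
      power_z <- as.vector(scale(rnorm(n_per)))
      phase <- runif(n_per, -pi, pi)
      van_raw <- b1 * power_z + (c_cos + c3 * power_z) * cos(phase) +
        (c_sin + c4 * power_z) * sin(phase) + rnorm(n_per, sd = resid_sd)
      van_z <- as.vector(scale(van_raw))
      pr <- plogis(b0 + a1 * power_z + a2 * van_z)
      tibble::tibble(
        participant = sprintf("s%02d", p),
        trial = seq_len(n_per) + p * 10000L,
        power = power_z, power_z = power_z, phase = phase,
        van = van_raw, van_z = van_z,
        perceived = rbinom(n_per, 1, pr),
        cue_field = sample(c("upper", "lower"), n_per, TRUE),
        cue_side = sample(c("left", "right"), n_per, TRUE)
      )
    }) |> tercile_split()
  })
}

# tiny low-noise simulation config for deterministic-ish end-to-end checks
quiet_config <- function(...) {
  sim_config(noise = list(pink_rms = 1e-6, white_rms = 1e-6),
             artifacts = list(blink_prob = 0), ...)
}
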