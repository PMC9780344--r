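# Synthetic single-trial EEG with known ground-truth coupling between
# prestimulus alpha power/phase, VAN-window amplitude and perception.
# Every analysis stage downstream is validated by recovering these truths.

ag_roi_channels <- c("POz", "PO3", "PO4", "PO7", "PO8", "Oz", "O1", "O2",
                     "P3", "P4")
ag_all_channels <- c(ag_roi_channels, "CPz", "FCz", "VEOG", "HEOG")

default_gain_map <- function() {
  g <- c(stats::setNames(rep(1, length(ag_roi_channels)), ag_roi_channels),
         CPz = 0.4, FCz = 0.1, VEOG = 0, HEOG = 0)
  g[ag_all_channels]
}

default_van_map <- function() {
  v <- c(stats::setNames(rep(1, length(ag_roi_channels)), ag_roi_channels),
         CPz = 0.2, FCz = -0.4, VEOG = 0, HEOG = 0)
  v[ag_all_channels]
}

#' Simulation configuration
#'
#' Parameters of the synthetic EEG generator. Defaults describe the emulated
#' study conditions: 20 participants, 750 trials each (20% cue-absent, so 600
#' cue-present), 250 Hz sampling over -1000..2000 ms, posterior-weighted 10 Hz
#' alpha with lognormal amplitude (median 5 uV, sdlog 0.4) and uniform phase,
#' 1/f plus white noise, a +3 uV P1 at 120 ms, and a VAN-like negativity at
#' 200 ms whose single-trial amplitude is
#' `v_base + v_pow * Pz + v_phase * gate(Pz) * cos(phase - phi_pref)`,
#' where `Pz` is the participant-wise z-score of log alpha power and the gate
#' is a logistic function of `Pz` (phase effects expressed mainly at high
#' power). Perception follows a logistic model driven by the (sign-flipped)
#' VAN z-score, with a 7% wrong-side lapse rate among perceived cues.
#'
#' @param n_participants,trials_per_participant cohort size.
#' @param fs sampling rate (Hz).
#' @param epoch_span_ms epoch limits in ms relative to cue onset.
#' @param cue_absent_frac fraction of trials without a cue.
#' @param alpha list: `f0` (Hz), `mu_log_amp`/`sd_log_amp` (lognormal
#'   amplitude, uV), `gain` (named per-channel gain map).
#' @param noise list: `pink_exponent`, `pink_rms`, `white_rms` (uV).
#' @param evoked list: `p1_amp`, `p1_latency`, `p1_width`, `van_latency`,
#'   `van_width` (uV / ms), `van_map` (named spatial map), `v_base`, `v_pow`,
#'   `v_phase` (uV), `phi_pref_deg` (degrees), `gate_slope`, `gate_mid`.
#' @param behavior list: logistic coefficients `b0`, `b_van`, `b_pow`,
#'   `b_phase` and wrong-side lapse rate `wrong_side_rate`.
#' @param artifacts list: `blink_prob` per trial and `blink_amp` (uV, VEOG).
#' @param topography_mode `"parietal"` (VAN map identical for upper- and
#'   lower-field cues) or `"calcarine"` (posterior ROI entries of the VAN map
#'   flip sign for upper-field cues, emulating a source on the calcarine
#'   banks).
#' @param seed integer RNG seed; identical (config, seed) gives bit-identical
#'   output.
#' @return a `sim_config` list.
#' @seealso [sim_preset()], [simulate_dataset()]
#' @export
sim_config <- function(n_participants = 20,
                       trials_per_participant = 750,
                       fs = 250,
                       epoch_span_ms = c(-1000, 2000),
                       cue_absent_frac = 0.20,
                       alpha = list(),
                       noise = list(),
                       evoked = list(),
                       behavior = list(),
                       artifacts = list(),
                       topography_mode = c("parietal", "calcarine"),
                       seed = 1L) {
  cfg <- list(
    n_participants = n_participants,
    trials_per_participant = trials_per_participant,
    fs = fs,
    epoch_span_ms = epoch_span_ms,
    cue_absent_frac = cue_absent_frac,
    alpha = utils::modifyList(list(
      f0 = 10, mu_log_amp = log(5), sd_log_amp = 0.4,
      gain = default_gain_map()
    ), alpha),
    noise = utils::modifyList(list(
      pink_exponent = 1, pink_rms = 3, white_rms = 1
    ), noise),
    evoked = utils::modifyList(list(
      p1_amp = 3, p1_latency = 120, p1_width = 25,
      van_latency = 200, van_width = 35, van_map = default_van_map(),
      v_base = -2, v_pow = 0.8, v_phase = -1.5, phi_pref_deg = 70,
      gate_slope = 2, gate_mid = 0
    ), evoked),
    behavior = utils::modifyList(list(
      b0 = -0.3, b_van = 0.8, b_pow = 0, b_phase = 0, wrong_side_rate = 0.07
    ), behavior),
    artifacts = utils::modifyList(list(
      blink_prob = 0.05, blink_amp = 80
    ), artifacts),
    topography_mode = match.arg(topography_mode),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$cue_absent_frac, cfg$behavior$wrong_side_rate,
             cfg$artifacts$blink_prob)
  if (any(probs < 0 | probs > 1)) stop_ag("probabilities must lie in [0, 1]")
  pos <- c(cfg$alpha$sd_log_amp, cfg$noise$pink_rms, cfg$noise$white_rms,
           cfg$evoked$p1_width, cfg$evoked$van_width, cfg$fs)
  if (any(pos <= 0)) stop_ag("widths, RMS values and fs must be positive")
  if (cfg$n_participants < 1 || cfg$trials_per_participant < 1) {
    stop_ag("need at least one participant and one trial")
  }
  for (m in c("gain", "van_map")) {
    map <- if (m == "gain") cfg$alpha$gain else cfg$evoked$van_map
    if (!all(ag_all_channels %in% names(map))) {
      stop_ag(sprintf("%s map must name every channel", m))
    }
  }
  span <- cfg$epoch_span_ms
  if (span[1] > -500 || span[2] < cfg$evoked$van_latency + 3 * cfg$evoked$van_width) {
    stop_ag("epoch span too short for the requested component latencies")
  }
  invisible(cfg)
}

#' Named simulation presets
#'
#' * `mediated` - defaults: power and (power-gated) phase shape the VAN, and
#'   perception depends on alpha only through the VAN (the mediated path).
#' * `null` - all couplings zero; used for false-positive calibration.
#' * `direct_phase` - phase acts on perception directly (`b_phase = 0.6`),
#'   not through the VAN (`v_phase = 0`).
#' * `calcarine` - as `mediated`, but the posterior VAN topography flips sign
#'   between upper- and lower-field cues.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [sim_config()].
#' @return a `sim_config`.
#' @examples
#' sim_preset("null")$evoked$v_phase
#' @export
sim_preset <- function(name = c("mediated", "null", "direct_phase",
                                "calcarine"), ...) {
  name <- match.arg(name)
  switch(name,
    mediated = sim_config(...),
    null = sim_config(evoked = list(v_pow = 0, v_phase = 0),
                      behavior = list(b_van = 0, b_pow = 0, b_phase = 0), ...),
    direct_phase = sim_config(evoked = list(v_phase = 0),
                              behavior = list(b_phase = 0.6), ...),
    calcarine = sim_config(topography_mode = "calcarine", ...)
  )
}

gauss_bump <- function(t_ms, latency, width) exp(-(t_ms - latency)^2 / (2 * width^2))

# Pink (1/f^a) + white noise for `n_sig` signals of length `n_samp`:
# frequency-domain shaping of white noise (the white spectrum is drawn
# directly as iid complex Gaussians per bin, scaled to the target PSD, and
# inverse-transformed at a fast composite length), independently per
# (trial, channel). `pink_rms`/`white_rms` set the expected RMS of each
# component; the pink spectrum has no DC so every draw is zero-mean in
# expectation across the padded window.
make_noise <- function(n_sig, n_samp, fs, pink_exponent, pink_rms, white_rms) {
  if (n_sig == 0) return(matrix(0, n_samp, 0))
  L <- stats::nextn(n_samp, c(2, 3))
  nb <- L %/% 2 - 1                       # positive-frequency bins (no DC/Nyquist)
  f <- seq_len(nb) * fs / L
  g <- f^(-pink_exponent)
  s2 <- pink_rms^2 / 4 * g / sum(g) + white_rms^2 / (4 * nb)
  s <- sqrt(s2)
  # Hermitian spectrum: X[k] = s_k (z1 + i z2), X[L-k] = Conj(X[k]);
  # then x = IFFT(X) is real with Var(x) = 4 * sum(s_k^2) = pink^2 + white^2
  Z <- matrix(complex(real = rnorm(nb * n_sig), imaginary = rnorm(nb * n_sig)),
              nb, n_sig) * s
  X <- rbind(matrix(0i, 1, n_sig), Z, matrix(0i, 1, n_sig),
             Conj(Z[rev(seq_len(nb)), , drop = FALSE]))
  x <- Re(stats::mvfft(X, inverse = TRUE))
  x[seq_len(n_samp), , drop = FALSE]
}

#' Simulate a ground-truth epoched EEG dataset
#'
#' Draws per-trial alpha amplitude (lognormal) and phase (uniform), composes
#' ongoing alpha + 1/f + white noise per channel, injects cue-evoked P1 and
#' VAN components on cue-present trials with the VAN amplitude tied to alpha
#' power and gated phase, samples perception reports from the logistic
#' behavior model, and occasionally plants blink artifacts on VEOG/FCz.
#' The phase convention is shared with [tfr_transform()]: `phase` is the
#' cosine phase of the alpha oscillation at -250 ms, so `phase = 0` means a
#' cosine peak at -250 ms.
#'
#' @param config a [sim_config()].
#' @return a list with elements `epochs` (an [epoch_set()]) and `truth`
#'   (tibble of per-trial ground truth: alpha amplitude `alpha_amp`, `phase`,
#'   z-scored log power `power_z_true`, `gate`, VAN amplitude `van_true`,
#'   perception probability `p_perceive`, `perceived`, `blink`).
#' @examples
#' sim <- simulate_dataset(sim_config(n_participants = 1,
#'                                    trials_per_participant = 10, seed = 7))
#' sim$epochs
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_p <- config$n_participants
  n_t <- config$trials_per_participant
  n_trials <- n_p * n_t
  fs <- config$fs
  span <- config$epoch_span_ms
  n_samp <- round((span[2] - span[1]) * fs / 1000) + 1
  onset <- round(-span[1] * fs / 1000) + 1
  t_ms <- (seq_len(n_samp) - onset) * 1000 / fs
  chans <- ag_all_channels
  n_ch <- length(chans)

  participant <- rep(sprintf("s%02d", seq_len(n_p)), each = n_t)

  # --- trial-level draws (fixed order for determinism) ---
  n_absent <- round(n_t * config$cue_absent_frac)
  cue_present <- as.vector(vapply(seq_len(n_p), function(p) {
    v <- rep(TRUE, n_t)
    v[sample.int(n_t, n_absent)] <- FALSE
    v
  }, logical(n_t)))
  cue_side <- ifelse(cue_present, sample(c("left", "right"), n_trials, TRUE), "none")
  cue_field <- ifelse(cue_present, sample(c("upper", "lower"), n_trials, TRUE), "none")
  cue_type <- ifelse(cue_present, sample(c("face", "house"), n_trials, TRUE), "none")

  A <- rlnorm(n_trials, config$alpha$mu_log_amp, config$alpha$sd_log_amp)
  phi <- wrap_angle(runif(n_trials, -pi, pi))

  logpow <- log(A^2)
  P_z <- as.vector(unlist(tapply(logpow, participant, scale), use.names = FALSE))

  ev <- config$evoked
  phi_pref <- deg2rad(ev$phi_pref_deg)
  gate <- plogis(ev$gate_slope * (P_z - ev$gate_mid))
  V <- ev$v_base + ev$v_pow * P_z + ev$v_phase * gate * cos(phi - phi_pref)

  # perception: z-score V among cue-present trials per participant
  bh <- config$behavior
  V_z <- rep(NA_real_, n_trials)
  for (p in unique(participant)) {
    i <- which(participant == p & cue_present)
    s_v <- stats::sd(V[i])
    V_z[i] <- if (is.finite(s_v) && s_v > 0) (V[i] - mean(V[i])) / s_v else 0
  }
  p_perc <- rep(0, n_trials)
  p_perc[cue_present] <- plogis(
    bh$b0 + bh$b_van * (-V_z[cue_present]) + bh$b_pow * P_z[cue_present] +
      bh$b_phase * cos(phi[cue_present] - phi_pref)
  )
  u <- runif(n_trials)
  lam <- bh$wrong_side_rate
  perceived <- cue_present & u < p_perc * (1 - lam)
  wrong <- cue_present & !perceived & u < p_perc
  other_side <- ifelse(cue_side == "left", "right",
                       ifelse(cue_side == "right", "left", "none"))
  report <- ifelse(perceived, cue_side, ifelse(wrong, other_side, "absent"))

  blink <- runif(n_trials) < config$artifacts$blink_prob
  blink_t <- runif(n_trials, -400, 1200)

  # --- waveform assembly, one participant block at a time ---
  gain <- config$alpha$gain[chans]
  van_map_base <- ev$van_map[chans]
  eeg_mask <- !(chans %in% c("VEOG", "HEOG"))
  p1_bump <- gauss_bump(t_ms, ev$p1_latency, ev$p1_width) * (t_ms >= 0)
  van_bump <- gauss_bump(t_ms, ev$van_latency, ev$van_width) * (t_ms >= 0)
  alpha_arg <- 2 * pi * config$alpha$f0 * (t_ms + 250) / 1000

  data <- array(NA_real_, c(n_trials, n_ch, n_samp))
  nz <- config$noise
  roi_idx <- which(chans %in% ag_roi_channels)
  for (p in seq_len(n_p)) {
    rows <- ((p - 1) * n_t + 1):(p * n_t)
    # ongoing alpha: A*cos(arg + phi) = A*cos(phi)*cos(arg) - A*sin(phi)*sin(arg)
    alpha_tr <- tcrossprod(A[rows] * cos(phi[rows]), cos(alpha_arg)) -
      tcrossprod(A[rows] * sin(phi[rows]), sin(alpha_arg))
    noise <- make_noise(n_t * n_ch, n_samp, fs, nz$pink_exponent,
                        nz$pink_rms, nz$white_rms)
    pres <- cue_present[rows]
    p1_tr <- matrix(0, n_t, n_samp)
    p1_tr[pres, ] <- matrix(rep(ev$p1_amp * p1_bump, sum(pres)),
                            ncol = n_samp, byrow = TRUE)
    van_tr <- matrix(0, n_t, n_samp)
    van_tr[pres, ] <- tcrossprod(V[rows][pres], van_bump)
    blink_tr <- matrix(0, n_t, n_samp)
    bl <- which(blink[rows])
    for (b in bl) {
      blink_tr[b, ] <- config$artifacts$blink_amp *
        gauss_bump(t_ms, blink_t[rows][b], 60)
    }
    for (c in seq_len(n_ch)) {
      vm <- rep(van_map_base[c], n_t)
      if (config$topography_mode == "calcarine" && c %in% roi_idx) {
        vm[cue_field[rows] == "upper"] <- -vm[cue_field[rows] == "upper"]
      }
      ncols <- ((c - 1) * n_t + 1):(c * n_t)
      chan_dat <- gain[c] * alpha_tr + t(noise[, ncols, drop = FALSE]) +
        gain[c] * p1_tr + vm * van_tr
      if (chans[c] == "VEOG") chan_dat <- chan_dat + blink_tr
      if (chans[c] == "FCz") chan_dat <- chan_dat + 0.15 * blink_tr
      data[rows, c, ] <- chan_dat
    }
  }

  trials <- tibble::tibble(
    participant_id = participant,
    trial_id = seq_len(n_trials),
    cue_present = cue_present,
    cue_side = cue_side,
    cue_field = cue_field,
    cue_type = cue_type,
    report = report,
    rejected = FALSE
  )
  truth <- tibble::tibble(
    participant_id = participant,
    trial_id = seq_len(n_trials),
    alpha_amp = A,
    phase = phi,
    power_z_true = P_z,
    gate = gate,
    van_true = ifelse(cue_present, V, NA_real_),
    p_perceive = ifelse(cue_present, p_perc, NA_real_),
    perceived = ifelse(cue_present, as.integer(perceived), NA_integer_),
    blink = blink
  )
  attr(truth, "config") <- config
  list(
    epochs = epoch_set(data, fs, onset, chans, trials, validate = FALSE),
    truth = truth
  )
}
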