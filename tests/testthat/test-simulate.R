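test_that("identical config and seed give identical output", {
  cfg <- sim_config(n_participants = 2, trials_per_participant = 30, seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(as.data.frame(a$epochs$trials), as.data.frame(b$epochs$trials))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("noise-free alpha at POz equals A * g * cos(phi) at -250 ms", {
  cfg <- quiet_config(n_participants = 1, trials_per_participant = 6,
                      cue_absent_frac = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  poz <- match("POz", sim$epochs$channel_names)
  i250 <- which(std_times() == -252) # nearest samples bracket -250 ms
  t_m <- std_times()[i250]
  expected <- sim$truth$alpha_amp *
    cos(2 * pi * 10 * (t_m + 250) / 1000 + sim$truth$phase)
  expect_equal(sim$epochs$data[, poz, i250], expected, tolerance = 1e-5)
  # EOG channels carry no alpha
  veog <- match("VEOG", sim$epochs$channel_names)
  expect_lt(max(abs(sim$epochs$data[, veog, i250])), 1e-4)
})

test_that("zero couplings make the VAN amplitude constant at v_base", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 20,
                    evoked = list(v_pow = 0, v_phase = 0), seed = 5)
  sim <- simulate_dataset(cfg)
  v <- sim$truth$van_true[sim$epochs$trials$cue_present]
  expect_equal(v, rep(cfg$evoked$v_base, length(v)))
})

test_that("presets encode the intended coupling structure", {
  expect_equal(sim_preset("null")$evoked$v_phase, 0)
  expect_equal(sim_preset("null")$evoked$v_pow, 0)
  expect_equal(sim_preset("null")$behavior$b_van, 0)
  expect_equal(sim_preset("mediated")$behavior$b_phase, 0)
  expect_equal(sim_preset("mediated")$evoked$v_phase, -1.5)
  expect_equal(sim_preset("direct_phase")$behavior$b_phase, 0.6)
  expect_equal(sim_preset("direct_phase")$evoked$v_phase, 0)
  expect_equal(sim_preset("calcarine")$topography_mode, "calcarine")
  expect_error(sim_preset("unknown"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cue_absent_frac = 1.2), "probabilities")
  expect_error(sim_config(noise = list(pink_rms = -1)), "positive")
  expect_error(sim_config(epoch_span_ms = c(-1000, 200)), "too short")
})

test_that("empirical perceived rate matches the logistic behavior model", {
  cfg <- sim_config(n_participants = 4, trials_per_participant = 300, seed = 11)
  sim <- simulate_dataset(cfg)
  pres <- sim$epochs$trials$cue_present
  # Monte-Carlo of the behavior equation: perception probability times the
  # correct-side retention factor (1 - lambda)
  expected <- mean(sim$truth$p_perceive[pres]) *
    (1 - cfg$behavior$wrong_side_rate)
  observed <- mean(sim$epochs$trials$report[pres] ==
                     sim$epochs$trials$cue_side[pres])
  expect_lt(abs(observed - expected), 0.05)
})

test_that("with zero couplings perception is independent of power and phase", {
  cfg <- sim_preset("null", n_participants = 2, trials_per_participant = 2048,
                    seed = 13)
  sim <- simulate_dataset(cfg)
  pres <- which(sim$epochs$trials$cue_present)
  n <- length(pres)
  perc <- sim$truth$perceived[pres]
  bound <- 3 / sqrt(n)
  expect_lt(abs(cor(perc, sim$truth$power_z_true[pres])), bound)
  expect_lt(abs(cor(perc, cos(sim$truth$phase[pres]))), bound)
  expect_lt(abs(cor(perc, sin(sim$truth$phase[pres]))), bound)
  # and the VAN amplitude is constant (no power or phase coupling)
  expect_equal(sd(sim$truth$van_true[pres]), 0)
})

test_that("posterior channels carry more alpha than FCz", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 60, seed = 17)
  sim <- simulate_dataset(cfg)
  ep <- sim$epochs
  pow_at <- function(ch) {
    tfr <- tfr_transform(ep, tfr_spec(freqs = 10, times = -250),
                         channels = ch, method = "direct")
    mean(log_power(tfr))
  }
  expect_gt(pow_at("Oz"), pow_at("FCz"))
})

test_that("injected alpha phase is exactly recoverable without noise", {
  cfg <- quiet_config(n_participants = 1, trials_per_participant = 24,
                      cue_absent_frac = 0, seed = 19)
  sim <- simulate_dataset(cfg)
  tfr <- tfr_transform(sim$epochs, tfr_spec(freqs = 10, times = -250),
                       channels = "POz", method = "direct")
  ph <- as.vector(phase_angles(tfr))
  err <- abs(circ_diff(ph, sim$truth$phase))
  expect_lt(max(err) * 180 / pi, 1)
})
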