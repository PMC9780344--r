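test_that("perception labels follow the correct-side / absent / excluded rule", {
  tr <- tibble::tibble(
    participant_id = "s01", trial_id = 1:4,
    cue_present = c(TRUE, TRUE, TRUE, FALSE),
    cue_side = c("left", "left", "left", "none"),
    cue_field = c("upper", "upper", "lower", "none"),
    cue_type = "face",
    report = c("left", "absent", "right", "absent"),
    rejected = FALSE
  )
  lab <- label_perception(tr)
  expect_equal(lab$perceived, c(1L, 0L, NA_integer_, NA_integer_))
  expect_equal(lab$retained, c(TRUE, TRUE, FALSE, FALSE))
  # artifact-rejected trials are never retained
  tr$rejected[1] <- TRUE
  expect_false(label_perception(tr)$retained[1])
  tr$report[2] <- "uncertain"
  expect_error(label_perception(tr), "malformed")
})

test_that("participants with under 30 trials per condition are excluded", {
  feats <- tibble::tibble(
    participant = rep(c("a", "b"), c(229, 60)),
    perceived = c(rep(1, 29), rep(0, 200), rep(1, 30), rep(0, 30))
  )
  out <- exclude_participants(feats)
  expect_equal(unique(out$participant), "b")         # 29 perceived -> out
  excl <- attr(out, "excluded")
  expect_equal(excl$participant, "a")
  expect_equal(excl$n_perceived, 29)
  # boundary: exactly 30/30 is kept
  expect_equal(nrow(out), 60)
  # everyone below threshold: empty table plus report, no crash
  all_out <- exclude_participants(feats, min_trials = 300)
  expect_equal(nrow(all_out), 0)
  expect_equal(nrow(attr(all_out, "excluded")), 2)
  expect_error(exclude_participants(feats[0, ]), "empty")
})

test_that("tercile split obeys the remainder rule and orders power", {
  f9 <- tibble::tibble(participant = "a", trial = 1:9, power = rnorm(9))
  expect_equal(as.vector(table(tercile_split(f9)$tercile)), c(3, 3, 3))
  f10 <- tibble::tibble(participant = "a", trial = 1:10, power = rnorm(10))
  expect_equal(as.vector(table(tercile_split(f10)$tercile)), c(4, 3, 3))
  f11 <- tibble::tibble(participant = "a", trial = 1:11, power = rnorm(11))
  expect_equal(as.vector(table(tercile_split(f11)$tercile)), c(4, 4, 3))

  f6 <- tibble::tibble(participant = "a", trial = 1:6, power = c(3, 1, 6, 2, 5, 4))
  lab <- tercile_split(f6)
  expect_equal(sort(f6$power[lab$tercile == "low"]), c(1, 2))
  expect_equal(sort(f6$power[lab$tercile == "high"]), c(5, 6))
  expect_lt(mean(f6$power[lab$tercile == "low"]),
            mean(f6$power[lab$tercile == "high"]))
  expect_error(tercile_split(tibble::tibble(participant = "a", trial = 1:2,
                                            power = 1:2)), ">= 3")
})

test_that("tercile split is a partition with ties broken by trial id", {
  set.seed(31)
  f <- tibble::tibble(participant = rep(c("a", "b"), c(50, 41)),
                      trial = 1:91, power = sample(rep(1:13, 7)))
  lab <- tercile_split(f)
  expect_false(anyNA(lab$tercile))
  for (p in c("a", "b")) {
    tab <- table(lab$tercile[lab$participant == p])
    expect_lte(abs(tab[["low"]] - tab[["high"]]), 1)
    expect_lte(max(lab$power[lab$participant == p & lab$tercile == "low"]),
               min(lab$power[lab$participant == p & lab$tercile == "high"]))
  }
  # determinism under ties
  expect_identical(tercile_split(f)$tercile, lab$tercile)
})

test_that("extract_features measures power, phase and VAN with z-invariants", {
  cfg <- quiet_config(n_participants = 2, trials_per_participant = 80,
                      seed = 33)
  sim <- simulate_dataset(cfg)
  ep <- baseline_correct(sim$epochs)
  fe <- extract_features(ep, min_trials = 5)
  tr <- sim$truth[match(fe$trial, sim$truth$trial_id), ]
  # phase matches the generator truth (noise-free)
  expect_lt(max(abs(circ_diff(fe$phase, tr$phase))) * 180 / pi, 1)
  # log power is monotone in the true alpha amplitude
  for (p in unique(fe$participant)) {
    i <- fe$participant == p
    expect_gt(cor(fe$power[i], log(tr$alpha_amp[i]^2),
                  method = "spearman"), 0.999)
  }
  # per-participant z-scores are exact
  for (p in unique(fe$participant)) {
    i <- fe$participant == p
    expect_lt(abs(mean(fe$power_z[i])), 1e-10)
    expect_lt(abs(sd(fe$power_z[i]) - 1), 1e-10)
    expect_lt(abs(mean(fe$van_z[i])), 1e-10)
    expect_lt(abs(sd(fe$van_z[i]) - 1), 1e-10)
  }
  # only cue-present, correct-side or absent-report trials are retained
  meta <- sim$epochs$trials[match(fe$trial, sim$epochs$trials$trial_id), ]
  expect_true(all(meta$cue_present))
  expect_true(all(meta$report == meta$cue_side | meta$report == "absent"))
})

test_that("a constant VAN-window trace is measured exactly", {
  es <- const_epochs(0, n_tr = 3,
                     channels = c(analysis_spec()$roi, "VEOG", "HEOG"))
  t_ms <- std_times()
  es$data[, seq_along(analysis_spec()$roi), t_ms >= 150 & t_ms < 250] <- -4
  expect_equal(window_mean(es, c(150, 250), analysis_spec()$roi), rep(-4, 3))
})

test_that("z-scoring a single-trial participant fails naming the participant", {
  feats <- tibble::tibble(participant = c("a", "a", "b"), power = c(1, 2, 3))
  expect_error(alphagate:::z_by_participant(feats$power, feats$participant),
               "'b'")
})

test_that("condition ERPs average trials and expose VAN-window means", {
  es <- epochs_from_traces(rbind(alpha_trace(0, 2), alpha_trace(0, 2)),
                           channels = c("POz", "Oz"))
  fe <- tibble::tibble(participant = "s01", trial = 1:2,
                       tercile = factor(c("low", "low"),
                                        levels = c("low", "mid", "high")))
  spec <- analysis_spec(roi = c("POz", "Oz"))
  erp <- condition_erp(es, fe, spec)
  expect_equal(erp$amplitude[erp$channel == "POz"], alpha_trace(0, 2))
  # +v and -v cancel
  es2 <- epochs_from_traces(rbind(alpha_trace(1, 3), -alpha_trace(1, 3)),
                            channels = c("POz", "Oz"))
  erp2 <- condition_erp(es2, fe, spec)
  expect_equal(max(abs(erp2$amplitude)), 0)
  expect_error(condition_erp(es, fe[fe$trial == 99, ], spec), "no trials")
})

test_that("low-tercile VAN is more negative than high under the mediated coupling", {
  cfg <- sim_config(n_participants = 2, trials_per_participant = 250,
                    noise = list(pink_rms = 0.5, white_rms = 0.2),
                    artifacts = list(blink_prob = 0), seed = 35)
  sim <- simulate_dataset(cfg)
  ep <- baseline_correct(sim$epochs)
  fe <- extract_features(ep, min_trials = 10)
  erp <- condition_erp(ep, fe)
  vm <- attr(erp, "van_mean")
  expect_lt(vm[["low"]], vm[["high"]])
})

test_that("diff_topography separates calcarine and parietal generators", {
  base <- list(n_participants = 2, trials_per_participant = 300,
               noise = list(pink_rms = 0.5, white_rms = 0.2),
               artifacts = list(blink_prob = 0), seed = 37)
  for (mode in c("parietal", "calcarine")) {
    sim <- simulate_dataset(do.call(sim_preset, c(list(name = if (mode == "calcarine") "calcarine" else "mediated"), base)))
    ep <- baseline_correct(sim$epochs)
    fe <- extract_features(ep, min_trials = 10)
    topo <- diff_topography(ep, fe)
    poz <- topo |>
      dplyr::filter(.data$channel == "POz") |>
      dplyr::group_by(.data$cue_field) |>
      dplyr::summarise(v = mean(.data$value))
    if (mode == "calcarine") {
      expect_lt(prod(poz$v), 0)     # opposite signs across fields
    } else {
      expect_gt(prod(poz$v), 0)     # same sign across fields
    }
  }
})
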