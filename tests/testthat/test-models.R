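test_that("trial_model recovers a known slope with covering bootstrap CIs", {
  set.seed(41)
  n_p <- 20; n <- 250
  d <- tibble::tibble(
    participant = rep(sprintf("s%02d", 1:n_p), each = n),
    x = rnorm(n_p * n),
    u = rep(rnorm(n_p, sd = 0.5), each = n)
  )
  d$y <- 1 + d$u + 0.8 * d$x + rnorm(nrow(d))
  m <- trial_model(d, y ~ x, "gaussian", B = 100, seed = 1)
  expect_equal(m$estimate, 0.8, tolerance = 0.05)
  expect_lt(m$ci_low, 0.8); expect_gt(m$ci_high, 0.8)
  expect_gt(m$evidence, 10)

  # pure noise: CI covers 0, evidence against the term
  d$y0 <- d$u + rnorm(nrow(d))
  m0 <- trial_model(d, y0 ~ x, "gaussian", B = 100, seed = 2)
  expect_lt(m0$ci_low, 0); expect_gt(m0$ci_high, 0)
  expect_lt(m0$evidence, 1)
})

test_that("trial_model flags separation and singular designs", {
  d <- tibble::tibble(participant = rep(c("a", "b"), each = 20),
                      x = rnorm(40), y = 1L)
  expect_error(trial_model(d, y ~ x, "bernoulli", B = 10),
               class = "alphagate_separation_error")
  d$y <- as.integer(d$x > 0)    # perfectly separated by x
  expect_error(trial_model(d, y ~ x, "bernoulli", B = 10),
               class = "alphagate_separation_error")
  d$y <- rnorm(40); d$x2 <- 2 * d$x
  err <- tryCatch(trial_model(d, y ~ x + x2, "gaussian", B = 10),
                  error = function(e) conditionMessage(e))
  expect_match(err, "x2")
})

test_that("power-by-perception contrast detects a constructed shift", {
  fe <- make_features(8, 120, a2 = 0, seed = 42)
  fe$power <- fe$power - 0.5 * (fe$perceived == 1)
  m <- compare_power_by_perception(fe, B = 100, seed = 3)
  expect_equal(m$estimate, -0.5, tolerance = 0.12)
  expect_lt(m$ci_high, 0)

  # null coupling: CI covers 0
  fe0 <- make_features(8, 120, seed = 43)
  m0 <- compare_power_by_perception(fe0, B = 100, seed = 4)
  expect_lt(m0$ci_low, 0); expect_gt(m0$ci_high, 0)
  fe1 <- fe0[fe0$perceived == 1, ]
  expect_error(compare_power_by_perception(fe1), "classes")
})

test_that("VAN-by-tercile contrast has the right sign and degenerate limit", {
  fe <- make_features(8, 150, b1 = 0.6, resid_sd = 0.5, seed = 44)
  m <- compare_van_by_tercile(fe, B = 100, seed = 5)
  expect_lt(m$estimate, 0)            # low power -> more negative VAN
  expect_lt(m$ci_high, 0)
  fe$van <- 1.5                        # identical VAN everywhere
  m0 <- compare_van_by_tercile(fe, B = 50, seed = 6)
  expect_equal(m0$estimate, 0, tolerance = 1e-10)
})

test_that("tercile rate comparison: F statistic and BIC evidence", {
  fe <- make_features(6, 90, seed = 45)
  rates <- fe |>
    dplyr::group_by(participant, tercile) |>
    dplyr::summarise(rate = mean(perceived), .groups = "drop")
  out <- compare_rates_by_tercile(fe)
  expect_equal(out$df1, 2)
  # identical rates -> F = 0
  fe2 <- fe; fe2$perceived <- rep_len(c(1, 0), nrow(fe2))
  # construct exactly equal rates by balancing within cells
  fe2 <- fe2 |>
    dplyr::group_by(participant, tercile) |>
    dplyr::mutate(perceived = as.integer(dplyr::row_number() %% 2 == 0)) |>
    dplyr::ungroup()
  r2 <- fe2 |>
    dplyr::group_by(participant, tercile) |>
    dplyr::summarise(rate = mean(perceived), .groups = "drop")
  if (length(unique(round(r2$rate, 12))) == 1) {
    expect_equal(compare_rates_by_tercile(fe2)$statistic, 0, tolerance = 1e-8)
  }
  # constructed monotone rates with small noise -> strong evidence
  set.seed(46)
  fe3 <- purrr::map_dfr(1:20, function(p) {
    purrr::map_dfr(c(low = 0.3, mid = 0.45, high = 0.6), function(r) {
      tibble::tibble(perceived = rbinom(120, 1, r))
    }, .id = "tercile") |>
      dplyr::mutate(participant = sprintf("s%02d", p))
  })
  fe3$tercile <- factor(fe3$tercile, levels = c("low", "mid", "high"))
  expect_gt(compare_rates_by_tercile(fe3)$evidence, 10)
})

test_that("preferred-phase comparison estimates a planted condition shift", {
  set.seed(47)
  n_p <- 20
  fe <- purrr::map_dfr(seq_len(n_p), function(p) {
    mu <- runif(1, -pi, pi)
    shift <- alphagate:::wrap_angle(rvonmises(1, pi, 8))
    tibble::tibble(
      participant = sprintf("s%02d", p),
      phase = c(rvonmises(80, alphagate:::wrap_angle(mu + shift), 1.2),
                rvonmises(80, mu, 1.2)),
      perceived = rep(c(1L, 0L), each = 80)
    )
  })
  cmp <- compare_preferred_phase(fe, n_iter = 400, n_flips = 2000, seed = 7)
  expect_lt(abs(circ_diff(cmp$estimate, pi)), 0.2)
  # the sign-flip statistic cannot see a shift at pi (flip-symmetric there);
  # the von Mises location test can
  expect_lt(cmp$p_location, 0.01)
  expect_equal(cmp$n_participants, n_p)
  expect_lt(abs(circ_diff(cmp$vonmises$mu, pi)), 0.3)

  # no shift: estimate ~ 0 differences and p near 1 when all deltas are 0
  fe0 <- fe
  fe0$phase[fe0$perceived == 1] <- fe0$phase[fe0$perceived == 0]
  cmp0 <- compare_preferred_phase(fe0, n_iter = 400, n_flips = 2000, seed = 8)
  expect_equal(cmp0$estimate, 0, tolerance = 1e-8)
  expect_gt(cmp0$p_signflip, 0.99)
  expect_equal(cmp0$p_location, 1)
})

test_that("sign-flip test is roughly calibrated under a uniform null", {
  set.seed(48)
  p_vals <- replicate(60, {
    fe <- purrr::map_dfr(1:8, function(p) {
      tibble::tibble(participant = sprintf("s%02d", p),
                     phase = runif(120, -pi, pi),
                     perceived = rep(c(1L, 0L), each = 60))
    })
    compare_preferred_phase(fe, n_iter = 150, n_flips = 400,
                            seed = sample.int(1e6, 1))$p_signflip
  })
  expect_gt(mean(p_vals < 0.1), 0.0)   # sanity: not degenerate at 0
  expect_lt(mean(p_vals < 0.1), 0.30)  # and not wildly anti-conservative
  expect_gt(mean(p_vals), 0.25)        # mean of ~uniform p-values near 0.5
})

test_that("topography model separates field, electrode and interaction terms", {
  # constructed per-participant cell values: strong FCz inversion, no field
  # effect; then a field flip at POz only
  set.seed(49)
  base <- tidyr::expand_grid(participant = sprintf("s%02d", 1:12),
                             cue_field = c("lower", "upper"),
                             channel = c("POz", "CPz", "FCz"))
  mu <- c(POz = -2.5, CPz = -0.4, FCz = 1.0)
  d1 <- base |>
    dplyr::mutate(value = mu[channel] + rnorm(dplyr::n(), sd = 0.3))
  m1 <- topography_interaction(d1, B = 100, seed = 9)
  fcz <- m1[m1$term == "channelFCz", ]
  fld <- m1[m1$term == "cue_fieldupper", ]
  expect_gt(fcz$estimate, 0); expect_gt(fcz$ci_low, 0)
  expect_lt(fld$ci_low, 0); expect_gt(fld$ci_high, 0)

  d2 <- base |>
    dplyr::mutate(value = ifelse(channel == "POz",
                                 ifelse(cue_field == "upper", 2.5, -2.5),
                                 mu[channel]) + rnorm(dplyr::n(), sd = 0.3))
  m2 <- topography_interaction(d2, B = 100, seed = 10)
  fld2 <- m2[m2$term == "cue_fieldupper", ]
  expect_gt(fld2$ci_low, 0)
  # all-zero input gives all-zero estimates
  d0 <- base |> dplyr::mutate(value = 0)
  m0 <- topography_interaction(d0, B = 20, seed = 11)
  expect_equal(max(abs(m0$estimate)), 0, tolerance = 1e-12)
  expect_error(topography_interaction(d1[-1, ]), "cells")
})

test_that("tidy returns the effect table columns", {
  fe <- make_features(4, 60, seed = 50)
  m <- compare_power_by_perception(fe, B = 20, seed = 12)
  td <- tidy(m)
  expect_named(td, c("term", "estimate", "ci_low", "ci_high", "evidence",
                     "n_obs", "method"))
})
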