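# Trial-level condition contrasts and the circular condition comparison.

#' Trial-level regression with participant intercepts
#'
#' Maximum-likelihood regression of a trial-level response on focal
#' predictors, with per-participant sum-to-zero fixed intercepts standing in
#' for random intercepts (adequate with tens of trials per participant).
#' 95% percentile confidence intervals come from a cluster bootstrap that
#' resamples whole participants, and per-term evidence is the
#' BIC-approximated Bayes factor `exp((BIC_without - BIC_with)/2)` for
#' retaining the term (values above 10 are read as strong evidence).
#'
#' @param data a data frame with the response, predictors and a `participant`
#'   column.
#' @param formula model formula for the focal part, e.g. `power ~ perceived`
#'   (participant intercepts are added automatically).
#' @param family `"gaussian"` or `"bernoulli"`.
#' @param B bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return an `alpha_effect` tibble: one row per focal term with `estimate`,
#'   `ci_low`, `ci_high`, `evidence`, `n_obs`, `method`; bootstrap draws in
#'   attribute `"boot"`.
#' @export
trial_model <- function(data, formula, family = c("gaussian", "bernoulli"),
                        B = 500, seed = 1L) {
  family <- match.arg(family)
  y <- stats::model.response(stats::model.frame(formula, data))
  if (!all(is.finite(y))) stop_ag("non-finite response values")
  X_focal <- model.matrix(stats::delete.response(stats::terms(formula)), data)
  X_focal <- X_focal[, colnames(X_focal) != "(Intercept)", drop = FALSE]
  if (!all(is.finite(X_focal))) stop_ag("non-finite design values")
  cluster_col <- data$participant %||% data$participant_id
  if (is.null(cluster_col)) stop_ag("data needs a `participant` column")
  cluster <- as.character(cluster_col)

  clusters <- unique(cluster)
  tpl <- participant_template(length(clusters))
  cl_idx <- match(cluster, clusters)
  X <- assemble_design(cl_idx, tpl, X_focal)
  fit <- fit_ml(X, y, family)

  focal <- colnames(X_focal)
  draws <- cluster_boot(X_focal, y, cluster, family, B, seed,
                        start = if (family == "bernoulli") fit$coef)
  ci <- percentile_ci(draws)
  evid <- vapply(focal, function(cn) bic_evidence(X, y, family, fit, cn),
                 numeric(1))
  out <- tibble::tibble(
    term = focal,
    estimate = unname(fit$coef[focal]),
    ci_low = ci[1, focal],
    ci_high = ci[2, focal],
    evidence = unname(evid),
    n_obs = length(y),
    method = "ml+cluster_bootstrap"
  )
  attr(out, "boot") <- draws
  attr(out, "fit") <- fit[c("coef", "vcov", "bic", "family")]
  class(out) <- c("alpha_effect", class(out))
  out
}

#' @method tidy alpha_effect
#' @export
tidy.alpha_effect <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("term", "estimate", "ci_low", "ci_high",
                                 "evidence", "n_obs", "method")])
}

#' Compare prestimulus alpha power between perception conditions
#'
#' Models trial-level ROI alpha log power with a perceived indicator
#' (not-perceived is the reference level); a negative estimate means lower
#' prestimulus power on perceived trials.
#'
#' @param features a `trial_features` table.
#' @param B,seed bootstrap settings, see [trial_model()].
#' @return an `alpha_effect` with term `perceived`.
#' @export
compare_power_by_perception <- function(features, B = 500, seed = 1L) {
  if (length(unique(features$perceived)) < 2) {
    stop_ag("both perception classes must be present")
  }
  trial_model(features, power ~ perceived, "gaussian", B = B, seed = seed)
}

#' Compare VAN-window amplitude between power terciles
#'
#' Models trial-level VAN-window amplitude (microvolts) with a low-power
#' indicator (high-power is the reference level); mid-tercile trials are
#' excluded. A negative estimate means the VAN is more negative on low-power
#' trials.
#'
#' @inheritParams compare_power_by_perception
#' @return an `alpha_effect` with term `low_power`.
#' @export
compare_van_by_tercile <- function(features, B = 500, seed = 1L) {
  d <- features[features$tercile %in% c("low", "high"), , drop = FALSE]
  if (!all(c("low", "high") %in% as.character(d$tercile))) {
    stop_ag("need non-empty low and high terciles")
  }
  d$low_power <- as.integer(d$tercile == "low")
  trial_model(d, van ~ low_power, "gaussian", B = B, seed = seed)
}

#' Compare perceived rates across power terciles
#'
#' One-way repeated-measures ANOVA on per-participant perceived rates in the
#' low/mid/high tercile conditions, with BIC evidence for the tercile factor
#' against the intercept-only (participant) model.
#'
#' @param features a `trial_features` table.
#' @return tibble with the F statistic, its degrees of freedom and evidence,
#'   plus the per-cell rates in attribute `"rates"`.
#' @export
compare_rates_by_tercile <- function(features) {
  rates <- features |>
    dplyr::group_by(.data$participant, .data$tercile) |>
    dplyr::summarise(rate = mean(.data$perceived), n = dplyr::n(),
                     .groups = "drop")
  if (any(table(rates$participant) < 3)) {
    stop_ag("every participant needs trials in all three terciles")
  }
  if (length(unique(rates$participant)) < 2) stop_ag("need >= 2 participants")
  full <- stats::lm(rate ~ participant + tercile, data = rates)
  null <- stats::lm(rate ~ participant, data = rates)
  an <- stats::anova(null, full)
  Fstat <- an$F[2]
  ss <- an$`Sum of Sq`[2]
  # identical fits (e.g. constant rates): treat a vanishing tercile sum of
  # squares as a zero effect rather than a 0/0 ratio
  if (is.na(Fstat) || !is.finite(Fstat) || abs(ss) < 1e-10) Fstat <- 0
  evid <- exp((stats::BIC(null) - stats::BIC(full)) / 2)
  out <- tibble::tibble(term = "tercile", statistic = Fstat,
                        df1 = an$Df[2], df2 = an$Res.Df[2],
                        evidence = evid, n_obs = nrow(rates),
                        method = "rm_anova+bic")
  attr(out, "rates") <- rates
  out
}

#' Compare preferred prestimulus alpha phase between perception conditions
#'
#' Computes, per participant and perception condition, the bootstrap
#' preferred phase (fixed 50-trial draws equate trial counts across
#' conditions), then tests whether the perceived-minus-not-perceived phase
#' difference has a consistent direction with a sign-flip permutation test:
#' under the null each participant's difference is equally likely to be
#' `+delta` or `-delta`; the statistic is the resultant length of the flipped
#' differences.
#'
#' @param features a `trial_features` table.
#' @param n_draw,n_iter bootstrap preferred-phase settings per participant
#'   and condition (see [bootstrap_preferred_phase()]).
#' @param n_flips sign-flip permutations.
#' @param seed RNG seed.
#' @return a `phase_comparison` list: `by_participant` (tibble of phases and
#'   differences), `condition_summary` (across-participant `circ_summary` per
#'   condition), `estimate` (circular mean difference, radians), `itpc_delta`,
#'   `p_signflip`, `p_location` (von Mises likelihood-ratio test that the
#'   mean difference is 0; unlike the sign-flip statistic it retains power
#'   for differences near half a cycle), `vonmises` (mu/kappa fit of the
#'   differences).
#' @export
compare_preferred_phase <- function(features, n_draw = 50, n_iter = 1000,
                                    n_flips = 10000, seed = 1L) {
  parts <- unique(features$participant)
  res <- purrr::map_dfr(seq_along(parts), function(k) {
    p <- parts[k]
    purrr::map_dfr(c(1, 0), function(cond) {
      ang <- features$phase[features$participant == p &
                              features$perceived == cond]
      # same per-participant seed in both conditions (common random numbers):
      # identical phase samples then give an exactly zero difference
      bs <- bootstrap_preferred_phase(ang, n_draw, n_iter,
                                      seed = derive_seed(seed, k))
      tibble::tibble(participant = p,
                     condition = if (cond == 1) "perceived" else "not_perceived",
                     phase = bs$preferred_phase, itpc = bs$itpc,
                     unstable = bs$unstable, n_trials = length(ang))
    })
  })
  unstable <- unique(res$participant[res$unstable])
  if (length(unstable)) {
    warn(paste0("dropping participant(s) with unstable preferred phase: ",
                paste(unstable, collapse = ", ")))
    res <- res[!res$participant %in% unstable, , drop = FALSE]
  }
  wide <- tidyr::pivot_wider(res[, c("participant", "condition", "phase")],
                             names_from = "condition", values_from = "phase")
  delta <- circ_diff(wide$perceived, wide$not_perceived)
  est <- circ_mean_resultant(delta)
  p_flip <- with_seed(derive_seed(seed, 1e6), {
    signs <- matrix(sample(c(-1, 1), length(delta) * n_flips, replace = TRUE),
                    length(delta), n_flips)
    r_perm <- Mod(colMeans(exp(1i * (delta * signs))))
    (1 + sum(r_perm >= est$itpc)) / (n_flips + 1)
  })
  cond_sum <- lapply(split(res$phase, res$condition), circ_mean_resultant)
  structure(list(
    by_participant = dplyr::mutate(wide, delta = delta),
    condition_summary = cond_sum,
    estimate = est$preferred_phase,
    itpc_delta = est$itpc,
    p_signflip = p_flip,
    p_location = vm_location_test(delta),
    vonmises = fit_vonmises(delta),
    n_participants = nrow(wide)
  ), class = "phase_comparison")
}

# von Mises likelihood-ratio test of mean direction 0. The sign-flip test is
# blind to differences concentrated near +/-pi (a von Mises(pi, kappa)
# difference distribution is itself flip-symmetric), so a location test is
# reported alongside it.
vm_location_test <- function(delta) {
  n <- length(delta)
  if (n < 3) return(NA_real_)
  s <- circ_mean_resultant(delta)
  if (s$itpc > 1 - 1e-10) {   # degenerate: all differences identical
    return(if (abs(s$preferred_phase) < 1e-8) 1 else 0)
  }
  ll <- function(mu, kappa) {
    kappa * sum(cos(delta - mu)) - n * log(2 * pi * besselI(kappa, 0))
  }
  k1 <- a1inv(s$itpc)
  c0 <- max(mean(cos(delta)), 0)          # constrained mu = 0
  k0 <- a1inv(c0)
  lr <- 2 * (ll(s$preferred_phase, k1) - ll(0, k0))
  pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf(
    "<phase_comparison> delta = %.2f rad (%.0f deg), resultant %.3f, sign-flip p = %.4g, n = %d\n",
    x$estimate, rad2deg(x$estimate), x$itpc_delta, x$p_signflip,
    x$n_participants))
  invisible(x)
}

#' @method tidy phase_comparison
#' @export
tidy.phase_comparison <- function(x, ...) {
  tibble::tibble(term = "perceived - not_perceived",
                 estimate = x$estimate,
                 estimate_deg = rad2deg(x$estimate),
                 itpc = x$itpc_delta,
                 p_signflip = x$p_signflip,
                 p_location = x$p_location,
                 vm_mu = x$vonmises$mu, vm_kappa = x$vonmises$kappa,
                 n_participants = x$n_participants)
}

#' Cue-field by electrode topography model
#'
#' Within-participant 2 (cue field: lower = reference) x 3 (electrode:
#' POz = reference) linear model of the low-minus-high VAN-window
#' differences, with participant sum-to-zero intercepts and cluster-bootstrap
#' CIs. The `cue_fieldupper` term is the field effect at POz; `channelCPz` /
#' `channelFCz` are electrode contrasts against POz; the interaction terms
#' test whether the field effect differs across electrodes.
#'
#' @param topo tibble from [diff_topography()].
#' @param B,seed bootstrap settings.
#' @return an `alpha_effect` tibble with the five contrast terms.
#' @export
topography_interaction <- function(topo, B = 500, seed = 1L) {
  cells <- table(topo$participant)
  if (any(cells < 6)) {
    stop_ag("every participant needs all 6 field x electrode cells")
  }
  d <- topo |>
    dplyr::mutate(
      cue_field = factor(.data$cue_field, levels = c("lower", "upper")),
      channel = factor(.data$channel, levels = c("POz", "CPz", "FCz")),
      value = .data$value
    )
  trial_model(d, value ~ cue_field * channel, "gaussian", B = B, seed = seed)
}
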