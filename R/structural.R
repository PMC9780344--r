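# Two-stage circular-harmonic structural model:
#   stage 1 (gaussian):  van_z ~ b0 + b1*power_z
#                               + (c1 + c3*power_z)*cos(phase)
#                               + (c2 + c4*power_z)*sin(phase)
#   stage 2 (bernoulli): logit P(perceived) = alpha_participant
#                               + a1*power_z + a2*van_z + a3*power_z*van_z
#                               + (d1 + d3*van_z)*cos(phase)
#                               + (d2 + d4*van_z)*sin(phase)
# The first harmonic in cos/sin encodes a single preferred phase; its
# power-dependent amplitude A(p) and direction phi_pref(p) are derived
# quantities. Stage 1 relies on per-participant z-scoring of both power and
# VAN amplitude; stage 2 carries explicit per-participant (sum-to-zero)
# intercepts because the binary response cannot be standardized.

stage1_terms <- c("power_z", "cos_phase", "sin_phase",
                  "power_z:cos_phase", "power_z:sin_phase")
stage2_terms <- c("power_z", "van_z", "power_z:van_z",
                  "cos_phase", "sin_phase", "van_z:cos_phase",
                  "van_z:sin_phase")

structural_design <- function(features) {
  cp <- cos(features$phase)
  sp <- sin(features$phase)
  X1 <- cbind(power_z = features$power_z, cos_phase = cp, sin_phase = sp,
              `power_z:cos_phase` = features$power_z * cp,
              `power_z:sin_phase` = features$power_z * sp)
  X2 <- cbind(power_z = features$power_z, van_z = features$van_z,
              `power_z:van_z` = features$power_z * features$van_z,
              cos_phase = cp, sin_phase = sp,
              `van_z:cos_phase` = features$van_z * cp,
              `van_z:sin_phase` = features$van_z * sp)
  list(X1 = X1, X2 = X2)
}

#' Fit the two-stage structural model
#'
#' Stage 1 regresses the z-scored VAN-window amplitude on z-scored log alpha
#' power and the first circular harmonic of alpha phase, with a power-by-phase
#' interaction (the phase effect's amplitude may depend on power). Stage 2 is
#' a logistic regression of trial-level perception on power, VAN amplitude,
#' their interaction, and the phase harmonic with a VAN-by-phase interaction,
#' with per-participant sum-to-zero intercepts. Both stages are fitted by
#' maximum likelihood; confidence intervals come from a cluster bootstrap
#' over participants, and per-term evidence is the BIC-approximated Bayes
#' factor. Joint Wald tests of the power-by-phase interaction (c3, c4) and of
#' all stage-2 phase terms (d1, d2, d3, d4) are reported with both
#' model-based and bootstrap covariance.
#'
#' @param features a `trial_features` table.
#' @param B cluster-bootstrap resamples.
#' @param seed RNG seed.
#' @return a `structural_fit` object; see [tidy.structural_fit()],
#'   [glance.structural_fit()], [preferred_phase_from_fit()] and
#'   [phase_effect_amplitude()].
#' @export
fit_structural <- function(features, B = 500, seed = 1L) {
  cluster <- as.character(features$participant)
  if (length(unique(cluster)) < 2) stop_ag("need >= 2 participants")
  if (!all(is.finite(features$power_z)) || !all(is.finite(features$van_z)) ||
      !all(is.finite(features$phase))) {
    stop_ag("non-finite feature values in the design")
  }
  ds <- structural_design(features)
  y1 <- features$van_z
  y2 <- features$perceived

  # stage 1 has no participant terms (responses are z-scored within
  # participant); an intercept-only "cluster" keeps the engine uniform
  X1 <- cbind(`(Intercept)` = 1, ds$X1)
  if (qr(X1)$rank < ncol(X1)) {
    stop_ag(paste0("stage-1 design is rank deficient (constant or aliased ",
                   "phase/power columns); phase terms unidentifiable"),
            class = "alphagate_rank_error")
  }
  fit1 <- fit_ml(X1, y1, "gaussian")

  clusters <- unique(cluster)
  tpl <- participant_template(length(clusters))
  cl_idx <- match(cluster, clusters)
  X2 <- assemble_design(cl_idx, tpl, ds$X2)
  fit2 <- fit_ml(X2, y2, "bernoulli")

  # joint cluster bootstrap of both stages on the same resamples
  rows_by <- lapply(clusters, function(cl) which(cluster == cl))
  all_terms <- c(paste0("s1_", c("(Intercept)", stage1_terms)),
                 paste0("s2_", stage2_terms))
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, B, length(all_terms),
                  dimnames = list(NULL, all_terms))
    K <- length(clusters)
    for (b in seq_len(B)) {
      pick <- sample.int(K, K, replace = TRUE)
      rows <- unlist(rows_by[pick], use.names = FALSE)
      cl_b <- rep(seq_len(K), times = lengths(rows_by)[pick])
      f1 <- tryCatch(fit_ml(X1[rows, , drop = FALSE], y1[rows], "gaussian"),
                     error = function(e) NULL)
      X2b <- assemble_design(cl_b, tpl, ds$X2[rows, , drop = FALSE])
      f2 <- tryCatch(fit_ml(X2b, y2[rows], "bernoulli", start = fit2$coef),
                     error = function(e) NULL)
      if (!is.null(f1) && !is.null(f2)) {
        out[b, ] <- c(f1$coef[c("(Intercept)", stage1_terms)],
                      f2$coef[stage2_terms])
      }
    }
    out
  })
  n_fail <- sum(!complete.cases(draws))
  if (n_fail > 0.2 * B) warn(sprintf("%d of %d bootstrap refits failed", n_fail, B))
  draws <- draws[complete.cases(draws), , drop = FALSE]

  c_terms <- c("power_z:cos_phase", "power_z:sin_phase")
  d_terms <- c("cos_phase", "sin_phase", "van_z:cos_phase", "van_z:sin_phase")
  boot_cov <- function(cols) stats::cov(draws[, cols, drop = FALSE])
  tests <- list(
    power_phase_interaction = list(
      wald = wald_joint(fit1$coef[c_terms], fit1$vcov[c_terms, c_terms]),
      wald_boot = wald_joint(fit1$coef[c_terms],
                             boot_cov(paste0("s1_", c_terms)))
    ),
    stage2_phase = list(
      wald = wald_joint(fit2$coef[d_terms], fit2$vcov[d_terms, d_terms]),
      wald_boot = wald_joint(fit2$coef[d_terms],
                             boot_cov(paste0("s2_", d_terms)))
    )
  )

  evid1 <- vapply(stage1_terms, function(cn)
    bic_evidence(X1, y1, "gaussian", fit1, cn), numeric(1))
  evid2 <- vapply(stage2_terms, function(cn)
    bic_evidence(X2, y2, "bernoulli", fit2, cn), numeric(1))

  structure(list(
    stage1 = list(coef = fit1$coef, vcov = fit1$vcov, sigma = fit1$sigma,
                  bic = fit1$bic, evidence = evid1),
    stage2 = list(coef = fit2$coef[stage2_terms],
                  intercepts = fit2$coef[grep("^\\.pid|Intercept",
                                              names(fit2$coef))],
                  vcov = fit2$vcov, bic = fit2$bic, evidence = evid2),
    boot = draws, tests = tests,
    n_obs = nrow(features), participants = clusters,
    B = B, seed = seed
  ), class = "structural_fit")
}

#' @export
print.structural_fit <- function(x, ...) {
  cat(sprintf("<structural_fit> %d trials, %d participants, B = %d bootstrap draws\n",
              x$n_obs, length(x$participants), nrow(x$boot)))
  cat(sprintf("  stage 1: b1(power) = %.3f; phase amplitude A(+1) = %.3f, A(-1) = %.3f\n",
              x$stage1$coef["power_z"], phase_effect_amplitude(x, 1),
              phase_effect_amplitude(x, -1)))
  cat(sprintf("  stage 2: a2(VAN) = %.3f; joint phase Wald p = %.3g\n",
              x$stage2$coef["van_z"], x$tests$stage2_phase$wald$p))
  invisible(x)
}

harmonic_coefs <- function(fit, p) {
  cc <- fit$stage1$coef
  c(cos = unname(cc["cos_phase"] + cc["power_z:cos_phase"] * p),
    sin = unname(cc["sin_phase"] + cc["power_z:sin_phase"] * p))
}

#' Phase-effect amplitude at a given power level
#'
#' `A(p) = sqrt((c1 + c3*p)^2 + (c2 + c4*p)^2)`: the peak-to-center depth of
#' the stage-1 phase modulation of the VAN at z-scored power `p`.
#'
#' @param fit a `structural_fit`.
#' @param p z-scored log alpha power.
#' @return non-negative amplitude in VAN z-score units.
#' @export
phase_effect_amplitude <- function(fit, p) {
  h <- harmonic_coefs(fit, p)
  sqrt(sum(h^2))
}

#' Preferred phase implied by a structural fit
#'
#' The phase at which the stage-1 model predicts the most negative VAN at
#' z-scored power `p`: `atan2(-(c2 + c4*p), -(c1 + c3*p))`. Undefined when
#' the phase-effect amplitude is essentially zero.
#'
#' @param fit a `structural_fit`.
#' @param p z-scored log alpha power.
#' @param units `"rad"` (default) or `"deg"` for reporting.
#' @param tol minimal amplitude below which the direction is undefined.
#' @return angle in (-pi, pi] radians (or degrees).
#' @export
preferred_phase_from_fit <- function(fit, p, units = c("rad", "deg"),
                                     tol = 1e-6) {
  units <- match.arg(units)
  h <- harmonic_coefs(fit, p)
  if (sqrt(sum(h^2)) < tol) {
    stop_ag(sprintf("phase-effect amplitude at p = %g is below tolerance; preferred phase undefined", p))
  }
  ang <- wrap_angle(atan2(-h["sin"], -h["cos"]))
  if (units == "deg") rad2deg(unname(ang)) else unname(ang)
}

#' @describeIn fit_structural tidy coefficient table (both stages, with
#'   cluster-bootstrap CIs and BIC evidence).
#' @param x a `structural_fit`.
#' @param ... unused.
#' @method tidy structural_fit
#' @export
tidy.structural_fit <- function(x, ...) {
  s1 <- tibble::tibble(stage = "van", term = stage1_terms,
                       estimate = unname(x$stage1$coef[stage1_terms]),
                       evidence = unname(x$stage1$evidence[stage1_terms]))
  s2 <- tibble::tibble(stage = "perception", term = stage2_terms,
                       estimate = unname(x$stage2$coef[stage2_terms]),
                       evidence = unname(x$stage2$evidence[stage2_terms]))
  out <- dplyr::bind_rows(s1, s2)
  cols <- c(paste0("s1_", stage1_terms), paste0("s2_", stage2_terms))
  ci <- percentile_ci(x$boot[, cols, drop = FALSE])
  out$ci_low <- ci[1, ]
  out$ci_high <- ci[2, ]
  out[, c("stage", "term", "estimate", "ci_low", "ci_high", "evidence")]
}

#' @describeIn fit_structural one-row model summary (sizes, BICs, derived
#'   preferred phase and phase-effect amplitudes at z-power +/-1).
#' @method glance structural_fit
#' @export
glance.structural_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_participants = length(x$participants),
    bic_van = x$stage1$bic,
    bic_perception = x$stage2$bic,
    phi_pref_deg_hi = tryCatch(preferred_phase_from_fit(x, 1, "deg"),
                               error = function(e) NA_real_),
    amp_hi = phase_effect_amplitude(x, 1),
    amp_lo = phase_effect_amplitude(x, -1),
    p_power_phase = x$tests$power_phase_interaction$wald$p,
    p_stage2_phase = x$tests$stage2_phase$wald$p
  )
}
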