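# Shared ML fitting engine: design matrices with per-participant sum-to-zero
# fixed intercepts, matrix-based refits for the cluster bootstrap, and
# BIC-approximated evidence. Kept matrix-level (lm.fit/glm.fit) because the
# bootstrap refits the same design hundreds of times.

# Sum-to-zero participant coding: cluster k of K maps to row k of a
# K x (K-1) template (identity for k < K, -1s for k = K).
participant_template <- function(n_clusters) {
  if (n_clusters == 1) return(matrix(0, 1, 0))
  tpl <- diag(n_clusters)[, -n_clusters, drop = FALSE]
  tpl[n_clusters, ] <- -1
  tpl
}

# X must carry an intercept column. family: "gaussian" or "bernoulli".
fit_ml <- function(X, y, family, start = NULL) {
  n <- length(y)
  if (family == "gaussian") {
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X)) {
      bad <- colnames(X)[is.na(fit$coefficients)]
      stop_ag(paste0("design is rank deficient; collinear column(s): ",
                     paste(bad, collapse = ", ")), class = "alphagate_rank_error")
    }
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - fit$rank)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    bic <- -2 * ll + (fit$rank + 1) * log(n)
    R <- qr.R(fit$qr)[, order(fit$qr$pivot), drop = FALSE]
    vc <- chol2inv(chol(crossprod(R))) * sigma2
    dimnames(vc) <- list(colnames(X), colnames(X))
    list(coef = fit$coefficients, vcov = vc, bic = bic,
         sigma = sqrt(sigma2), fitted = y - fit$residuals, family = family)
  } else {
    if (length(unique(y)) < 2) {
      stop_ag("perfect separation: response takes a single value",
              class = "alphagate_separation_error")
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(), start = start)
    )
    if (fit$rank < ncol(X) || anyNA(fit$coefficients)) {
      bad <- colnames(X)[is.na(fit$coefficients)]
      stop_ag(paste0("design is rank deficient; collinear column(s): ",
                     paste(bad, collapse = ", ")), class = "alphagate_rank_error")
    }
    mu <- fit$fitted.values
    if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      stop_ag("perfect separation detected (fitted probabilities of 0 or 1)",
              class = "alphagate_separation_error")
    }
    bic <- fit$deviance + fit$rank * log(n)
    R <- qr.R(fit$qr)[, order(fit$qr$pivot), drop = FALSE]
    vc <- chol2inv(chol(crossprod(R)))
    dimnames(vc) <- list(colnames(X), colnames(X))
    list(coef = fit$coefficients, vcov = vc, bic = bic,
         fitted = mu, family = family)
  }
}

# Assemble [intercept | participant sum-coding | focal columns].
assemble_design <- function(cl_idx, tpl, X_focal) {
  P <- tpl[cl_idx, , drop = FALSE]
  if (ncol(P)) colnames(P) <- paste0(".pid", seq_len(ncol(P)))
  X <- cbind(`(Intercept)` = 1, P, X_focal)
  X
}

# Cluster bootstrap: resample participants with replacement, relabel
# duplicates as distinct clusters, refit, return focal coefficient draws.
cluster_boot <- function(X_focal, y, cluster, family, B, seed, start = NULL) {
  clusters <- unique(cluster)
  K <- length(clusters)
  rows_by <- lapply(clusters, function(cl) which(cluster == cl))
  focal_names <- colnames(X_focal)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, B, length(focal_names),
                  dimnames = list(NULL, focal_names))
    for (b in seq_len(B)) {
      pick <- sample.int(K, K, replace = TRUE)
      rows <- unlist(rows_by[pick], use.names = FALSE)
      cl_idx <- rep(seq_len(K), times = lengths(rows_by)[pick])
      tpl <- participant_template(K)
      Xb <- assemble_design(cl_idx, tpl, X_focal[rows, , drop = FALSE])
      fit <- tryCatch(fit_ml(Xb, y[rows], family, start = start),
                      error = function(e) NULL)
      if (!is.null(fit)) out[b, ] <- fit$coef[focal_names]
    }
    out
  })
  failed <- sum(!complete.cases(draws))
  if (failed > 0.2 * B) {
    warn(sprintf("%d of %d bootstrap refits failed", failed, B))
  }
  draws[complete.cases(draws), , drop = FALSE]
}

percentile_ci <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
}

# Joint Wald chi-square test that a coefficient subset is zero.
wald_joint <- function(est, V) {
  stat <- tryCatch(as.numeric(t(est) %*% solve(V, est)),
                   error = function(e) NA_real_)
  list(statistic = stat, df = length(est),
       p = if (is.na(stat)) NA_real_ else pchisq(stat, length(est), lower.tail = FALSE))
}

# evidence for keeping `cols` in the model: exp((BIC_without - BIC_with)/2)
bic_evidence <- function(X, y, family, full_fit, cols) {
  keep <- setdiff(colnames(X), cols)
  red <- fit_ml(X[, keep, drop = FALSE], y, family)
  exp((red$bic - full_fit$bic) / 2)
}
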