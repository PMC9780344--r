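# Circular summary statistics and the bootstrap preferred-phase procedure.

#' Circular mean, resultant length and circular SD
#'
#' The preferred phase is the argument of the mean resultant vector
#' `sum(exp(i*theta))/n`; its length is the intertrial phase coherence (ITPC)
#' in [0, 1]; the circular SD is `sqrt(-2*log(ITPC))`. When the resultant is
#' essentially zero (ITPC < 1e-3) the mean direction is meaningless and the
#' summary is flagged unstable.
#'
#' @param angles numeric vector of angles (radians).
#' @return a `circ_summary`: list with `preferred_phase` (radians, (-pi, pi]),
#'   `itpc`, `n`, `circ_sd`, `unstable`.
#' @examples
#' circ_mean_resultant(c(0.9, 1.0, 1.1))
#' @export
circ_mean_resultant <- function(angles) {
  n <- length(angles)
  if (n == 0) stop_ag("need at least one angle")
  z <- mean(exp(1i * angles))
  itpc <- min(Mod(z), 1)
  unstable <- itpc < 1e-3
  structure(list(
    preferred_phase = if (unstable) NA_real_ else wrap_angle(Arg(z)),
    itpc = itpc, n = n,
    circ_sd = sqrt(-2 * log(max(itpc, .Machine$double.xmin))),
    unstable = unstable
  ), class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("<circ_summary> mean %.3f rad (%.1f deg), ITPC %.3f, circ SD %.3f, n = %d%s\n",
              x$preferred_phase, rad2deg(x$preferred_phase), x$itpc,
              x$circ_sd, x$n, if (x$unstable) " [unstable]" else ""))
  invisible(x)
}

#' Bootstrap preferred phase
#'
#' Resamples `n_draw` angles with replacement, takes their circular mean, and
#' repeats `n_iter` times; the preferred phase is the circular mean of the
#' iteration means and `circ_sd` their circular SD. Drawing a fixed number of
#' trials per iteration equates the effective trial count across conditions
#' with unequal sizes.
#'
#' @param angles numeric vector of angles (radians).
#' @param n_draw angles drawn per iteration (with replacement).
#' @param n_iter number of bootstrap iterations.
#' @param seed RNG seed; the global RNG state is untouched.
#' @return a `circ_summary` over the iteration means (with `n = n_iter`),
#'   carrying the sample size as attribute `n_angles`.
#' @export
bootstrap_preferred_phase <- function(angles, n_draw = 50, n_iter = 10000,
                                      seed = 1L) {
  n <- length(angles)
  if (n == 0) stop_ag("need at least one angle")
  means <- with_seed(seed, {
    idx <- sample.int(n, n_draw * n_iter, replace = TRUE)
    z <- exp(1i * angles)[idx]
    dim(z) <- c(n_draw, n_iter)
    wrap_angle(Arg(colMeans(z)))
  })
  out <- circ_mean_resultant(means)
  attr(out, "n_angles") <- n
  out
}

#' Signed circular difference
#'
#' `a - b` wrapped into (-pi, pi].
#'
#' @param a,b angles (radians); vectorized.
#' @return signed angular differences.
#' @examples
#' circ_diff(3, -3)  # wraps through pi to about -0.283
#' @export
circ_diff <- function(a, b) wrap_angle(a - b)

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler; used to build calibrated test fixtures.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop_ag("kappa must be non-negative")
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_angle(mu + out)
}

# Maximum-likelihood von Mises concentration from a resultant length
# (standard series approximations).
a1inv <- function(r) {
  if (r >= 0.9) return(1 / (r^3 - 4 * r^2 + 3 * r))
  if (r < 0.53) return(2 * r + r^3 + 5 * r^5 / 6)
  -0.4 + 1.39 * r + 0.43 / (1 - r)
}

#' Fit a von Mises distribution
#'
#' @param angles numeric vector (radians).
#' @return list with `mu` (radians) and `kappa` (ML estimate).
#' @export
fit_vonmises <- function(angles) {
  s <- circ_mean_resultant(angles)
  list(mu = s$preferred_phase, kappa = a1inv(s$itpc))
}
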