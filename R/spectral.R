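# Hanning-tapered complex-convolution time-frequency transform.
#
# Conventions (shared with the synthetic generator, and load-bearing for the
# parameter-recovery tests):
#  * kernel length = cycles*fs/f rounded to the nearest odd sample count, so a
#    center sample exists and "center = analysis time" is unambiguous;
#  * the kernel is normalized so a unit-amplitude sinusoid at f yields
#    |coeff| = 0.5 (analytic-signal convention);
#  * phase = 0 means a cosine peak at the analysis time;
#  * requested analysis times map to the nearest sample; the coefficient's
#    phase is then rotated by -2*pi*f*(t_sample - t_requested) so the reported
#    phase refers to the requested time even when it falls between samples
#    (50-ms steps are not an integer number of 4-ms samples);
#  * windows that overrun the epoch are flagged invalid, never zero-padded.

#' Cycle count per frequency
#'
#' Taper window lengths follow a piecewise rule: 3 cycles up to 7 Hz,
#' 5 cycles for 8-14 Hz, 7 for 15-30 Hz and 10 for 31-60 Hz, giving an
#' alpha-band window of ~500 ms.
#'
#' @param f frequency (Hz), within 1..60. Vectorized.
#' @return integer cycle count(s).
#' @examples
#' cycles_for_frequency(c(5, 10, 20, 40))
#' @export
cycles_for_frequency <- function(f) {
  if (any(f < 1 | f > 60)) stop_ag("frequencies must lie in [1, 60] Hz")
  unname(c(3L, 5L, 7L, 10L)[findInterval(f, c(1, 7 + 1e-9, 14 + 1e-9, 30 + 1e-9))])
}

#' Time-frequency analysis specification
#'
#' @param freqs analysis frequencies (Hz), ascending, within 1..60.
#' @param times analysis times (ms relative to onset); each maps to the
#'   nearest sample at transform time.
#' @return a `tfr_spec`.
#' @export
tfr_spec <- function(freqs = 1:60, times = seq(-1000, 2000, by = 50)) {
  if (is.unsorted(freqs, strictly = TRUE)) stop_ag("freqs must be strictly ascending")
  cycles_for_frequency(freqs)  # validates range
  structure(list(freqs = freqs, times = times, taper = "hanning"),
            class = "tfr_spec")
}

hanning <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Hanning-tapered complex wavelet
#'
#' Builds the complex kernel `hanning(n) * exp(i*2*pi*f*t_k)` with `t_k`
#' centered on 0 and `n = cycles*fs/f` rounded to the nearest odd count,
#' scaled by `1/sum(hanning(n))` so a unit cosine at `f` yields `|coeff| = 0.5`.
#'
#' @param f frequency (Hz).
#' @param cycles number of cycles in the window (default per
#'   [cycles_for_frequency()]).
#' @param fs sampling rate (Hz).
#' @return complex vector with attribute `center` (1-based center index).
#' @examples
#' length(make_tapered_wavelet(10, fs = 250)) # 125 samples ~ 500 ms
#' @export
make_tapered_wavelet <- function(f, cycles = cycles_for_frequency(f), fs) {
  if (f <= 0 || fs <= 0) stop_ag("f and fs must be positive")
  m <- cycles * fs / f
  n <- max(2 * round((m - 1) / 2) + 1, 3)
  h <- hanning(n)
  center <- (n + 1) / 2
  t_k <- (seq_len(n) - center) / fs
  k <- h * exp(1i * 2 * pi * f * t_k) / sum(h)
  attr(k, "center") <- center
  k
}

#' Tapered complex-convolution time-frequency transform
#'
#' Computes, for every trial, channel, frequency and analysis time, the inner
#' product of the conjugated tapered wavelet with the epoch segment centered
#' at that time. The default FFT path and the `direct` path (explicit inner
#' products) are numerically interchangeable; the direct path is faster when
#' only a few analysis times are requested.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [tfr_spec()].
#' @param channels channels to transform (default all).
#' @param method `"fft"` (overlap-free FFT cross-correlation) or `"direct"`.
#' @return a `tfr_stack`: list with `coeff` (complex array, trials x channels
#'   x freqs x times), `freqs`, `times` (requested), `sample_times` (freq x
#'   time matrix of the sample-grid times actually used), `valid` (freq x time
#'   logical), plus channel names and the trial table.
#' @export
tfr_transform <- function(epochs, spec = tfr_spec(), channels = NULL,
                          method = c("fft", "direct")) {
  method <- match.arg(method)
  channels <- channels %||% epochs$channel_names
  ci <- channel_idx(epochs, channels)
  fs <- epochs$fs
  t_ms <- epoch_times(epochs)
  n_samp <- length(t_ms)
  n_tr <- dim(epochs$data)[1]
  n_ch <- length(ci)
  n_f <- length(spec$freqs)
  n_t <- length(spec$times)

  # requested times -> nearest sample index
  tidx <- vapply(spec$times, function(tt) which.min(abs(t_ms - tt)), integer(1))
  sample_times <- matrix(rep(t_ms[tidx], each = n_f), n_f, n_t)

  coeff <- array(NA_complex_, c(n_tr, n_ch, n_f, n_t))
  valid <- matrix(FALSE, n_f, n_t)

  # per-frequency kernels, validity and phase compensation to requested times
  kernels <- lapply(spec$freqs, function(f)
    make_tapered_wavelet(f, cycles_for_frequency(f), fs))
  halves <- (lengths(kernels) - 1) / 2
  rots <- matrix(NA_complex_, n_f, n_t)
  for (fi in seq_len(n_f)) {
    f <- spec$freqs[fi]
    if (lengths(kernels)[fi] > n_samp) {
      warn(sprintf("kernel for %g Hz (%d samples) exceeds the epoch; all times invalid",
                   f, lengths(kernels)[fi]))
      next
    }
    valid[fi, ] <- tidx - halves[fi] >= 1 & tidx + halves[fi] <= n_samp
    if (!any(valid[fi, ])) {
      warn(sprintf("no analysis time at %g Hz fits inside the epoch", f))
    }
    rots[fi, ] <- exp(-1i * 2 * pi * f * (t_ms[tidx] - spec$times) / 1000)
  }

  # channel-at-a-time keeps the memory footprint flat on large epoch sets
  L <- stats::nextn(n_samp + max(lengths(kernels)) - 1, 2)
  for (ch in seq_len(n_ch)) {
    dat <- matrix(epochs$data[, ci[ch], ], n_tr, n_samp)
    X <- if (method == "fft") {
      stats::mvfft(t(cbind(dat, matrix(0, n_tr, L - n_samp))))
    }
    for (fi in seq_len(n_f)) {
      if (!any(valid[fi, ])) next
      w <- kernels[[fi]]
      half <- halves[fi]
      if (method == "direct") {
        wc <- Conj(w)
        for (ti in which(valid[fi, ])) {
          seg <- dat[, (tidx[ti] - half):(tidx[ti] + half), drop = FALSE]
          coeff[, ch, fi, ti] <- (seg %*% wc) * rots[fi, ti]
        }
      } else {
        W <- fft(c(as.complex(w), rep(0i, L - length(w))))
        # cross-correlation identity: IDFT(X*conj(W))[n] = sum_k conj(w_k) x(n+k)
        S <- stats::mvfft(X * Conj(as.vector(W)), inverse = TRUE) / L
        # so the coefficient centered (1-based) at sample s sits in row s - half
        for (ti in which(valid[fi, ])) {
          coeff[, ch, fi, ti] <- S[tidx[ti] - half, ] * rots[fi, ti]
        }
      }
    }
  }
  structure(list(coeff = coeff, freqs = spec$freqs, times = spec$times,
                 sample_times = sample_times, valid = valid, fs = fs,
                 channel_names = channels, trials = epochs$trials),
            class = "tfr_stack")
}

#' @export
print.tfr_stack <- function(x, ...) {
  d <- dim(x$coeff)
  cat(sprintf("<tfr_stack> %d trials x %d channels x %d freqs x %d times; %d/%d valid cells\n",
              d[1], d[2], d[3], d[4], sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Natural-log power of a time-frequency stack
#'
#' `ln(|coeff|^2 + 1e-20)`; the epsilon only guards identically-zero synthetic
#' segments against `-Inf`. Invalid cells propagate as `NA`.
#'
#' @param tfr a `tfr_stack` from [tfr_transform()].
#' @return numeric array, trials x channels x freqs x times.
#' @export
log_power <- function(tfr) {
  lp <- log(Mod(tfr$coeff)^2 + 1e-20)
  invalidate_cells(lp, tfr$valid)
}

#' Phase angles of a time-frequency stack
#'
#' Argument of the complex coefficients under the cosine-at-center convention
#' (0 = cosine peak at the analysis time), in (-pi, pi]. Zero coefficients
#' have no defined phase and come back as `NA` with a warning.
#'
#' @param tfr a `tfr_stack`.
#' @return numeric array of angles, trials x channels x freqs x times.
#' @export
phase_angles <- function(tfr) {
  ph <- wrap_angle(Arg(tfr$coeff))
  zero <- Mod(tfr$coeff) == 0
  if (any(zero, na.rm = TRUE)) {
    warn(sprintf("%d zero coefficient(s): phase undefined, set to NA",
                 sum(zero, na.rm = TRUE)))
    ph[zero] <- NA_real_
  }
  invalidate_cells(ph, tfr$valid)
}

invalidate_cells <- function(arr, valid) {
  if (all(valid)) return(arr)
  d <- dim(arr)
  for (fi in seq_len(d[3])) for (ti in seq_len(d[4])) {
    if (!valid[fi, ti]) arr[, , fi, ti] <- NA_real_
  }
  arr
}
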