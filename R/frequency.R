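#' Resample an NN series onto a uniform tachogram
#'
#' Cubic-spline interpolation of the (end time, interval) pairs onto a
#' uniform grid at `fs` Hz spanning the recording, as required before FFT
#' based spectral analysis of the intrinsically unevenly sampled NN data.
#' Editing gaps are bridged by the spline — the abnormal data inside them
#' was already removed, and no interpolated point is ever fed back into the
#' time-domain statistics.
#'
#' @param nn an [nn_series()] with at least 2 intervals spanning >= 120 s
#'   (shorter recordings cannot resolve the 0.04 Hz LF edge).
#' @param fs resampling rate, Hz (default 4; must exceed twice the 0.40 Hz
#'   upper analysis edge).
#' @return A list of class `hrv_tachogram` with `values` (ms), `fs`, and
#'   `t0` (grid origin, ms).
#' @export
resample_nn <- function(nn, fs = 4) {
  stopifnot(inherits(nn, "nn_series"), length(nn$intervals) >= 2, fs > 0.8)
  t <- nn$end_times
  span_s <- (t[length(t)] - t[1]) / 1000
  if (span_s < 120) {
    stop("recording spans only ", round(span_s, 1),
         " s; at least 120 s needed for spectral analysis")
  }
  grid <- seq(t[1], t[length(t)], by = 1000 / fs)
  values <- stats::spline(x = t, y = nn$intervals, xout = grid, method = "fmm")$y
  structure(list(values = values, fs = fs, t0 = t[1]), class = "hrv_tachogram")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))

# least-squares removal of a straight line (includes the mean)
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::.lm.fit(cbind(1, t), x)$residuals
}

#' Welch power spectral density of a tachogram
#'
#' Averaged modified periodograms: the tachogram is split into
#' `segment_s`-second segments with `overlap` fractional overlap; each
#' segment is linearly detrended (removing its mean and any slow drift),
#' Hann-windowed, and Fourier transformed.  The one-sided density is
#' normalized by the window power so that its integral over frequency
#' equals the time-domain variance of the signal.
#'
#' @param tachogram output of [resample_nn()].
#' @param segment_s segment length, s (default 256).
#' @param overlap fractional segment overlap in \[0, 1) (default 0.5).
#' @return A list of class `hrv_psd` with `freq` (Hz), `density` (ms^2/Hz),
#'   and the bin width `df`.
#' @export
welch_psd <- function(tachogram, segment_s = 256, overlap = 0.5) {
  stopifnot(inherits(tachogram, "hrv_tachogram"),
            segment_s > 0, overlap >= 0, overlap < 1)
  x <- tachogram$values
  fs <- tachogram$fs
  L <- round(segment_s * fs)
  if (length(x) < L) {
    warning("tachogram shorter than one Welch segment; ",
            "falling back to a single periodogram")
    L <- length(x)
  }
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq.int(1L, length(x) - L + 1L, by = step)
  w <- hann_window(L)
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- detrend_linear(x[s:(s + L - 1L)]) * w
    X <- stats::fft(seg)
    P <- Mod(X[seq_len(nf)])^2 / (fs * U)
    # one-sided: double everything except DC (and Nyquist when L is even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + P * dbl
  }
  structure(list(freq = seq(0, nf - 1) * fs / L,
                 density = acc / length(starts),
                 df = fs / L, n_segments = length(starts)),
            class = "hrv_psd")
}

#' @export
print.hrv_psd <- function(x, ...) {
  cat(sprintf("<hrv_psd> %d bins, df = %.5f Hz, %d Welch segment(s), total %.1f ms^2\n",
              length(x$freq), x$df, x$n_segments, sum(x$density) * x$df))
  invisible(x)
}

#' @export
plot.hrv_psd <- function(x, xlim = c(0, 0.5), ...) {
  graphics::plot(x$freq, x$density, type = "l", xlim = xlim,
                 xlab = "Frequency (Hz)", ylab = expression(PSD ~ (ms^2 / Hz)), ...)
  graphics::abline(v = c(0.04, 0.15, 0.40), lty = 3, col = "grey40")
  invisible(x)
}

#' Spectral band powers and peaks
#'
#' Integrates the PSD over the conventional short-term bands — VLF
#' \[0.0033, 0.04) Hz, LF \[0.04, 0.15) Hz (modulated sympathetic activity)
#' and HF \[0.15, 0.40\] Hz (vagal, respiratory) — with half-open edges so
#' no bin is double counted.  Total power is the sum of the three bands.
#' Normalized powers are LF/(LF+HF) and HF/(LF+HF), which are exact
#' complements; sympathovagal balance is the LF/HF ratio.
#'
#' @param psd output of [welch_psd()].
#' @param vlf,lf,hf band edges, Hz.
#' @return A list of class `spectral_metrics` with `tp`, `vlf`, `lf`, `hf`
#'   (ms^2), `n_lf`, `n_hf`, `lf_hf`, and the peak frequency of each band
#'   (`peak_vlf`, `peak_lf`, `peak_hf`, Hz).  `lf_hf` is `NA` when the HF
#'   power is zero.
#' @export
band_powers <- function(psd, vlf = c(0.0033, 0.04), lf = c(0.04, 0.15),
                        hf = c(0.15, 0.40)) {
  stopifnot(inherits(psd, "hrv_psd"))
  if (max(psd$freq) < hf[2]) stop("PSD does not cover the HF band")
  f <- psd$freq
  masks <- list(vlf = f >= vlf[1] & f < vlf[2],
                lf = f >= lf[1] & f < lf[2],
                hf = f >= hf[1] & f <= hf[2])
  power <- vapply(masks, function(m) sum(psd$density[m]) * psd$df, 0)
  peak <- vapply(masks, function(m) {
    if (!any(m)) return(NA_real_)
    f[m][which.max(psd$density[m])]
  }, 0)
  lf_p <- power[["lf"]]
  hf_p <- power[["hf"]]
  denom <- lf_p + hf_p
  structure(list(tp = sum(power), vlf = power[["vlf"]], lf = lf_p, hf = hf_p,
                 n_lf = if (denom > 0) lf_p / denom else NA_real_,
                 n_hf = if (denom > 0) hf_p / denom else NA_real_,
                 lf_hf = if (hf_p > 0) lf_p / hf_p else NA_real_,
                 peak_vlf = peak[["vlf"]], peak_lf = peak[["lf"]],
                 peak_hf = peak[["hf"]]),
            class = "spectral_metrics")
}

#' @export
print.spectral_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Frequency-domain HRV (Welch)\n",
    "  TP %.1f  VLF %.1f  LF %.1f  HF %.1f ms^2\n",
    "  nLF %s  nHF %s  LF/HF %s\n",
    "  peaks: VLF %s  LF %s  HF %s Hz\n"),
    x$tp, x$vlf, x$lf, x$hf,
    fmt_na(x$n_lf, "%.2f"), fmt_na(x$n_hf, "%.2f"), fmt_na(x$lf_hf, "%.2f"),
    fmt_na(x$peak_vlf, "%.3f"), fmt_na(x$peak_lf, "%.3f"),
    fmt_na(x$peak_hf, "%.3f")))
  invisible(x)
}

#' Full spectral pipeline for an NN series
#'
#' Convenience wrapper: [resample_nn()] then [welch_psd()] then
#' [band_powers()].
#'
#' @inheritParams resample_nn
#' @inheritParams welch_psd
#' @inheritParams band_powers
#' @return A `spectral_metrics` list (see [band_powers()]).
#' @export
spectral_metrics <- function(nn, fs = 4, segment_s = 256, overlap = 0.5,
                             vlf = c(0.0033, 0.04), lf = c(0.04, 0.15),
                             hf = c(0.15, 0.40)) {
  band_powers(welch_psd(resample_nn(nn, fs = fs), segment_s = segment_s,
                        overlap = overlap),
              vlf = vlf, lf = lf, hf = hf)
}
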