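## Shared signal-processing helpers: FIR band-pass, analytic signal,
## Butterworth low-pass + decimation, Welch spectra.

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase (window-design) band-pass applied forward and backward.
#' The default order corresponds to three cycles of the low band edge,
#' the resolution the sliding-window wave fit assumes.
#'
#' @param x numeric vector.
#' @param band length-2 band in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (even); default `ceiling(3*fs/band[1]/2)*2`.
#' @return filtered vector, same length.
#' @export
bandpass_fir <- function(x, band = c(7, 13), fs = 100, order = NULL) {
  nyq <- fs / 2
  if (band[2] >= nyq) stop("band edge at or above Nyquist")
  if (is.null(order)) order <- ceiling(3 * fs / band[1] / 2) * 2
  h <- signal::fir1(order, band / nyq, type = "pass")
  as.numeric(signal::filtfilt(filt = h, x = x))
}

#' Analytic signal via the FFT Hilbert transform
#'
#' @param x real numeric vector.
#' @return complex vector; `Arg()` of it is the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Low-pass filter and decimate a set of traces
#'
#' Zero-phase 3rd-order Butterworth low-pass (20 Hz cutoff by default)
#' followed by decimation, the preprocessing applied to source traces
#' before EEG projection (1 kHz -> 100 Hz).
#'
#' @param x numeric vector or matrix (time in rows).
#' @param fs input sampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @param fs_out output sampling rate, Hz (must divide `fs`).
#' @return filtered, downsampled vector/matrix.
#' @export
lowpass_decimate <- function(x, fs = 1000, cutoff = 20, fs_out = 100) {
  dec <- fs / fs_out
  if (abs(dec - round(dec)) > 1e-9) stop("fs_out must divide fs")
  dec <- round(dec)
  bf <- signal::butter(3, cutoff / (fs / 2), type = "low")
  f1 <- function(v) {
    if (length(v) < 3 * max(length(bf$b), length(bf$a)))
      stop("input too short to filter")
    as.numeric(signal::filtfilt(bf, v))[seq(1, length(v), by = dec)]
  }
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

#' Welch power spectral density
#'
#' Mean periodogram over Hann-windowed overlapping segments.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param seg_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @param demean subtract the mean of each segment.
#' @return list with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5, demean = TRUE) {
  nseg <- round(seg_s * fs)
  nseg <- min(nseg, length(x))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    if (demean) seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg * w))^2
  }
  p <- acc / length(starts) / (fs * sum(w^2))
  nf <- floor(nseg / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / nseg, power = p[seq_len(nf)])
}

#' Spectral peak frequency within a band
#'
#' @param x numeric vector (a rate or EEG trace).
#' @param fs sampling rate, Hz.
#' @param band search band, Hz.
#' @param seg_s Welch segment length, seconds.
#' @param interp parabolic (log-power) interpolation of the peak
#'   position between frequency bins.
#' @return peak frequency in Hz (argmax of the Welch PSD in `band`).
#' @export
spectral_peak <- function(x, fs, band = c(5, 15), seg_s = 2,
                          interp = FALSE) {
  ps <- welch_psd(x, fs, seg_s = seg_s)
  sel <- which(ps$freq >= band[1] & ps$freq <= band[2])
  peak_interp(ps$freq, ps$power, sel, interp)
}

#' Sub-bin spectral peak location
#'
#' Parabolic interpolation of the peak position on log power around the
#' argmax bin of a power spectrum.
#'
#' @param freq frequency axis, Hz (uniform grid).
#' @param power power values.
#' @param sel integer indices of the search band.
#' @param interp set `FALSE` to return the raw argmax bin.
#' @return peak frequency in Hz.
#' @export
peak_interp <- function(freq, power, sel, interp = TRUE) {
  i <- sel[which.max(power[sel])]
  if (!interp || i <= 1 || i >= length(freq)) return(freq[i])
  lp <- log(power[(i - 1):(i + 1)] + 1e-300)
  den <- lp[1] - 2 * lp[2] + lp[3]
  if (den >= 0) return(freq[i])
  delta <- 0.5 * (lp[1] - lp[3]) / den
  freq[i] + delta * (freq[2] - freq[1])
}

## circular helpers
circ_mean <- function(theta) Arg(sum(exp(1i * theta)))
wrap_pi <- function(theta) Arg(exp(1i * theta))
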