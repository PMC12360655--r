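## Synthetic validation data: ideal planar scalp waves with known
## direction, and phase-lagged dipole configurations projected through the
## production lead field. Every generator is seed-deterministic and
## carries its ground truth in the returned object.

#' Ideal planar scalp wave
#'
#' Each channel receives `sin(2*pi*f*t - a*x - b*y)` plus optional white
#' noise, where `(a, b) = xi * (cos(direction), sin(direction))` and
#' `direction` is the propagation direction. The spatial phase gradient
#' of such a wave points along `direction + pi`: a wave propagating
#' toward anterior (`direction = pi/2`) is a forward wave.
#'
#' @param direction propagation direction, radians (`pi/2` = anterior =
#'   FW; `-pi/2` = posterior = BW).
#' @param xi spatial frequency, radians per unit of 2D layout distance.
#' @param freq temporal frequency, Hz.
#' @param duration seconds.
#' @param amplitude wave amplitude.
#' @param noise_sd additive white-noise SD.
#' @param montage an `eeg_montage`.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed for the noise.
#' @return a `sim_eeg` with attribute `ground_truth` (list with the
#'   generator parameters and the implied gradient direction).
#' @export
make_planar_scalp_wave <- function(direction, xi = 1, freq = 10,
                                   duration = 5, amplitude = 1,
                                   noise_sd = 0, montage = load_montage(),
                                   fs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  a <- xi * cos(direction); b <- xi * sin(direction)
  ph_sp <- a * montage$x2d + b * montage$y2d
  dat <- amplitude * sin(outer(2 * pi * freq * tt, ph_sp, "-"))
  if (noise_sd > 0)
    dat <- dat + matrix(stats::rnorm(length(dat), sd = noise_sd),
                        nrow(dat))
  colnames(dat) <- montage$channel
  out <- structure(list(data = dat, fs = fs, montage = montage),
                   class = "sim_eeg")
  attr(out, "ground_truth") <- list(direction = wrap_pi(direction),
                                    gradient = wrap_pi(direction + pi),
                                    xi = xi, freq = freq)
  out
}

#' Phase-lagged oscillatory dipole sources
#'
#' Two or three sinusoidal sources at the cortical-area dipole positions
#' with imposed per-source phase offsets, projected through the same
#' spherical lead field as real simulations. Occipital leading parietal
#' leading frontal (increasingly negative offsets up the hierarchy) is
#' the forward configuration.
#'
#' @param phase_offsets numeric vector (length 2 or 3) of per-source
#'   phase offsets in radians, ordered from the lowest (occipital) area.
#'   A source with a larger offset is further along its cycle, i.e.
#'   leads.
#' @param freq common frequency, Hz.
#' @param duration seconds.
#' @param montage an `eeg_montage`.
#' @param fs sampling rate, Hz.
#' @param n_noise,snr_range noise configuration passed to [project_eeg].
#' @param seed RNG seed.
#' @return a `sim_eeg` with attribute `ground_truth` (`"FW"`, `"BW"` or
#'   `"none"` from the sign of the imposed lag).
#' @export
make_lagged_dipole_eeg <- function(phase_offsets = c(0, -0.7, -1.4),
                                   freq = 10, duration = 5,
                                   montage = load_montage(), fs = 100,
                                   n_noise = 0, snr_range = c(0.4, 1.6),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_src <- length(phase_offsets)
  stopifnot(n_src %in% c(2, 3))
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  src <- vapply(phase_offsets,
                function(p0) sin(2 * pi * freq * tt + p0),
                numeric(length(tt)))
  ## pad missing areas with silent sources so area indexing matches
  if (n_src == 2) src <- cbind(src, 0 * tt)
  out <- project_eeg(src, montage, hemi = rep("", 3), fs = fs,
                     n_noise = n_noise, snr_range = snr_range)
  lag <- phase_offsets[1] - phase_offsets[n_src]
  attr(out, "ground_truth") <- list(
    offsets = phase_offsets,
    state = if (abs(lag) < 1e-12) "none" else if (lag > 0) "FW" else "BW")
  out
}
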