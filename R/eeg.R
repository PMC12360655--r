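## Scalp-level EEG forward projection: spherical-head radial-dipole lead
## field, per-area source signals, 1/f noise sources and the preprocessing
## chain (low-pass + downsample) applied to the simulated rates.

#' Load the packaged 64-channel montage
#'
#' Standard BioSemi-64 electrode positions (unit-sphere 3D coordinates)
#' together with the 2D azimuthal-equidistant projection used by the wave
#' fit.
#'
#' @param path optional path to a montage CSV with columns
#'   `channel,x,y,z,x2d,y2d`; default is the packaged layout.
#' @return data.frame of class `eeg_montage`.
#' @export
load_montage <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "biosemi64_montage.csv",
                        package = "lamwave")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "x", "y", "z", "x2d", "y2d") %in% names(m)))
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' Electrode region-of-interest presets
#'
#' Frozen electrode lists derived from the 2D layout geometry: a midline
#' rectangle of 38 electrodes spanning Iz-Fz occipito-frontally, and two
#' lateral ROIs of 20 electrodes each (midline excluded).
#'
#' @param roi `"midline"`, `"left"` or `"right"`.
#' @return character vector of channel names.
#' @export
electrode_roi <- function(roi = c("midline", "left", "right")) {
  roi <- match.arg(roi)
  tab <- utils::read.csv(system.file("extdata", "electrode_rois.csv",
                                     package = "lamwave"),
                         stringsAsFactors = FALSE)
  tab$channel[tab$roi == roi]
}

#' Dipole positions for the cortical areas
#'
#' MNI coordinates (mm) of the bilateral radial dipoles representing each
#' cortical area: occipital for the lowest, parietal and frontal above it.
#'
#' @param n_areas number of areas (only the 3-area placement is defined).
#' @return data.frame with `area`, `hemi` (`L`/`R`) and `x,y,z` in mm.
#' @export
area_dipoles <- function(n_areas = 3) {
  if (n_areas != 3)
    stop("dipole placements are defined for the 3-area model")
  base <- data.frame(
    area = rep(1:3, each = 2),
    hemi = rep(c("L", "R"), 3),
    x = c(-8, 8, -24, 24, -5, 5),
    y = c(-76, -76, -61, -61, 48, 48),
    z = c(10, 10, 58, 58, 30, 30))
  base
}

## Legendre polynomials P_1..P_nmax at x, by recurrence; returns matrix
## length(x) x nmax
.legendre <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))       # P_0
  p <- x                          # P_1
  out[, 1] <- p
  for (n in 2:nmax) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[, n] <- pn
    pm1 <- p; p <- pn
  }
  out
}

#' Spherical-head lead field for radial dipoles
#'
#' Surface potential of a radial current dipole in a homogeneous
#' conducting sphere, via the Legendre series
#' `V(gamma) ~ sum_n (2n+1) b^(n-1) P_n(cos gamma)` where `b` is the
#' dipole eccentricity (fraction of the sphere radius) and `gamma` the
#' angle between electrode and dipole position. The overall conductivity
#' scale is irrelevant here because source signals are z-scored and noise
#' is calibrated by SNR.
#'
#' @param montage an `eeg_montage`.
#' @param positions matrix/data.frame of dipole positions in MNI mm
#'   (columns x, y, z).
#' @param head_radius_mm scalp sphere radius used to scale MNI positions.
#' @param max_eccentricity eccentricity cap (series convergence and
#'   physical plausibility).
#' @param n_terms series terms.
#' @return gain matrix, electrodes x sources.
#' @export
sphere_leadfield <- function(montage, positions, head_radius_mm = 100,
                             max_eccentricity = 0.6, n_terms = 60) {
  E <- as.matrix(montage[, c("x", "y", "z")])
  P <- as.matrix(positions)
  if (ncol(P) != 3) stop("positions must have columns x, y, z")
  G <- matrix(0, nrow(E), nrow(P))
  for (s in seq_len(nrow(P))) {
    pos <- P[s, ]
    rr <- sqrt(sum(pos^2))
    b <- min(rr / head_radius_mm, max_eccentricity)
    u <- if (rr > 0) pos / rr else c(0, 0, 1)
    cosg <- pmin(pmax(E %*% u, -1), 1)
    L <- .legendre(as.numeric(cosg), n_terms)
    coefs <- (2 * seq_len(n_terms) + 1) * b^(seq_len(n_terms) - 1)
    G[, s] <- L %*% coefs
  }
  rownames(G) <- montage$channel
  G
}

#' 1/f (pink) noise series
#'
#' Spectral synthesis: Fourier amplitudes shaped as `f^(-1/2)` (power
#' slope -1) with random phases; zero-mean output.
#'
#' @param n_samples length.
#' @return numeric vector.
#' @export
make_pink_noise <- function(n_samples) {
  n <- n_samples
  nf <- floor(n / 2)
  amp <- (seq_len(nf))^(-0.5)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Mod(spec[nf]) *
                              sign(cos(phase[nf])))
    if (nf >= 2) full[seq(n, n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  } else {
    full[seq(n, n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Per-area source signal from simulated traces
#'
#' Average of the five laminar node traces of one area, demeaned. This is
#' the signal assigned to the area's dipole(s).
#'
#' @param traces a `sim_traces` object.
#' @param area area index.
#' @param hemi `""`, `"L."` or `"R."`.
#' @return numeric vector at the trace sampling rate.
#' @export
area_source_signal <- function(traces, area, hemi = "") {
  cols <- paste0(hemi, "Cx", area, ".",
                 c("L4X", "L4IN", "SGX", "SGIN", "IGIB"))
  x <- rowMeans(traces$rates[, cols, drop = FALSE])
  x - mean(x)
}

#' Project source signals to the scalp
#'
#' Linear projection of per-area source signals through the spherical
#' lead field, with bilateral half-amplitude placement in single-stream
#' mode (hemisphere-specific full amplitude in dual-stream mode), plus
#' five independent 1/f noise sources at random intracranial positions,
#' each scaled to a signal-to-noise ratio drawn uniformly from
#' `snr_range` (RMS of the noise projection relative to RMS of the scalp
#' signal mixture). Source signals are z-scored before projection; the
#' wave fit uses phase only.
#'
#' @param sources numeric matrix, time x source signals at 100 Hz. In
#'   single-stream mode one column per area; in dual-stream mode columns
#'   ordered (L areas..., R areas...) with `hemi` labels.
#' @param montage an `eeg_montage`.
#' @param hemi character vector, one of `""` (bilateral placement at half
#'   amplitude) or `"L"`/`"R"` per column.
#' @param fs sampling rate of `sources`, Hz.
#' @param n_noise number of 1/f noise sources (0 disables noise).
#' @param snr_range range of the per-source noise/signal RMS ratio.
#' @param snr_space where the RMS ratio is enforced: `"source"` scales
#'   each (unit-RMS) noise source's dipole amplitude relative to the
#'   unit-RMS cortical source signals before projection; `"sensor"`
#'   scales the noise's scalp projection relative to the RMS of the
#'   projected signal mixture.
#' @param noise_eccentricity noise sources are placed uniformly within
#'   this fraction of the head radius.
#' @param max_eccentricity eccentricity cap of the lead field; the
#'   default pulls sources toward the sphere center, mimicking the
#'   spatial smoothing of realistic multi-shell head models (the plane
#'   fit needs smooth dipolar topographies, not focal ones).
#' @param head_radius_mm scalp sphere radius, mm.
#' @return object of class `sim_eeg`: `data` (time x 64), `fs`,
#'   `montage`.
#' @export
project_eeg <- function(sources, montage = load_montage(),
                        hemi = NULL, fs = 100,
                        n_noise = 5, snr_range = c(0.4, 1.6),
                        snr_space = c("source", "sensor"),
                        noise_eccentricity = 0.85,
                        max_eccentricity = 0.6,
                        head_radius_mm = 100) {
  sources <- as.matrix(sources)
  n_src <- ncol(sources)
  if (is.null(hemi)) hemi <- rep("", n_src)
  stopifnot(length(hemi) == n_src)
  dip <- area_dipoles(3)

  Z <- apply(sources, 2, function(x) {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else x - mean(x)
  })

  pos <- NULL; amp <- NULL; src_col <- NULL
  for (j in seq_len(n_src)) {
    aj <- ((j - 1) %% 3) + 1    # area index for this column
    if (hemi[j] == "") {
      d <- dip[dip$area == aj, ]
      pos <- rbind(pos, as.matrix(d[, c("x", "y", "z")]))
      amp <- c(amp, rep(0.5, nrow(d)))
      src_col <- c(src_col, rep(j, nrow(d)))
    } else {
      d <- dip[dip$area == aj & dip$hemi == hemi[j], ]
      pos <- rbind(pos, as.matrix(d[, c("x", "y", "z")]))
      amp <- c(amp, 1)
      src_col <- c(src_col, j)
    }
  }
  G <- sphere_leadfield(montage, pos, head_radius_mm = head_radius_mm,
                        max_eccentricity = max_eccentricity)
  sig <- Z[, src_col, drop = FALSE] %*% t(G * rep(amp, each = nrow(G)))

  snr_space <- match.arg(snr_space)
  eeg <- sig
  if (n_noise > 0) {
    rms_sig <- sqrt(mean(sig^2))
    mean_amp <- mean(amp)
    for (k in seq_len(n_noise)) {
      ## uniform random position inside the allowed sphere
      repeat {
        p <- stats::runif(3, -1, 1)
        if (sum(p^2) <= 1) break
      }
      p <- p * noise_eccentricity * head_radius_mm
      gk <- sphere_leadfield(montage, matrix(p, 1),
                             head_radius_mm = head_radius_mm,
                             max_eccentricity = max_eccentricity)
      nz <- make_pink_noise(nrow(sources))
      snr <- stats::runif(1, snr_range[1], snr_range[2])
      if (snr_space == "source") {
        proj <- (nz * snr * mean_amp) %*% t(gk)
      } else {
        proj <- nz %*% t(gk)
        proj <- proj * snr * rms_sig / sqrt(mean(proj^2))
      }
      eeg <- eeg + proj
    }
  }
  colnames(eeg) <- montage$channel
  structure(list(data = eeg, fs = fs, montage = montage),
            class = "sim_eeg")
}

#' @export
print.sim_eeg <- function(x, ...) {
  cat(sprintf("Simulated EEG: %d channels x %.1f s at %.0f Hz\n",
              ncol(x$data), nrow(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Full source-to-scalp chain for simulated traces
#'
#' Per-area source signals -> zero-phase 20 Hz low-pass -> downsample to
#' 100 Hz -> dipole projection with 1/f noise. Neither the pulvinar nor
#' the input layers are projected.
#'
#' @param traces a `sim_traces` object.
#' @param montage an `eeg_montage`.
#' @param ... passed to [project_eeg] (e.g. `n_noise = 0`).
#' @return a `sim_eeg` object.
#' @export
eeg_from_traces <- function(traces, montage = load_montage(), ...) {
  cfg <- traces$network$config
  fs_in <- 1 / traces$dt
  if (cfg$hemispheres == 2) {
    hemi <- c(rep("L", cfg$n_areas), rep("R", cfg$n_areas))
    src <- cbind(
      vapply(seq_len(cfg$n_areas),
             function(a) area_source_signal(traces, a, "L."),
             numeric(nrow(traces$rates))),
      vapply(seq_len(cfg$n_areas),
             function(a) area_source_signal(traces, a, "R."),
             numeric(nrow(traces$rates))))
  } else {
    hemi <- rep("", cfg$n_areas)
    src <- vapply(seq_len(cfg$n_areas),
                  function(a) area_source_signal(traces, a),
                  numeric(nrow(traces$rates)))
  }
  src100 <- lowpass_decimate(src, fs = fs_in, fs_out = 100)
  project_eeg(src100, montage, hemi = hemi, fs = 100, ...)
}
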