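## Traveling-wave quantification from multichannel phase maps: band-pass +
## analytic phase, exhaustive plane fit over a direction x spatial-frequency
## grid, circular-correlation significance against an electrode-permutation
## null, and FW/BW/Null state classification.
##
## Sign conventions: the fitted plane is theta_hat = a*x + b*y + const and
## alpha = atan2(b, a) is the direction of the spatial phase *gradient*
## (the direction in which phase increases). A wave propagates opposite its
## phase gradient, so a forward (posterior-to-anterior) wave has its
## gradient pointing posterior: alpha = -pi/2 in the 2D layout (+y
## anterior). That value is the default forward reference axis.

#' Default forward-wave reference axis
#'
#' The phase-gradient direction of a forward (occipito-frontal) wave in
#' the 2D layout: pointing posterior, `-pi/2`.
#'
#' @return angle in radians.
#' @export
fw_axis_default <- function() -pi / 2

#' Relative phase maps for a set of electrodes
#'
#' FIR band-pass (7-13 Hz default), analytic (Hilbert) phase, referenced
#' to the circular mean phase across the ROI at each sample, then
#' circularly averaged within a sliding window.
#'
#' @param eeg a `sim_eeg` object, or a numeric matrix time x channels
#'   (then `fs` and `channels` must be given).
#' @param band frequency band, Hz.
#' @param roi ROI name (see [electrode_roi]) or character vector of
#'   channel names.
#' @param window_s sliding window, seconds.
#' @param step window step in samples.
#' @param fs,channels,positions needed only when `eeg` is a bare matrix;
#'   `positions` is a 2-column matrix of 2D coordinates per channel.
#' @return object of class `phase_map`: `phases` (windows x electrodes,
#'   radians in (-pi, pi]), `times` (window centers, s), `positions`,
#'   `channels`, `band`.
#' @export
compute_phase <- function(eeg, band = c(7, 13), roi = "midline",
                          window_s = 0.1, step = 1,
                          fs = NULL, channels = NULL, positions = NULL) {
  if (inherits(eeg, "sim_eeg")) {
    dat <- eeg$data; fs <- eeg$fs
    channels <- eeg$montage$channel
    positions <- as.matrix(eeg$montage[, c("x2d", "y2d")])
  } else {
    dat <- as.matrix(eeg)
    if (is.null(fs) || is.null(channels) || is.null(positions))
      stop("fs, channels and positions are required for matrix input")
    positions <- as.matrix(positions)
  }
  if (band[2] >= fs / 2) stop("band outside Nyquist range")
  if (nrow(dat) < fs) stop("need at least 1 s of data")
  sel <- if (length(roi) == 1 && roi %in% c("midline", "left", "right"))
    electrode_roi(roi) else roi
  ci <- match(sel, channels)
  if (any(is.na(ci))) stop("ROI channels missing from data")
  dat <- dat[, ci, drop = FALSE]
  pos <- positions[ci, , drop = FALSE]

  ph <- apply(dat, 2, function(x)
    Arg(analytic_signal(bandpass_fir(x - mean(x), band, fs))))
  ## reference to ROI circular mean per sample
  z <- exp(1i * ph)
  ref <- Arg(rowSums(z))
  z <- z * exp(-1i * ref)
  ## sliding circular mean
  w <- max(1, round(window_s * fs))
  kern <- rep(1 / w, w)
  zr <- stats::filter(Re(z), kern, sides = 2)
  zi <- stats::filter(Im(z), kern, sides = 2)
  ok <- which(!is.na(zr[, 1]))
  idx <- ok[seq(1, length(ok), by = step)]
  phases <- atan2(as.matrix(zi[idx, , drop = FALSE]),
                  as.matrix(zr[idx, , drop = FALSE]))
  structure(list(phases = phases, times = (idx - 1) / fs,
                 positions = pos, channels = sel, band = band,
                 fs = fs, step = step),
            class = "phase_map")
}

#' Direction x spatial-frequency search grid
#'
#' 60 directions over the full circle and 30 spatial-frequency steps from
#' 0 up to one cycle (2*pi radians) over the maximum electrode distance.
#'
#' @param positions 2-column matrix of electrode coordinates.
#' @param n_dir,n_xi grid sizes.
#' @return list with `alpha`, `xi` (per grid row), `a`, `b` and the
#'   predicted-phase matrix `pred` (grid rows x electrodes).
#' @export
plane_fit_grid <- function(positions, n_dir = 60, n_xi = 30) {
  d_max <- max(stats::dist(positions))
  alphas <- seq(0, 2 * pi, length.out = n_dir + 1)[seq_len(n_dir)]
  xis <- seq(0, 2 * pi / d_max, length.out = n_xi)
  g <- expand.grid(alpha = alphas, xi = xis)
  a <- g$xi * cos(g$alpha)
  b <- g$xi * sin(g$alpha)
  pred <- outer(a, positions[, 1]) + outer(b, positions[, 2])
  list(alpha = g$alpha, xi = g$xi, a = a, b = b, pred = pred,
       d_max = d_max, n_dir = n_dir, n_xi = n_xi)
}

#' Plane fit of phase maps over the search grid
#'
#' For every window, evaluates the planar-wave model
#' `theta_hat = a*x + b*y + const` on the whole grid and selects the
#' parameters maximizing the resultant length of the circular residuals
#' `rbar = |mean(exp(i*(theta - theta_hat)))|`. Windows whose best fit is
#' the uniform-phase solution (`xi = 0`) get `alpha = NA` (direction
#' undefined without a gradient).
#'
#' @param phases matrix windows x electrodes (or a `phase_map`).
#' @param positions 2-column coordinate matrix (ignored for `phase_map`
#'   input).
#' @param grid optional precomputed [plane_fit_grid].
#' @param chunk windows per matrix-product block.
#' @return data.frame with `alpha`, `xi`, `rbar`, `rho` per window.
#' @export
plane_fit <- function(phases, positions = NULL, grid = NULL, chunk = 2048) {
  if (inherits(phases, "phase_map")) {
    positions <- phases$positions
    phases <- phases$phases
  }
  phases <- if (is.matrix(phases)) phases else matrix(phases, nrow = 1)
  ne <- ncol(phases)
  if (ne < 3) stop("need at least 3 electrodes")
  if (is.null(grid)) {
    if (qr(cbind(1, positions))$rank < 3) stop("collinear electrode layout")
    grid <- plane_fit_grid(positions)
  }
  Mr <- cos(grid$pred); Mi <- sin(grid$pred)
  nwin <- nrow(phases)
  alpha <- xi <- rbar <- rho <- numeric(nwin)
  for (s0 in seq(1, nwin, by = chunk)) {
    s1 <- min(s0 + chunk - 1, nwin)
    th <- t(phases[s0:s1, , drop = FALSE])   # ne x nw
    Wr <- cos(th); Wi <- sin(th)
    ReS <- Mr %*% Wr + Mi %*% Wi
    ImS <- Mr %*% Wi - Mi %*% Wr
    R2 <- ReS^2 + ImS^2
    best <- max.col(t(R2), ties.method = "first")
    for (j in seq_along(best)) {
      g <- best[j]; w <- s0 + j - 1
      alpha[w] <- grid$alpha[g]; xi[w] <- grid$xi[g]
      rbar[w] <- sqrt(R2[g, j]) / ne
      rho[w] <- circ_corr(phases[w, ], grid$pred[g, ])
    }
  }
  alpha[xi == 0] <- NA_real_
  data.frame(alpha = wrap_pi(alpha), xi = xi, rbar = rbar, rho = rho)
}

#' Circular correlation between observed and predicted phases
#'
#' `rho = sum(sin(t - tbar) sin(p - pbar)) /
#'  sqrt(sum(sin^2(t - tbar)) sum(sin^2(p - pbar)))` with circular means
#' `tbar`, `pbar`.
#'
#' @param theta,theta_hat phase vectors, radians, equal length >= 3.
#' @return correlation in `[-1, 1]` (0 when either spread is degenerate).
#' @export
circ_corr <- function(theta, theta_hat) {
  stopifnot(length(theta) == length(theta_hat), length(theta) >= 3)
  st <- sin(theta - circ_mean(theta))
  sp <- sin(theta_hat - circ_mean(theta_hat))
  den <- sqrt(sum(st^2) * sum(sp^2))
  if (den == 0) return(0)
  sum(st * sp) / den
}

#' Permutation null distribution for the plane fit
#'
#' Repeats the fit with randomly permuted electrode positions (10
#' permutations by default) at reduced temporal resolution (every 5th
#' window), collates the resulting circular correlations and returns
#' their one-sided 95% threshold.
#'
#' @param phase_map a `phase_map` (or windows x electrodes matrix with
#'   `positions`).
#' @param positions needed for matrix input.
#' @param n_perm number of electrode-position permutations.
#' @param every temporal subsampling factor for the null fits.
#' @param prob quantile for the threshold.
#' @return object of class `wave_null`: list with `rho` (collated null
#'   values) and `threshold`.
#' @export
build_null <- function(phase_map, positions = NULL, n_perm = 10,
                       every = 5, prob = 0.95) {
  if (inherits(phase_map, "phase_map")) {
    positions <- phase_map$positions
    phases <- phase_map$phases
  } else phases <- phase_map
  sub <- phases[seq(1, nrow(phases), by = every), , drop = FALSE]
  rhos <- numeric(0)
  for (p in seq_len(n_perm)) {
    perm <- sample(nrow(positions))
    fit <- plane_fit(sub, positions[perm, , drop = FALSE])
    rhos <- c(rhos, fit$rho)
  }
  structure(list(rho = rhos,
                 threshold = stats::quantile(rhos, prob, names = FALSE)),
            class = "wave_null")
}

#' Classify plane fits into FW / BW / Null states
#'
#' A window is `FW` when its circular correlation exceeds the null
#' threshold and its gradient direction lies within 0.5 rad of the
#' forward reference axis; `BW` for the opposite direction; `Null`
#' otherwise (including undefined directions at `xi = 0`).
#'
#' @param fit data.frame from [plane_fit].
#' @param null a `wave_null` (or numeric threshold).
#' @param reference_axis forward-wave axis in radians
#'   ([fw_axis_default] for non-lateralized data).
#' @param tol_rad angular tolerance.
#' @return factor with levels `FW`, `BW`, `Null`.
#' @export
classify_states <- function(fit, null, reference_axis = fw_axis_default(),
                            tol_rad = 0.5) {
  thr <- if (inherits(null, "wave_null")) null$threshold else null
  sig <- fit$rho > thr & !is.na(fit$alpha)
  d_fw <- abs(wrap_pi(fit$alpha - reference_axis))
  d_bw <- abs(wrap_pi(fit$alpha - reference_axis - pi))
  state <- rep("Null", nrow(fit))
  state[sig & d_fw <= tol_rad] <- "FW"
  state[sig & d_bw <= tol_rad] <- "BW"
  factor(state, levels = c("FW", "BW", "Null"))
}

#' Fit traveling-wave states to multichannel EEG
#'
#' The full estimation chain: relative phase maps ([compute_phase]),
#' exhaustive plane fit ([plane_fit]), electrode-permutation null
#' ([build_null]) and state classification ([classify_states]).
#'
#' @param eeg a `sim_eeg` or numeric matrix (see [compute_phase]).
#' @param band,roi,window_s,step passed to [compute_phase].
#' @param null a precomputed `wave_null` (rebuilt from this dataset when
#'   `NULL`); pass a numeric threshold to skip the permutation step.
#' @param reference_axis forward-wave axis, radians.
#' @param n_perm permutations for the null.
#' @param ... passed to [compute_phase] (e.g. `fs`, `channels`,
#'   `positions` for matrix input).
#' @return object of class `wavefit`: `windows` data.frame (time, alpha,
#'   xi, rbar, rho, state), `null`, `roi`, `band`, `reference_axis`,
#'   `positions`.
#' @export
fit_waves <- function(eeg, band = c(7, 13), roi = "midline",
                      window_s = 0.1, step = 1, null = NULL,
                      reference_axis = fw_axis_default(),
                      n_perm = 10, ...) {
  pm <- compute_phase(eeg, band = band, roi = roi, window_s = window_s,
                      step = step, ...)
  grid <- plane_fit_grid(pm$positions)
  fit <- plane_fit(pm$phases, pm$positions, grid = grid)
  if (is.null(null)) null <- build_null(pm, n_perm = n_perm)
  fit$state <- classify_states(fit, null, reference_axis)
  fit$time <- pm$times
  structure(list(windows = fit[, c("time", "alpha", "xi", "rbar",
                                   "rho", "state")],
                 null = null, roi = roi, band = band,
                 reference_axis = reference_axis,
                 positions = pm$positions, channels = pm$channels,
                 grid = list(n_dir = grid$n_dir, n_xi = grid$n_xi,
                             d_max = grid$d_max)),
            class = "wavefit")
}

#' @export
print.wavefit <- function(x, ...) {
  tab <- table(x$windows$state)
  n <- nrow(x$windows)
  cat(sprintf("Traveling-wave fit: %d windows, band %.0f-%.0f Hz, ROI '%s'\n",
              n, x$band[1], x$band[2],
              paste(x$roi, collapse = "+")))
  cat(sprintf("  FW %.1f%%  BW %.1f%%  Null %.1f%%  (rho threshold %.3f)\n",
              100 * tab["FW"] / n, 100 * tab["BW"] / n,
              100 * tab["Null"] / n, threshold(x)))
  invisible(x)
}

#' @export
summary.wavefit <- function(object, ...) {
  w <- object$windows
  by_state <- function(st) {
    s <- w[w$state == st, ]
    c(fraction = nrow(s) / nrow(w),
      median_alpha = if (nrow(s)) circ_median(s$alpha) else NA_real_,
      mean_xi = if (nrow(s)) mean(s$xi) else NA_real_,
      mean_rho = if (nrow(s)) mean(s$rho) else NA_real_)
  }
  out <- rbind(FW = by_state("FW"), BW = by_state("BW"),
               Null = by_state("Null"))
  structure(list(table = out, n = nrow(w),
                 threshold = threshold(object)),
            class = "summary.wavefit")
}

#' @export
print.summary.wavefit <- function(x, ...) {
  cat(sprintf("Wave-state summary over %d windows (rho threshold %.3f):\n",
              x$n, x$threshold))
  print(round(x$table, 3))
  invisible(x)
}

#' @export
coef.wavefit <- function(object, ...) {
  w <- object$windows
  c(p_fw = mean(w$state == "FW"),
    p_bw = mean(w$state == "BW"),
    alpha_fw = circ_median(w$alpha[w$state == "FW"]),
    alpha_bw = circ_median(w$alpha[w$state == "BW"]),
    xi_fw = mean(w$xi[w$state == "FW"]),
    xi_bw = mean(w$xi[w$state == "BW"]))
}

#' @export
plot.wavefit <- function(x, ...) {
  w <- x$windows
  cols <- c(FW = "#2166ac", BW = "#b2182b", Null = "grey70")
  graphics::plot(w$time, w$alpha, col = cols[as.character(w$state)],
                 pch = 16, cex = 0.4, ylim = c(-pi, pi),
                 xlab = "time (s)", ylab = "gradient direction (rad)", ...)
  graphics::abline(h = c(x$reference_axis,
                         wrap_pi(x$reference_axis + pi)),
                   lty = 2, col = cols[c("FW", "BW")])
  graphics::legend("topright", legend = names(cols), col = cols,
                   pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Null threshold of a wavefit
#'
#' @param x a `wavefit`.
#' @return numeric threshold.
#' @export
threshold <- function(x) {
  if (inherits(x$null, "wave_null")) x$null$threshold else x$null
}

#' Circular median of a set of angles
#'
#' The data angle minimizing the summed absolute wrapped distance.
#'
#' @param theta angles in radians (NAs dropped).
#' @return angle in radians (NA for empty input).
#' @export
circ_median <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (!length(theta)) return(NA_real_)
  cand <- c(theta, circ_mean(theta))
  cost <- vapply(cand, function(t0)
    sum(abs(wrap_pi(theta - t0))), numeric(1))
  ## ties (e.g. symmetric distributions) resolve to the circular mean,
  ## which is the geometrically central direction
  best <- min(cost)
  if (cost[length(cand)] <= best + 1e-9) return(cand[length(cand)])
  cand[which.min(cost)]
}

#' Reference axis for lateralized data
#'
#' Combines classified FW and BW gradient directions from one or two
#' lateral-ROI fits into a single distribution: backward directions are
#' reflected through pi, the second (right) ROI is mirrored across the
#' sagittal plane, and the circular median of the merged distribution is
#' returned as the forward reference axis.
#'
#' @param fit_left a `wavefit` (left or only ROI).
#' @param fit_right optional second `wavefit` (mirrored before merging).
#' @return forward axis in radians.
#' @export
lateral_reference_axis <- function(fit_left, fit_right = NULL) {
  dirs <- function(f, mirror = FALSE) {
    w <- f$windows
    a <- c(w$alpha[w$state == "FW"],
           wrap_pi(w$alpha[w$state == "BW"] + pi))
    if (mirror) a <- wrap_pi(pi - a)   # (x, y) -> (-x, y)
    a
  }
  all_dirs <- dirs(fit_left)
  if (!is.null(fit_right)) all_dirs <- c(all_dirs, dirs(fit_right, TRUE))
  all_dirs <- all_dirs[!is.na(all_dirs)]
  if (length(all_dirs) < 1) return(fw_axis_default())
  circ_median(all_dirs)
}
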