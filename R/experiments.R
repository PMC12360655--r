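## Scripted experiment drivers: response curves, impulse responses, state
## time-courses, spectral analyses, delay sweeps, pulvinar sweeps and
## lateralized simulations. All drivers are seed-deterministic and return
## plain data structures.

#' Simulate one trial and classify its scalp wave states
#'
#' Convenience chain: simulate -> EEG projection -> wave fit, with an
#' optional precomputed null threshold.
#'
#' @param net an `alpha_network`.
#' @param stimulus a `stimulus_protocol` (or list for dual-stream), or
#'   `NULL`.
#' @param duration seconds.
#' @param seed RNG seed for the trial.
#' @param null a `wave_null` or numeric threshold (`NULL` rebuilds one
#'   from this trial).
#' @param roi ROI preset name.
#' @param reference_axis forward axis, radians.
#' @param step window step in samples (100 Hz windows for `step = 1`).
#' @param ... passed to [eeg_from_traces].
#' @return the `wavefit` object; attribute `traces` holds the
#'   simulation.
#' @export
classify_trial <- function(net, stimulus = NULL, duration = 5, seed = NULL,
                           null = NULL, roi = "midline",
                           reference_axis = fw_axis_default(),
                           step = 1, ...) {
  tr <- simulate(net, duration = duration, seed = seed,
                 stimulus = stimulus)
  eeg <- eeg_from_traces(tr, ...)
  wf <- fit_waves(eeg, roi = roi, null = null, step = step,
                  reference_axis = reference_axis)
  attr(wf, "traces") <- tr
  wf
}

## shared: build one permutation null from a rest + a stimulated trial
.experiment_null <- function(net, amplitude, duration = 4, seed = 1,
                             roi = "midline") {
  rest <- simulate(net, duration = duration, seed = seed)
  stim <- simulate(net, duration = duration, seed = seed + 1,
                   stimulus = make_dc_stimulus(amplitude, 1, duration))
  pm_r <- compute_phase(eeg_from_traces(rest), roi = roi, step = 5)
  pm_s <- compute_phase(eeg_from_traces(stim), roi = roi, step = 5)
  phases <- rbind(pm_r$phases, pm_s$phases)
  build_null(phases, positions = pm_r$positions)
}

#' Four-parameter logistic fit
#'
#' `y = floor + (ceiling - floor) / (1 + exp(-slope*(x - midpoint)))`.
#' The response threshold is the midpoint (center of the sigmoid).
#'
#' @param x,y data.
#' @return list with `coef` (floor, ceiling, slope, midpoint),
#'   `threshold`, `fitted`, and `converged`.
#' @export
fit_logistic4 <- function(x, y) {
  st <- list(fl = min(y), ce = max(y), sl = 5 / (diff(range(x)) + 1e-9),
             mi = stats::approx(y, x, xout = (min(y) + max(y)) / 2,
                                ties = mean)$y)
  if (!is.finite(st$mi)) st$mi <- mean(x)
  f <- function(p) p[1] + (p[2] - p[1]) / (1 + exp(-p[3] * (x - p[4])))
  obj <- function(p) sum((y - f(p))^2)
  par <- unlist(st)
  fit <- NULL
  for (k in 1:5) {   # Nelder-Mead with restarts until converged
    fit <- try(stats::optim(par, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) break
    par <- fit$par
    if (fit$convergence == 0) break
  }
  if (inherits(fit, "try-error") || fit$convergence != 0) {
    warning("logistic fit did not converge; returning raw curve")
    return(list(coef = c(floor = NA, ceiling = NA, slope = NA,
                         midpoint = NA),
                threshold = NA_real_, fitted = rep(NA_real_, length(x)),
                converged = FALSE))
  }
  p <- unname(fit$par)
  ## canonical form: the 4PL is invariant under swapping floor/ceiling
  ## with a sign flip of the slope; keep floor <= ceiling
  if (p[1] > p[2]) p <- c(p[2], p[1], -p[3], p[4])
  list(coef = c(floor = p[1], ceiling = p[2], slope = p[3],
                midpoint = p[4]),
       threshold = unname(p[4]), fitted = f(p), converged = TRUE)
}

#' FW/BW response curve over stimulus currents
#'
#' Probability of FW (and BW) classification during a DC stimulation as
#' a function of input current, with a 4-parameter logistic fit whose
#' midpoint estimates the wave-reversal threshold current.
#'
#' @param currents nA grid (>= 10 values spanning the reversal).
#' @param n_runs runs per current.
#' @param duration stimulation length, seconds.
#' @param seed base RNG seed.
#' @param config a [network_config].
#' @param roi ROI preset.
#' @param burn_in_s seconds of rest before stimulus onset (discarded).
#' @param step window step in samples.
#' @return object of class `response_curve`: data.frame `curve`
#'   (current, p_fw, p_bw), logistic fits `fit_fw`, `fit_bw`,
#'   `threshold` (nA).
#' @export
run_response_curve <- function(currents = seq(0, 2, length.out = 15),
                               n_runs = 20, duration = 3, seed = 1,
                               config = network_config(),
                               roi = "midline", burn_in_s = 1,
                               step = 2) {
  net <- alpha_network(config)
  null <- .experiment_null(net, max(currents), seed = seed, roi = roi)
  p_fw <- p_bw <- numeric(length(currents))
  for (ci in seq_along(currents)) {
    n_fw <- n_bw <- n_tot <- 0
    for (r in seq_len(n_runs)) {
      wf <- classify_trial(
        net, make_dc_stimulus(currents[ci], burn_in_s,
                              burn_in_s + duration),
        duration = burn_in_s + duration,
        seed = seed + 1000 * ci + r, null = null, roi = roi,
        step = step)
      w <- wf$windows
      sel <- w$time >= burn_in_s + 0.2
      n_fw <- n_fw + sum(w$state[sel] == "FW")
      n_bw <- n_bw + sum(w$state[sel] == "BW")
      n_tot <- n_tot + sum(sel)
    }
    p_fw[ci] <- n_fw / n_tot
    p_bw[ci] <- n_bw / n_tot
  }
  fit_fw <- fit_logistic4(currents, p_fw)
  fit_bw <- fit_logistic4(currents, p_bw)
  structure(list(curve = data.frame(current = currents, p_fw = p_fw,
                                    p_bw = p_bw),
                 fit_fw = fit_fw, fit_bw = fit_bw,
                 threshold = fit_fw$threshold, null = null,
                 n_runs = n_runs),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("FW response curve over %d currents x %d runs\n",
              nrow(x$curve), x$n_runs))
  cat(sprintf("  reversal threshold (sigmoid midpoint): %.3f nA\n",
              x$threshold))
  invisible(x)
}

#' @export
plot.response_curve <- function(x, ...) {
  graphics::plot(x$curve$current, x$curve$p_fw, type = "b", pch = 16,
                 col = "#2166ac", ylim = c(0, 1),
                 xlab = "stimulus current (nA)",
                 ylab = "P(state)", ...)
  graphics::lines(x$curve$current, x$curve$p_bw, type = "b", pch = 16,
                  col = "#b2182b")
  if (x$fit_fw$converged)
    graphics::lines(x$curve$current, x$fit_fw$fitted, col = "#2166ac",
                    lty = 2)
  graphics::abline(v = x$threshold, lty = 3)
  graphics::legend("right", c("FW", "BW"), col = c("#2166ac", "#b2182b"),
                   pch = 16, bty = "n")
  invisible(x)
}

#' Impulse (temporal) response of the wave state
#'
#' Cross-correlates the binary FW (and BW) state sequence with a
#' suprathreshold random step stimulus, against a chance band from
#' shuffled trial pairings. The non-rhythmic stimulus updates at 10 Hz,
#' so the correlogram traces the network's generalized impulse response.
#'
#' @param amplitude stimulus current (above the reversal threshold), nA.
#' @param trial_s stimulated seconds per trial.
#' @param n_trials trials.
#' @param seed base seed.
#' @param config a [network_config].
#' @param max_lag_s correlogram lag range, seconds.
#' @param n_shuffle trial shufflings for the chance band.
#' @param step window step in samples.
#' @return object of class `impulse_response`: `lags` (s), `corr_fw`,
#'   `corr_bw`, chance `band` (2.5/97.5 percentiles per lag),
#'   `decay_lag_s` (first post-peak lag staying inside the band).
#' @export
run_impulse_response <- function(amplitude = 1.2, trial_s = 10,
                                 n_trials = 25, seed = 1,
                                 config = network_config(),
                                 max_lag_s = 1.5, n_shuffle = 100,
                                 step = 2) {
  net <- alpha_network(config)
  null <- .experiment_null(net, amplitude, seed = seed)
  burn <- 1
  fw_list <- bw_list <- st_list <- list()
  for (tr in seq_len(n_trials)) {
    stim <- make_random_step_stimulus(amplitude, burn + trial_s,
                                      seed = seed + 500 + tr)
    wf <- classify_trial(net, stim, duration = burn + trial_s,
                         seed = seed + tr, null = null, step = step)
    w <- wf$windows
    sel <- w$time >= burn
    stim_w <- stimulus_trace(stim, round((burn + trial_s) * 1000),
                             0.001)[round(w$time * 1000) + 1]
    fw_list[[tr]] <- as.numeric(w$state[sel] == "FW")
    bw_list[[tr]] <- as.numeric(w$state[sel] == "BW")
    st_list[[tr]] <- as.numeric(stim_w[sel] > 0)
  }
  fs_w <- 100 / step
  lags <- seq(0, max_lag_s, by = 1 / fs_w)
  xcorr <- function(s, r) {
    vapply(seq_along(lags) - 1, function(L) {
      n <- length(s) - L
      a <- s[seq_len(n)]; b <- r[seq_len(n) + L]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    }, numeric(1))
  }
  corr_fw <- rowMeans(vapply(seq_len(n_trials), function(i)
    xcorr(st_list[[i]], fw_list[[i]]), numeric(length(lags))))
  corr_bw <- rowMeans(vapply(seq_len(n_trials), function(i)
    xcorr(st_list[[i]], bw_list[[i]]), numeric(length(lags))))
  ## chance band: shuffle stimulus-response trial pairing
  sh <- matrix(NA_real_, length(lags), n_shuffle)
  for (k in seq_len(n_shuffle)) {
    perm <- sample(n_trials)
    while (any(perm == seq_len(n_trials)) && n_trials > 3)
      perm <- sample(n_trials)
    sh[, k] <- rowMeans(vapply(seq_len(n_trials), function(i)
      xcorr(st_list[[perm[i]]], fw_list[[i]]), numeric(length(lags))))
  }
  band <- t(apply(sh, 1, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
  peak <- which.max(corr_fw)
  inside <- corr_fw >= band[, 1] & corr_fw <= band[, 2]
  hold <- max(1, round(0.1 * fs_w))   # must stay inside ~one cycle
  decay <- NA_real_
  for (i in seq(peak + 1, length(lags))) {
    if (all(inside[i:min(i + hold, length(lags))])) {
      decay <- lags[i]; break
    }
  }
  structure(list(lags = lags, corr_fw = corr_fw, corr_bw = corr_bw,
                 band = band, decay_lag_s = decay, n_trials = n_trials),
            class = "impulse_response")
}

#' FW/BW probability time-course across repeated trials
#'
#' Runs `n_runs` trials of DC stimulation followed by rest and computes
#' the across-trial probability of each wave state per time point, plus
#' the onset latency ("time to first peak") and the slope-corrected
#' return-to-baseline latency after stimulus offset.
#'
#' @param amplitude stimulus current, nA (threshold-level by default).
#' @param stim_s,rest_s stimulus-on and post-offset rest durations, s.
#' @param n_runs trials.
#' @param seed base seed.
#' @param config a [network_config].
#' @param burn_in_s pre-stimulus seconds; the default leaves the
#'   network time to relax from its synchronized initial state, and the
#'   window from 0.3 s after relaxation to 0.3 s before onset serves as
#'   the baseline.
#' @param step window step in samples.
#' @param smooth_s smoothing window applied to the probability
#'   time-courses before latency extraction, seconds.
#' @return object of class `state_timecourse`: `time` (s, 0 = stimulus
#'   onset), `p_fw`, `p_bw`, `log_ratio`, `time_to_first_peak_ms`,
#'   `return_to_baseline_ms`.
#' @export
run_state_timecourse <- function(amplitude = 0.88, stim_s = 5,
                                 rest_s = 5, n_runs = 100, seed = 1,
                                 config = network_config(),
                                 burn_in_s = 3, step = 1,
                                 smooth_s = 0.05) {
  net <- alpha_network(config)
  null <- .experiment_null(net, amplitude, seed = seed)
  duration <- burn_in_s + stim_s + rest_s
  acc_fw <- acc_bw <- NULL
  for (r in seq_len(n_runs)) {
    wf <- classify_trial(net,
                         make_dc_stimulus(amplitude, burn_in_s,
                                          burn_in_s + stim_s),
                         duration = duration, seed = seed + r,
                         null = null, step = step)
    w <- wf$windows
    if (is.null(acc_fw)) {
      acc_fw <- acc_bw <- numeric(nrow(w))
      times <- w$time
    }
    acc_fw <- acc_fw + (w$state == "FW")
    acc_bw <- acc_bw + (w$state == "BW")
  }
  p_fw <- acc_fw / n_runs
  p_bw <- acc_bw / n_runs
  fs_w <- 100 / step
  k <- max(1, round(smooth_s * fs_w))
  smooth <- function(x) {
    y <- stats::filter(x, rep(1 / k, k), sides = 2)
    y[is.na(y)] <- x[is.na(y)]
    as.numeric(y)
  }
  pf <- smooth(p_fw)
  tt <- times - burn_in_s           # 0 = stimulus onset
  ## time to first peak: the onset transient can saturate the
  ## probability, so the "first local maximum" is read as the first
  ## contiguous near-maximal run after onset (within one binomial
  ## standard error of the running maximum), reported at its midpoint
  post <- which(tt > 0 & tt <= 0.5)
  ttfp <- NA_real_
  pmax_on <- max(pf[post])
  tol <- max(0.02, sqrt(pmax_on * (1 - pmax_on) / n_runs), 1 / n_runs)
  at_peak <- pf[post] >= pmax_on - tol
  i0 <- which(at_peak)[1]
  if (!is.na(i0)) {
    j <- i0
    while (j < length(at_peak) && at_peak[j + 1]) j <- j + 1
    ttfp <- (tt[post[i0]] + tt[post[j]]) / 2 * 1000
  }
  ## return to baseline: linear-slope-corrected post-offset re-entry.
  ## The baseline window ends 0.3 s before onset: the zero-phase FIR
  ## smears the onset transition backward by up to ~2 filter half-widths.
  base_sel <- tt >= -(burn_in_s - 1) & tt <= -0.3
  if (!any(base_sel)) base_sel <- tt < 0
  ## band width from the raw (unsmoothed) baseline probability: the
  ## smoothed trace understates the trial-count noise and makes the
  ## re-entry time degenerate
  base_mu <- mean(p_fw[base_sel]); base_sd <- stats::sd(p_fw[base_sel])
  off <- stim_s
  post_off <- which(tt >= off)
  tail_sel <- which(tt >= off + rest_s - 2)
  dtail <- data.frame(t = tt[tail_sel], y = p_fw[tail_sel])
  dtfit <- stats::lm(y ~ t, data = dtail)
  trend <- stats::predict(dtfit, newdata = data.frame(t = tt[post_off]))
  corrected <- p_fw[post_off] - (trend - mean(dtail$y))
  inband <- abs(corrected - base_mu) <= 2 * base_sd
  rtb <- NA_real_
  hit <- which(inband)
  if (length(hit)) rtb <- (tt[post_off[hit[1]]] - off) * 1000
  structure(list(time = tt, p_fw = p_fw, p_bw = p_bw,
                 log_ratio = log((p_fw + 1e-3) / (p_bw + 1e-3)),
                 time_to_first_peak_ms = ttfp,
                 return_to_baseline_ms = rtb,
                 stim_s = stim_s, n_runs = n_runs),
            class = "state_timecourse")
}

#' @export
print.state_timecourse <- function(x, ...) {
  cat(sprintf("State time-course over %d runs (%g s stimulation)\n",
              x$n_runs, x$stim_s))
  cat(sprintf("  time to first FW peak: %.0f ms; return to baseline: %.0f ms\n",
              x$time_to_first_peak_ms, x$return_to_baseline_ms))
  invisible(x)
}

#' @export
plot.state_timecourse <- function(x, ...) {
  graphics::plot(x$time, x$p_fw, type = "l", col = "#2166ac",
                 ylim = c(0, max(x$p_fw, x$p_bw)),
                 xlab = "time from stimulus onset (s)",
                 ylab = "P(state)", ...)
  graphics::lines(x$time, x$p_bw, col = "#b2182b")
  graphics::rect(0, -1, x$stim_s, 2, col = grDevices::adjustcolor("grey", 0.3),
                 border = NA)
  invisible(x)
}

#' Effect of single-weight variations on the wave-state response
#'
#' Re-runs the state time-course while varying one synaptic weight
#' (jointly for all areas): the Layer-4 recurrent inhibition (input
#' adaptation) or the inter-areal infragranular feedback.
#'
#' @param param `"w_l4in_l4x"` or `"w_igib_igib_fb"`.
#' @param values weight values to test.
#' @param amplitude,stim_s,rest_s,n_runs,seed,config,step see
#'   [run_state_timecourse].
#' @return list of `state_timecourse` objects, one per value, with the
#'   values as names.
#' @export
run_parameter_variation <- function(param = c("w_l4in_l4x",
                                              "w_igib_igib_fb"),
                                    values, amplitude = 0.88,
                                    stim_s = 5, rest_s = 5, n_runs = 20,
                                    seed = 1, config = network_config(),
                                    step = 2) {
  param <- match.arg(param)
  out <- list()
  for (v in values) {
    cfg <- config
    cfg[[param]] <- v
    out[[as.character(v)]] <-
      run_state_timecourse(amplitude, stim_s, rest_s, n_runs = n_runs,
                           seed = seed, config = cfg, step = step)
  }
  out
}

#' Band-limited oscillatory power of a trace
#'
#' Welch power integrated over a band.
#'
#' @param x trace.
#' @param fs sampling rate, Hz.
#' @param band Hz.
#' @return scalar power.
#' @export
band_power <- function(x, fs, band = c(7, 13)) {
  ps <- welch_psd(x, fs)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  sum(ps$power[sel]) * (ps$freq[2] - ps$freq[1])
}

#' Spectral analysis of node types vs input current
#'
#' Welch spectra of supragranular (SG_X) and infragranular (IG_IB)
#' activity during stimulation at each current (and at rest), averaged
#' over areas and runs; peak frequencies in the 5-15 Hz band.
#'
#' @param currents nA values (0 is treated as rest).
#' @param n_runs runs per current.
#' @param duration analysed seconds per run (after 1 s burn-in).
#' @param seed base seed.
#' @param config a [network_config].
#' @param seg_s Welch segment length, seconds (sets the spectral
#'   resolution of the peak estimates).
#' @return object of class `spectral_summary`: data.frame `peaks`
#'   (current, node, peak_hz, power), list `spectra`.
#' @export
run_spectral_analysis <- function(currents = seq(0, 2, by = 0.25),
                                  n_runs = 4, duration = 6, seed = 1,
                                  config = network_config(),
                                  seg_s = 4) {
  net <- alpha_network(config)
  burn <- 1
  peaks <- NULL; spectra <- list()
  for (ci in seq_along(currents)) {
    I <- currents[ci]
    acc <- list(SGX = 0, IGIB = 0)
    for (r in seq_len(n_runs)) {
      stim <- if (I > 0)
        make_dc_stimulus(I, burn, burn + duration) else NULL
      tr <- simulate(net, duration = burn + duration,
                     seed = seed + 100 * ci + r, stimulus = stim)
      for (node in c("SGX", "IGIB")) {
        xm <- node_rates(tr, node)[-(1:(burn * 1000)), , drop = FALSE]
        for (a in seq_len(ncol(xm))) {
          ps <- welch_psd(xm[, a], 1000, seg_s = seg_s)
          sel <- ps$freq <= 50
          acc[[node]] <- acc[[node]] + ps$power[sel] / ncol(xm) / n_runs
        }
        freq <- ps$freq[sel]
      }
    }
    for (node in c("SGX", "IGIB")) {
      p <- acc[[node]]
      insel <- which(freq >= 5 & freq <= 15)
      peaks <- rbind(peaks, data.frame(
        current = I, node = node,
        peak_hz = peak_interp(freq, p, insel),
        alpha_power = sum(p[freq >= 7 & freq <= 13])))
    }
    spectra[[ci]] <- list(current = I, freq = freq, sgx = acc$SGX,
                          igib = acc$IGIB)
  }
  structure(list(peaks = peaks, spectra = spectra, currents = currents),
            class = "spectral_summary")
}

#' Peak-frequency increase over the suprathreshold range
#'
#' Difference in peak frequency between the highest and the lowest
#' suprathreshold current, per node type.
#'
#' @param spec a `spectral_summary`.
#' @param threshold_nA reversal threshold, nA.
#' @return named numeric vector (`SGX`, `IGIB`), Hz.
#' @export
suprathreshold_increase <- function(spec, threshold_nA = 0.88) {
  out <- c(SGX = NA_real_, IGIB = NA_real_)
  for (node in names(out)) {
    p <- spec$peaks[spec$peaks$node == node &
                      spec$peaks$current > threshold_nA, ]
    p <- p[order(p$current), ]
    if (nrow(p) >= 2)
      out[node] <- p$peak_hz[nrow(p)] - p$peak_hz[1]
  }
  out
}

#' Inter-areal delay sweep in full and FW-isolated configurations
#'
#' Peak frequency and alpha power of SG_X and IG_IB activity during
#' suprathreshold stimulation as a function of the inter-areal delay,
#' for the full model and for the isolated feedforward pathway
#' (infragranular nodes reduced to passive relays, inter-areal
#' infragranular feedback removed).
#'
#' @param delays_s delay values, seconds.
#' @param amplitude stimulus current, nA.
#' @param n_runs runs per condition.
#' @param duration analysed seconds (after 1 s burn-in).
#' @param seed base seed.
#' @param config base [network_config].
#' @return data.frame with `delay_ms`, `configuration`, `node`,
#'   `peak_hz`, `alpha_power`.
#' @export
run_delay_sweep <- function(delays_s = seq(0.004, 0.04, by = 0.004),
                            amplitude = 1.2, n_runs = 4, duration = 6,
                            seed = 1, config = network_config()) {
  out <- NULL
  burn <- 1
  for (iso in c(FALSE, TRUE)) {
    for (di in seq_along(delays_s)) {
      cfg <- config
      cfg$delay_cx <- delays_s[di]
      cfg$fw_isolated <- iso
      net <- alpha_network(cfg)
      acc <- list(SGX = NULL, IGIB = NULL)
      for (r in seq_len(n_runs)) {
        tr <- simulate(net, duration = burn + duration,
                       seed = seed + 1000 * di + 100 * iso + r,
                       stimulus = make_dc_stimulus(amplitude, burn,
                                                   burn + duration))
        for (node in names(acc)) {
          xm <- node_rates(tr, node)[-(1:(burn * 1000)), , drop = FALSE]
          x <- rowMeans(xm)
          ps <- welch_psd(x, 1000)
          acc[[node]] <- if (is.null(acc[[node]])) ps$power / n_runs
          else acc[[node]] + ps$power / n_runs
        }
        freq <- ps$freq
      }
      for (node in names(acc)) {
        insel <- freq >= 5 & freq <= 15
        out <- rbind(out, data.frame(
          delay_ms = delays_s[di] * 1000,
          configuration = if (iso) "fw_isolated" else "full",
          node = node,
          peak_hz = freq[insel][which.max(acc[[node]][insel])],
          alpha_power = sum(acc[[node]][freq >= 7 & freq <= 13])))
      }
    }
  }
  out
}

#' Epoch-triggered spatial activity maps
#'
#' Averages SG_X and IG_IB firing rates across epochs centered on the
#' band-limited activity peaks of a reference node (Cx_2 IG_IB by
#' default, the intersection of the FW and BW pathways at the center of
#' the network).
#'
#' @param traces a `sim_traces`.
#' @param center_node reference node name.
#' @param half_width_s epoch half width, seconds.
#' @param band peak-detection band, Hz.
#' @param burn_in_s discarded seconds.
#' @return list with arrays `sgx`, `igib` (areas x time) and the epoch
#'   `lag_s` axis.
#' @export
epoch_triggered_maps <- function(traces, center_node = "Cx2.IGIB",
                                 half_width_s = 0.15, band = c(7, 13),
                                 burn_in_s = 1) {
  fs <- 1 / traces$dt
  x <- traces$rates[, center_node]
  bp <- bandpass_fir(x - mean(x), band, fs)
  i0 <- round(burn_in_s * fs); n <- length(x)
  hw <- round(half_width_s * fs)
  pk <- which(diff(sign(diff(bp))) == -2) + 1
  pk <- pk[pk > i0 + hw & pk < n - hw & bp[pk] > 0]
  lag <- (-hw:hw) / fs
  avg_map <- function(node) {
    xm <- node_rates(traces, node)
    out <- matrix(0, ncol(xm), 2 * hw + 1)
    for (p in pk) out <- out + t(xm[(p - hw):(p + hw), ])
    out / length(pk)
  }
  list(sgx = avg_map("SGX"), igib = avg_map("IGIB"), lag_s = lag,
       n_epochs = length(pk))
}

#' Pulvinar engagement sweep
#'
#' FW/BW probabilities as a function of the pulvino-cortical weight and
#' the stimulus current, the baseline FW/BW log-ratio at zero current,
#' and epoch-triggered spatial maps of the spontaneous-FW state.
#'
#' @param w_grid pulvino-cortical weights in `[0, 2.2]`.
#' @param currents stimulus currents, nA.
#' @param n_runs runs per cell.
#' @param duration per-trial stimulated/rest seconds.
#' @param seed base seed.
#' @param config base [network_config] (the pulvinar toggle and weight
#'   are overridden).
#' @param step window step in samples.
#' @return object of class `pulvinar_sweep`: data.frame `grid`
#'   (w, current, p_fw, p_bw), `baseline_log_ratio` per weight.
#' @export
run_pulvinar_sweep <- function(w_grid = c(0, 1, 2),
                               currents = c(0, 0.5, 1, 1.5, 2),
                               n_runs = 10, duration = 3, seed = 1,
                               config = network_config(),
                               step = 2) {
  out <- NULL
  burn <- 1
  for (w in w_grid) {
    cfg <- config
    cfg$pulvinar_enabled <- w > 0
    cfg$w_pul_l4x <- max(w, 0)
    net <- alpha_network(cfg)
    null <- .experiment_null(net, max(currents), seed = seed)
    for (I in currents) {
      n_fw <- n_bw <- n_tot <- 0
      for (r in seq_len(n_runs)) {
        stim <- if (I > 0)
          make_dc_stimulus(I, burn, burn + duration) else NULL
        wf <- classify_trial(net, stim, duration = burn + duration,
                             seed = seed + round(1000 * w) + 17 * r +
                               round(100 * I),
                             null = null, step = step)
        wsel <- wf$windows$time >= burn + 0.2
        n_fw <- n_fw + sum(wf$windows$state[wsel] == "FW")
        n_bw <- n_bw + sum(wf$windows$state[wsel] == "BW")
        n_tot <- n_tot + sum(wsel)
      }
      out <- rbind(out, data.frame(w = w, current = I,
                                   p_fw = n_fw / n_tot,
                                   p_bw = n_bw / n_tot))
    }
  }
  base <- out[out$current == 0, ]
  structure(list(grid = out,
                 baseline_log_ratio = data.frame(
                   w = base$w,
                   log_ratio = log((base$p_fw + 1e-3) /
                                     (base$p_bw + 1e-3)))),
            class = "pulvinar_sweep")
}

#' Lateralized (two-hemisphere) simulation and per-ROI wave states
#'
#' Simulates two independent thalamo-cortical streams projected to a
#' single EEG, and classifies wave states separately in the two lateral
#' electrode ROIs (reference axes from the folded direction
#' distributions). Optionally applies hemisphere-specific stimulation or
#' pulvino-cortical weights.
#'
#' @param amplitude_left,amplitude_right DC amplitudes per hemisphere,
#'   nA (0 = no stimulation of that side).
#' @param w_pul_left,w_pul_right pulvino-cortical weights (0 disables
#'   the pulvinar for both).
#' @param stim_s stimulated seconds.
#' @param n_runs trials.
#' @param seed base seed.
#' @param config base [network_config].
#' @param step window step in samples.
#' @return object of class `lateralization_result`: `p_fw_left`,
#'   `p_fw_right` (time courses), `time`, per-ROI FW fractions during
#'   stimulation, and the RMS topography over the first 100 ms after
#'   onset.
#' @export
run_lateralization <- function(amplitude_left = 1.2,
                               amplitude_right = 0,
                               w_pul_left = 0, w_pul_right = 0,
                               stim_s = 1, n_runs = 20, seed = 1,
                               config = network_config(), step = 1) {
  cfg <- config
  cfg$hemispheres <- 2
  if (w_pul_left > 0 || w_pul_right > 0) {
    cfg$pulvinar_enabled <- TRUE
    cfg$w_pul_l4x <- max(w_pul_left, w_pul_right)
  }
  net0 <- alpha_network(cfg)
  ## hemisphere-specific pulvinar weights applied on the built table
  if (cfg$pulvinar_enabled) {
    pul_rows <- grepl("^L\\.Pul", net0$conns$src)
    net0$conns$weight[pul_rows] <- w_pul_left
    pul_rows_r <- grepl("^R\\.Pul", net0$conns$src)
    net0$conns$weight[pul_rows_r] <- w_pul_right
  }
  burn <- 1
  duration <- burn + stim_s + 1
  mk_stim <- function(a) if (a > 0)
    make_dc_stimulus(a, burn, burn + stim_s) else NULL
  stim <- list(left = mk_stim(amplitude_left),
               right = mk_stim(amplitude_right))
  ## null from the midline ROI phases of a calibration pair, reused for
  ## both lateral ROIs (threshold is permutation-based, ROI-size driven)
  null_l <- null_r <- NULL
  acc_l <- acc_r <- NULL; rms_topo <- 0
  for (r in seq_len(n_runs)) {
    tr <- simulate(net0, duration = duration, seed = seed + r,
                   stimulus = stim)
    eeg <- eeg_from_traces(tr)
    if (is.null(null_l)) {
      pm_l <- compute_phase(eeg, roi = "left", step = 5)
      pm_r <- compute_phase(eeg, roi = "right", step = 5)
      null_l <- build_null(pm_l)
      null_r <- build_null(pm_r)
    }
    wl <- fit_waves(eeg, roi = "left", null = null_l, step = step)
    wr <- fit_waves(eeg, roi = "right", null = null_r, step = step)
    ## re-classify against the folded lateral reference axis
    ax <- lateral_reference_axis(wl, wr)
    wl$windows$state <- classify_states(wl$windows, null_l, ax)
    wr$windows$state <- classify_states(wr$windows, null_r, ax)
    if (is.null(acc_l)) {
      acc_l <- acc_r <- numeric(nrow(wl$windows))
      times <- wl$windows$time
    }
    acc_l <- acc_l + (wl$windows$state == "FW")
    acc_r <- acc_r + (wr$windows$state == "FW")
    on_i <- round(burn * eeg$fs) + seq_len(round(0.1 * eeg$fs))
    rms_topo <- rms_topo + sqrt(colMeans(eeg$data[on_i, ]^2)) / n_runs
  }
  tt <- times - burn
  stim_sel <- tt > 0 & tt <= stim_s
  structure(list(time = tt, p_fw_left = acc_l / n_runs,
                 p_fw_right = acc_r / n_runs,
                 fw_left = mean((acc_l / n_runs)[stim_sel]),
                 fw_right = mean((acc_r / n_runs)[stim_sel]),
                 rms_topography = rms_topo, n_runs = n_runs),
            class = "lateralization_result")
}

#' @export
print.lateralization_result <- function(x, ...) {
  cat(sprintf("Lateralized simulation over %d runs\n", x$n_runs))
  cat(sprintf("  FW fraction during stimulation: left ROI %.2f, right ROI %.2f\n",
              x$fw_left, x$fw_right))
  invisible(x)
}
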