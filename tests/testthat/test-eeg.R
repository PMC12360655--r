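# EEG forward chain: montage, preprocessing, lead field, noise, projection

test_that("packaged montage and ROI presets have the documented structure", {
  m <- load_montage()
  expect_equal(nrow(m), 64)
  expect_true(all(c("Oz", "Fz", "Iz", "C3", "C4") %in% m$channel))
  # unit-sphere 3D positions
  expect_equal(sqrt(rowSums(as.matrix(m[, c("x", "y", "z")])^2)),
               rep(1, 64), tolerance = 1e-3)
  expect_length(electrode_roi("midline"), 38)
  expect_length(electrode_roi("left"), 20)
  expect_length(electrode_roi("right"), 20)
  expect_false(any(c("Oz", "Fz", "Cz") %in% electrode_roi("left")))
  # lateral ROIs are disjoint and mirror-balanced across the midline
  lf <- electrode_roi("left"); rt <- electrode_roi("right")
  expect_length(intersect(lf, rt), 0)
  expect_true(all(m$x2d[match(lf, m$channel)] < 0))
  expect_true(all(m$x2d[match(rt, m$channel)] > 0))
  expect_equal(sort(abs(m$x2d[match(lf, m$channel)])),
               sort(abs(m$x2d[match(rt, m$channel)])), tolerance = 1e-6)
})

test_that("low-pass + decimation passes DC, attenuates 40 Hz, outputs 100 Hz", {
  fs <- 1000
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  dc <- rep(2.5, length(tt))
  out <- lowpass_decimate(dc, fs = fs)
  expect_equal(length(out), length(tt) / 10)   # exactly 100 Hz
  # unit DC gain away from the filter's edge transients
  expect_equal(out[40:360], rep(2.5, 321), tolerance = 0.01)

  s40 <- sin(2 * pi * 40 * tt)
  f40 <- lowpass_decimate(s40, fs = fs)
  # analytic oracle: |H| = 1/sqrt(1 + (f/fc)^(2*3)) at f = 2*fc, applied
  # twice (zero-phase forward-backward pass)
  gain_expected <- (1 / sqrt(1 + 2^6))^2
  mid <- f40[30:370]
  gain_measured <- stats::sd(mid) / stats::sd(s40)
  expect_equal(gain_measured, gain_expected, tolerance = 0.35)
  expect_lt(gain_measured, 0.05)   # ~ -36 dB in any case

  expect_error(lowpass_decimate(1:5, fs = fs), "short")
})

test_that("pink noise has 1/f power, zero mean, independent realizations", {
  set.seed(11)
  x <- make_pink_noise(1e4)
  expect_equal(mean(x), 0, tolerance = 1e-9)
  sp <- welch_psd(x, fs = 100, seg_s = 20)
  sel <- sp$freq >= 1 & sp$freq <= 40
  fit <- stats::lm(log(sp$power[sel]) ~ log(sp$freq[sel]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.2)

  # independence: compare after differencing (1/f series have slowly
  # decaying autocorrelation, so raw sample correlations are heavy-tailed)
  y <- make_pink_noise(1e4)
  expect_lt(abs(stats::cor(diff(x), diff(y))), 0.05)
})

test_that("spherical lead field is finite, smooth, and strongest near the source", {
  m <- load_montage()
  G <- sphere_leadfield(m, area_dipoles()[, c("x", "y", "z")])
  expect_true(all(is.finite(G)))
  expect_equal(dim(G), c(64, 6))
  # occipital dipole: posterior electrodes see more gain than frontal
  occ <- abs(G[m$channel == "Oz", 1])
  fro <- abs(G[m$channel == "Fpz", 1])
  expect_gt(occ, fro)
})

test_that("projection is linear and lateralized sources lateralize the scalp RMS", {
  set.seed(2)
  src <- matrix(sin(2 * pi * 10 * (1:300) / 100), ncol = 1)
  m <- load_montage()
  e1 <- project_eeg(cbind(src, 0 * src, 0 * src), m, n_noise = 0)
  e2 <- project_eeg(cbind(2 * src, 0 * src, 0 * src), m, n_noise = 0)
  # z-scoring makes the projection amplitude-invariant; scale the output
  expect_equal(e2$data, e1$data, tolerance = 1e-9)

  # left-hemisphere-only source: left electrodes carry more power
  el <- project_eeg(src, m, hemi = "L", n_noise = 0)
  x2d <- m$x2d
  rms <- sqrt(colMeans(el$data^2))
  expect_gt(mean(rms[x2d < -0.2]), mean(rms[x2d > 0.2]))
})

test_that("the noise mixture obeys the drawn SNR in sensor space", {
  set.seed(3)
  src <- matrix(sin(2 * pi * 10 * (1:500) / 100), ncol = 1)
  e0 <- project_eeg(cbind(src, 0 * src, 0 * src), n_noise = 0)
  set.seed(3)
  e5 <- project_eeg(cbind(src, 0 * src, 0 * src), n_noise = 5,
                    snr_range = c(1, 1), snr_space = "sensor")
  nz <- e5$data - e0$data
  # five sources each at snr 1 relative to the signal mixture
  expect_equal(sqrt(mean(nz^2)) / sqrt(mean(e0$data^2)), sqrt(5),
               tolerance = 0.15)
})

test_that("the full chain preserves the source-level direction at the scalp", {
  net <- alpha_network(network_config())
  agree <- total <- 0
  for (s in 1:2) {
    rest <- simulate(net, duration = 4, seed = 300 + s)
    expect_true(all(source_phase_lags(rest)$igib_by_area < 0)) # backward ordering
    wf <- classify_trial(net, NULL, 4, seed = 300 + s, step = 2)
    w <- wf$windows[wf$windows$time >= 1, ]
    cls <- w$state[w$state != "Null"]
    agree <- agree + sum(cls == "BW"); total <- total + length(cls)

    wfs <- classify_trial(net, make_dc_stimulus(1.2, 1, 4), 4,
                          seed = 400 + s, step = 2)
    w2 <- wfs$windows[wfs$windows$time >= 1.3, ]
    cls2 <- w2$state[w2$state != "Null"]
    agree <- agree + sum(cls2 == "FW"); total <- total + length(cls2)
  }
  expect_gt(agree / total, 0.9)
})
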