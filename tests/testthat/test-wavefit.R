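# Phase maps, plane fitting, circular statistics, null and classification

test_that("relative phase maps are referenced, offset-invariant, and recover ramps", {
  m <- load_montage()
  fs <- 100
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  same <- matrix(sin(2 * pi * 10 * tt), length(tt), 64)
  colnames(same) <- m$channel
  pm <- compute_phase(same, fs = fs, channels = m$channel,
                      positions = as.matrix(m[, c("x2d", "y2d")]))
  expect_lt(max(abs(pm$phases)), 1e-6)

  # imposed linear phase ramp along y
  b <- 0.8
  ramp <- sin(outer(2 * pi * 10 * tt, b * m$y2d, "+"))
  colnames(ramp) <- m$channel
  pm2 <- compute_phase(ramp, fs = fs, channels = m$channel,
                       positions = as.matrix(m[, c("x2d", "y2d")]))
  y <- pm2$positions[, 2]
  expected <- b * y - mean(b * y)
  mid <- pm2$phases[seq(50, nrow(pm2$phases) - 50), ]
  err <- sweep(mid, 2, expected)
  expect_lt(max(abs(atan2(sin(err), cos(err)))), 0.05)

  # adding a common offset to all channels leaves the map unchanged
  shifted <- sin(outer(2 * pi * 10 * tt, b * m$y2d, "+") + 1.1)
  colnames(shifted) <- m$channel
  pm3 <- compute_phase(shifted, fs = fs, channels = m$channel,
                       positions = as.matrix(m[, c("x2d", "y2d")]))
  inner <- seq(30, nrow(pm3$phases) - 30)   # away from filter edges
  d <- pm3$phases[inner, ] - pm2$phases[inner, ]
  expect_lt(max(abs(atan2(sin(d), cos(d)))), 1e-4)

  expect_error(compute_phase(same, band = c(7, 60), fs = fs,
                             channels = m$channel,
                             positions = as.matrix(m[, c("x2d", "y2d")])),
               "Nyquist")
})

test_that("plane fit recovers grid-generated parameters and handles degeneracy", {
  m <- load_montage()
  roi <- electrode_roi("midline")
  pos <- as.matrix(m[match(roi, m$channel), c("x2d", "y2d")])
  grid <- plane_fit_grid(pos)

  set.seed(8)
  for (g in sample(which(grid$xi > 0), 12)) {
    theta <- grid$pred[g, ] + stats::runif(1, -pi, pi)
    fit <- plane_fit(matrix(theta, 1), pos, grid = grid)
    expect_lt(abs(wrap_pi(fit$alpha - grid$alpha[g])), 2 * pi / 60 + 1e-9)
    expect_lt(abs(fit$xi - grid$xi[g]), diff(grid$xi[c(1, 61)]) + 1e-9)
    expect_gt(fit$rbar, 0.999)
  }

  # spatially uniform phases: xi = 0, direction undefined
  fit0 <- plane_fit(matrix(0.3, 1, nrow(pos)), pos)
  expect_equal(fit0$xi, 0)
  expect_true(is.na(fit0$alpha))

  # adding pi to every phase changes nothing
  g <- which(grid$xi > 0)[100]
  f1 <- plane_fit(matrix(grid$pred[g, ], 1), pos, grid = grid)
  f2 <- plane_fit(matrix(grid$pred[g, ] + pi, 1), pos, grid = grid)
  expect_equal(f1[, c("alpha", "xi", "rbar")],
               f2[, c("alpha", "xi", "rbar")], tolerance = 1e-9)

  expect_error(plane_fit(matrix(0, 1, 2), matrix(rnorm(4), 2)), "3 electrodes")
  expect_error(plane_fit(matrix(0, 1, 4),
                         cbind(1:4, 2 * (1:4) + 3)), "collinear")
})

test_that("coarse grid argmax agrees with a dense brute-force oracle", {
  set.seed(5)
  pos <- matrix(stats::runif(10, -1.5, 1.5), 5, 2)
  coarse <- plane_fit_grid(pos, n_dir = 60, n_xi = 30)
  dense <- plane_fit_grid(pos, n_dir = 600, n_xi = 90)
  for (k in 1:5) {
    theta <- wrap_pi(0.9 * pos[, 1] - 0.5 * pos[, 2] +
                       stats::rnorm(5, sd = 0.05 * k))
    fc <- plane_fit(matrix(theta, 1), pos, grid = coarse)
    fd <- plane_fit(matrix(theta, 1), pos, grid = dense)
    expect_lt(abs(wrap_pi(fc$alpha - fd$alpha)), 2 * pi / 60 + 1e-9)
    expect_lt(abs(fc$xi - fd$xi), coarse$xi[61] + 1e-9)
  }
})

test_that("circular correlation behaves as the circular analogue of r", {
  set.seed(1)
  th <- stats::runif(38, -2, 2)
  expect_equal(circ_corr(th, th), 1, tolerance = 1e-12)
  expect_equal(circ_corr(th, -th), -1, tolerance = 1e-6)
  m <- replicate(1000, circ_corr(stats::runif(38, -pi, pi),
                                 stats::runif(38, -pi, pi)))
  expect_lt(abs(mean(m)), 0.02)
  expect_lt(stats::sd(m), 0.3)
})

test_that("resultant length is 1 exactly for constant residuals", {
  pos <- as.matrix(load_montage()[1:10, c("x2d", "y2d")])
  grid <- plane_fit_grid(pos)
  g <- 500
  fit <- plane_fit(matrix(grid$pred[g, ] + 1.234, 1), pos, grid = grid)
  expect_equal(fit$rbar, 1, tolerance = 1e-9)
})

test_that("the permutation null separates planar waves from channel noise", {
  set.seed(21)
  wave <- make_planar_scalp_wave(pi / 2, xi = 1, duration = 4,
                                 noise_sd = 0.3, seed = 22)
  pm <- compute_phase(wave, step = 2)
  null <- build_null(pm)
  fit <- plane_fit(pm)
  expect_gt(mean(fit$rho > null$threshold), 0.95)

  noise <- matrix(stats::rnorm(400 * 64), 400, 64)
  colnames(noise) <- load_montage()$channel
  pmn <- compute_phase(noise, fs = 100, channels = load_montage()$channel,
                       positions = as.matrix(load_montage()[, c("x2d", "y2d")]))
  nn <- build_null(pmn)
  fn <- plane_fit(pmn)
  frac <- mean(fn$rho > nn$threshold)
  expect_gt(frac, 0.005); expect_lt(frac, 0.2)   # ~5% by construction
})

test_that("classification applies the axis and significance rules", {
  fit <- data.frame(alpha = c(-pi / 2, -pi / 2, pi / 2, 0, NA),
                    xi = c(1, 1, 1, 1, 0),
                    rbar = 1,
                    rho = c(0.9, 0.1, 0.9, 0.9, 0.9))
  st <- classify_states(fit, null = 0.5)
  expect_equal(as.character(st),
               c("FW", "Null", "BW", "Null", "Null"))
})

test_that("the lateral reference axis folds FW and BW into one distribution", {
  mkfit <- function(alphas, states) {
    structure(list(windows = data.frame(alpha = alphas,
                                        state = factor(states,
                                                       c("FW", "BW", "Null")))),
              class = "wavefit")
  }
  # all occipito-frontal: axis is the occipito-frontal gradient direction
  f <- mkfit(rep(-pi / 2, 20), rep("FW", 20))
  expect_equal(lateral_reference_axis(f), -pi / 2, tolerance = 1e-9)
  # left ROI tilted +0.3, right ROI tilted -0.3: mirrored merge -> midline
  fl <- mkfit(rep(-pi / 2 + 0.3, 10), rep("FW", 10))
  fr <- mkfit(rep(-pi / 2 + 0.3, 10), rep("FW", 10))  # mirrored inside
  ax <- lateral_reference_axis(fl, fr)
  expect_lt(abs(wrap_pi(ax + pi / 2)), 0.01)   # symmetric -> midline
  # a single classified window defines the axis by itself
  f1 <- mkfit(c(-1.2), c("FW"))
  expect_equal(lateral_reference_axis(f1), -1.2)
  # BW windows are reflected through pi before merging
  fb <- mkfit(rep(pi / 2, 5), rep("BW", 5))
  expect_equal(lateral_reference_axis(fb), -pi / 2, tolerance = 1e-9)
})

test_that("fit_waves returns a complete classed object with methods", {
  wave <- make_planar_scalp_wave(pi / 2, xi = 1, duration = 3,
                                 noise_sd = 0.2, seed = 30)
  wf <- fit_waves(wave, step = 2)
  expect_s3_class(wf, "wavefit")
  expect_true(all(c("time", "alpha", "xi", "rbar", "rho", "state") %in%
                    names(wf$windows)))
  expect_true(all(wf$windows$rbar >= 0 & wf$windows$rbar <= 1))
  expect_true(all(wf$windows$rho >= -1 & wf$windows$rho <= 1))
  expect_output(print(wf), "Traveling-wave fit")
  s <- summary(wf)
  expect_output(print(s), "Wave-state summary")
  expect_named(coef(wf), c("p_fw", "p_bw", "alpha_fw", "alpha_bw",
                           "xi_fw", "xi_bw"))
  expect_gt(coef(wf)[["p_fw"]], 0.9)
  quiet_plot(plot(wf))
})
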