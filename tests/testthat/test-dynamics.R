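# Mean-field kernels: FI curve, OU noise, synaptic gating, input summation

test_that("FI curve matches its closed form, including the singular point", {
  p <- fi_params()   # lambda 270, beta 108, theta 0.154

  # singular branch: lambda*I = beta at I = 0.4 -> r = 1/theta
  expect_equal(fi_rate(0.4, p), 1 / 0.154, tolerance = 1e-9)

  # closed-form oracle evaluated independently of the implementation
  closed <- function(I) {
    x <- 270 * I - 108
    x / (1 - exp(-0.154 * x))
  }
  expect_equal(fi_rate(0.5, p), closed(0.5), tolerance = 1e-12)
  expect_equal(fi_rate(0.5, p), 27.4293, tolerance = 1e-4)
  expect_equal(fi_rate(0, p), closed(0), tolerance = 1e-12)
  expect_lt(fi_rate(0, p), 1e-5)   # effectively silent below threshold

  expect_error(fi_rate(NaN, p), "non-finite")
})

test_that("FI curve is continuous at the kink and nondecreasing", {
  p <- fi_params()
  at_kink <- 1 / p$theta_curvature
  eps <- 1e-9 / p$lambda_slope
  expect_lt(abs(fi_rate(0.4 + eps, p) - at_kink), 1e-6 * at_kink)
  expect_lt(abs(fi_rate(0.4 - eps, p) - at_kink), 1e-6 * at_kink)

  grid <- seq(-1, 3, length.out = 2001)
  r <- fi_rate(grid, p)
  expect_true(all(diff(r) >= -1e-12))
  expect_true(all(is.finite(r)) && all(r >= 0))
})

test_that("OU noise decays exponentially without diffusion and holds zero", {
  st <- noise_state(epsilon = 1, tau_eps = 0.002, sigma_eps = 0)
  dt <- 1e-4
  for (i in 1:100) st <- ou_step(st, dt)
  # discrete-time decay oracle: (1 - dt/tau)^n
  expect_equal(st$epsilon, (1 - dt / 0.002)^100, tolerance = 1e-12)

  st0 <- noise_state(epsilon = 0, sigma_eps = 0)
  for (i in 1:50) st0 <- ou_step(st0, 1e-4)
  expect_identical(st0$epsilon, 0)
  expect_error(ou_step(st0, -1), "dt")
})

test_that("OU noise has stationary SD sigma_eps and lag-tau autocorrelation 1/e", {
  set.seed(42)
  st <- noise_state(epsilon = 0, tau_eps = 0.002, sigma_eps = 0.025)
  dt <- 2e-4
  n <- 2e5
  eps <- numeric(n)
  for (i in seq_len(n)) {
    st <- ou_step(st, dt)
    eps[i] <- st$epsilon
  }
  eps <- eps[-(1:1000)]
  expect_equal(stats::sd(eps), 0.025, tolerance = 0.05)
  lag <- round(0.002 / dt)
  ac <- stats::cor(eps[-(1:lag)], eps[seq_len(length(eps) - lag)])
  expect_equal(ac, exp(-1), tolerance = 0.1)
})

test_that("synaptic gate decays, saturates, and matches its equilibrium", {
  fast <- synapse_spec(1, "fast_exc")
  # decay oracle: r = 0 held -> discrete exponential decay
  s <- 0.5
  for (i in 1:40) s <- as.numeric(synapse_step(s, 0, fast, 1e-3))
  expect_equal(s, 0.5 * (1 - 1e-3 / 0.02)^40, tolerance = 1e-10)

  # equilibrium oracle solved from the gating ODE: s* = g r tau/(1 + g r tau)
  s <- 0
  for (i in 1:5000) s <- as.numeric(synapse_step(s, 10, fast, 1e-3))
  expect_equal(s, 0.16 / 1.16, tolerance = 1e-3)
  expect_equal(synapse_equilibrium(10, fast), 0.16 / 1.16, tolerance = 1e-12)

  # equilibrium strictly increases with rate and stays below 1
  rates <- seq(0, 500, by = 10)
  eq <- synapse_equilibrium(rates, fast)
  expect_true(all(diff(eq) > 0))
  expect_true(all(eq < 1))

  expect_error(synapse_step(0, -1, fast, 1e-3), "negative")
})

test_that("gates stay in [0,1] for all synapse classes at 1 ms and rates <= 200 Hz", {
  classes <- c("fast_exc", "slow_exc", "fast_inh", "slow_inh", "ig_self_exc")
  for (cl in classes) {
    w <- if (grepl("inh", cl)) -1 else 1
    sp <- synapse_spec(w, cl)
    for (r in c(0, 25, 100, 200)) {
      s <- 0
      for (i in 1:400) {
        s <- as.numeric(synapse_step(s, r, sp, 1e-3))
        expect_gte(s, 0)
        expect_lte(s, 1)
      }
    }
  }
})

test_that("node input sums weighted gates, base, noise and external currents", {
  expect_equal(node_input(), 0.33)
  inc <- list(list(spec = synapse_spec(2, "fast_exc"), s_gate = 0.1),
              list(spec = synapse_spec(-1.2, "slow_inh"), s_gate = 0.05))
  expect_equal(node_input(inc), 0.33 + 0.2 - 0.06)
  expect_equal(node_input(inc, i_external = 1.2) - node_input(inc), 1.2)
})

test_that("synapse specs validate weight sign and class", {
  expect_error(synapse_spec(1, "no_such_class"), "unknown")
  expect_error(synapse_spec(1, "fast_inh"), "positive")
  expect_error(synapse_spec(-1, "fast_exc"), "negative")
})
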