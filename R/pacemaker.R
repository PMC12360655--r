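## The infragranular pacemaker: a homogeneous population of Izhikevich
## neurons with intrinsic ~10 Hz bursting, coupled to the mean-field
## network through fixed input/output conversions.

#' Izhikevich neuron parameters
#'
#' Defaults produce short bursts of spikes at regularly paced intervals of
#' roughly 100 ms at the baseline drive of the network.
#'
#' @param a recovery time scale (1/ms, dimensionless in the standard form).
#' @param b recovery sensitivity.
#' @param c reset potential, mV.
#' @param d recovery reset increment.
#' @return An object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.0067, b = 0.2, c = -50, d = 2) {
  structure(list(a = a, b = b, c = c, d = d), class = "izhikevich_params")
}

#' Pacemaker population state
#'
#' @param n_neurons population size (350 by default).
#' @param p an [izhikevich_params] object.
#' @param v,u optional initial membrane potential (mV) and recovery
#'   variable vectors; default is the resting state `v = -70`, `u = b*v`.
#' @return An object of class `population_state`.
#' @export
population_state <- function(n_neurons = 350, p = izhikevich_params(),
                             v = NULL, u = NULL) {
  stopifnot(n_neurons >= 1)
  if (is.null(v)) v <- rep(-70, n_neurons)
  if (is.null(u)) u <- p$b * v
  stopifnot(length(v) == n_neurons, length(u) == n_neurons)
  structure(list(v = v, u = u, n_neurons = n_neurons, params = p),
            class = "population_state")
}

#' One membrane step of the Izhikevich population
#'
#' Applies `dv/dt = 0.04 v^2 + 5v + 140 - u + I` and `du/dt = a(bv - u)`
#' (time in ms) with the spike-and-reset rule `v >= 30 mV: v <- c,
#' u <- u + d`, using two 0.5 ms explicit Euler substeps per call
#' (`dt = 1 ms`). Reset is applied at the start of each substep, so a
#' neuron flagged as spiking is reset before integrating further.
#'
#' @param state a [population_state].
#' @param per_neuron_current numeric vector of per-neuron input currents
#'   (Izhikevich units), length `n_neurons`.
#' @param dt node time step in seconds (default 0.001; the membrane
#'   substeps are `dt/2`).
#' @return list with the updated `state` and logical `spike_mask` marking
#'   neurons that spiked during the step.
#' @export
izhikevich_step <- function(state, per_neuron_current, dt = 0.001) {
  stopifnot(length(per_neuron_current) == state$n_neurons)
  if (any(!is.finite(state$v))) stop("NaN/Inf in membrane state (divergence)")
  p <- state$params
  v <- state$v; u <- state$u
  h <- dt * 1000 / 2               # substep in ms
  spiked <- rep(FALSE, state$n_neurons)
  for (sub in 1:2) {
    fired <- v >= 30
    spiked <- spiked | fired
    v[fired] <- p$c
    u[fired] <- u[fired] + p$d
    v_old <- v
    v <- v + h * (0.04 * v_old^2 + 5 * v_old + 140 - u + per_neuron_current)
    u <- u + h * (p$a * (p$b * v_old - u))
  }
  state$v <- v; state$u <- u
  list(state = state, spike_mask = spiked)
}

#' Instantaneous population spike rate
#'
#' Fraction of the population spiking in the current step.
#'
#' @param spike_mask logical vector from [izhikevich_step].
#' @return fraction in `[0, 1]`.
#' @export
population_rate <- function(spike_mask) {
  mean(spike_mask)
}

#' Per-neuron input currents from the node current
#'
#' `I_n = 4*I_node + mu_eps + sigma_eps*N(0,1)`, drawn independently per
#' neuron each step. This noise is the only source of heterogeneity in the
#' population.
#'
#' @param node_current summed mean-field input current to the node, nA.
#' @param mu_eps,sigma_eps mean and SD of the per-neuron Gaussian drive.
#' @param n_neurons population size.
#' @return numeric vector of per-neuron currents.
#' @export
spiking_input <- function(node_current, mu_eps = 6, sigma_eps = 4,
                          n_neurons = 350) {
  4 * node_current + mu_eps + sigma_eps * stats::rnorm(n_neurons)
}

#' Simulate an isolated pacemaker population
#'
#' Runs one pacemaker node with its mean-field self-excitation
#' (`w = 0.7`, infragranular self-excitatory class) driven by a prescribed
#' node-current time series, and returns the population rate trace at the
#' node resolution (1 kHz for `dt = 1 ms`; membrane equations run at two
#' 0.5 ms substeps per node step).
#'
#' The population output that enters any mean-field synapse is
#' `gain * fraction / dt` — an instantaneous rate in Hz scaled by the
#' pacemaker output gain (see [network_config] for the calibrated default).
#'
#' @param duration seconds to simulate (`>= 1` for spectral estimates), or
#'   `NULL` to take the length of `drive`.
#' @param drive node input current in nA: a scalar (held constant) or a
#'   vector with one value per 1 ms step. Default is the base current.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param gain pacemaker output gain.
#' @param n_neurons,params,mu_eps,sigma_eps population setup.
#' @param w_self self-excitation weight (Table-style default 0.7).
#' @param noise_mode `"white"` (per-step) or `"quenched"` (frozen
#'   per-neuron) Gaussian drive.
#' @param dt node step, seconds.
#' @return object of class `pacemaker_trace`: list with `rate` (Hz),
#'   `fraction` (per-step spiking fraction), `dt` and the call parameters.
#' @export
simulate_population <- function(duration = 10, drive = 0.33, seed = NULL,
                                gain = pacemaker_gain_default(),
                                n_neurons = 350,
                                params = izhikevich_params(),
                                mu_eps = 6, sigma_eps = 4,
                                w_self = 0.7,
                                noise_mode = c("quenched", "white"),
                                dt = 0.001) {
  noise_mode <- match.arg(noise_mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) {
    stopifnot(length(drive) > 1)
    n_steps <- length(drive)
  } else {
    n_steps <- round(duration / dt)
  }
  if (length(drive) == 1) drive <- rep(drive, n_steps)
  stopifnot(length(drive) == n_steps)
  cls <- .synapse_classes$ig_self_exc
  out <- cpp_population(drive, dt, n_neurons,
                        params$a, params$b, params$c, params$d,
                        mu_eps, sigma_eps, gain,
                        w_self, cls$tau, cls$gamma,
                        as.integer(noise_mode == "quenched"))
  structure(list(rate = out$rate, fraction = out$fraction, dt = dt,
                 gain = gain, n_neurons = n_neurons),
            class = "pacemaker_trace")
}

#' Detect bursts on a population rate trace
#'
#' Smooths the rate trace, removes its slow baseline (the population is
#' only partially synchronized, so the rate oscillates around a nonzero
#' floor rather than returning to silence between bursts), thresholds
#' the result at 50% of its robust maximum (97.5th percentile) and
#' merges onsets closer than a refractory window. Used for inter-burst
#' interval statistics.
#'
#' @param rate population rate trace (Hz) at `1/dt` sampling.
#' @param dt sampling step, seconds.
#' @param smooth_ms width of the moving-average smoother, ms.
#' @param baseline_ms width of the slow-baseline (detrending) window,
#'   ms; should span at least two oscillation cycles.
#' @param refractory_ms minimum separation between burst onsets, ms.
#' @param burn_in_s seconds discarded at the start.
#' @return list with `onsets` (seconds), `intervals` (ms), `mean_ibi_ms`
#'   and `cv` (coefficient of variation of the intervals).
#' @export
burst_intervals <- function(rate, dt = 0.001, smooth_ms = 25,
                            baseline_ms = 251, refractory_ms = 20,
                            burn_in_s = 1) {
  i0 <- round(burn_in_s / dt)
  r <- rate[(i0 + 1):length(rate)]
  w <- max(1, round(smooth_ms / (dt * 1000)))
  sm <- stats::filter(r, rep(1 / w, w), sides = 2)
  wb <- max(3, round(baseline_ms / (dt * 1000)))
  base <- stats::filter(r, rep(1 / wb, wb), sides = 2)
  sm <- sm - base
  sm[is.na(sm)] <- 0
  thr <- 0.5 * stats::quantile(sm, 0.975, names = FALSE)
  above <- sm > thr
  onsets <- which(diff(c(FALSE, above)) == 1)
  if (length(onsets) > 1) {
    keep <- c(TRUE, diff(onsets) * dt * 1000 > refractory_ms)
    onsets <- onsets[keep]
  }
  ivl <- diff(onsets) * dt * 1000
  list(onsets = (onsets + i0) * dt,
       intervals = ivl,
       mean_ibi_ms = if (length(ivl)) mean(ivl) else NA_real_,
       cv = if (length(ivl) > 1) stats::sd(ivl) / mean(ivl) else NA_real_)
}
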