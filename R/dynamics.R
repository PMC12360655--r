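## Mean-field node kernels: FI curve, OU noise, saturating synaptic gating.
## These are the reference (pure-R) implementations of the dynamics the
## compiled network integrator uses; tests cross-check the two paths.

#' FI-curve parameters
#'
#' Parameters of the input-current-to-firing-rate transfer function used by
#' every mean-field node. Defaults are the values used for all cortical,
#' thalamic and input-layer nodes.
#'
#' @param lambda_slope slope (excitability), Hz per nA. Must be > 0.
#' @param beta_offset offset (neural threshold), Hz.
#' @param theta_curvature curvature, seconds. Must be > 0.
#' @return An object of class `fi_params`.
#' @export
fi_params <- function(lambda_slope = 270, beta_offset = 108,
                      theta_curvature = 0.154) {
  stopifnot(is.finite(lambda_slope), lambda_slope > 0,
            is.finite(beta_offset),
            is.finite(theta_curvature), theta_curvature > 0)
  structure(list(lambda_slope = lambda_slope, beta_offset = beta_offset,
                 theta_curvature = theta_curvature),
            class = "fi_params")
}

#' Firing rate from input current (FI curve)
#'
#' `r = (lambda*I - beta) / (1 - exp(-theta*(lambda*I - beta)))`, with the
#' removable singularity at `lambda*I = beta` evaluated as `1/theta`. The
#' function is continuous, nonnegative and nondecreasing in `I`; output is
#' floored at 0 (the closed form can only go negative through floating-point
#' error).
#'
#' @param current input current in nA (vectorized).
#' @param p an [fi_params] object.
#' @return firing rate(s) in Hz.
#' @export
fi_rate <- function(current, p = fi_params()) {
  if (any(!is.finite(current))) stop("non-finite input current")
  x <- p$lambda_slope * current - p$beta_offset
  r <- ifelse(abs(x) < 1e-9,
              1 / p$theta_curvature,
              x / (1 - exp(-p$theta_curvature * x)))
  pmax(r, 0)
}

#' Ornstein-Uhlenbeck noise state
#'
#' Per-node temporally correlated input noise. The discretization in
#' [ou_step] is scaled so that the stationary standard deviation of the
#' process equals `sigma_eps` exactly.
#'
#' @param epsilon current value, nA.
#' @param tau_eps correlation time constant, seconds.
#' @param sigma_eps stationary standard deviation, nA.
#' @return An object of class `noise_state`.
#' @export
noise_state <- function(epsilon = 0, tau_eps = 0.002, sigma_eps = 0.025) {
  stopifnot(tau_eps > 0, sigma_eps >= 0)
  structure(list(epsilon = epsilon, tau_eps = tau_eps,
                 sigma_eps = sigma_eps),
            class = "noise_state")
}

#' One Euler-Maruyama step of the OU noise process
#'
#' `eps <- eps*(1 - dt/tau) + sigma*sqrt(2*dt/tau)*N(0,1)`. With this
#' scaling the discrete process has stationary SD `sigma_eps` (up to
#' O(dt/tau) discretization error); with `sigma_eps = 0` it reduces to pure
#' exponential decay `exp(-t/tau)`.
#'
#' @param state a [noise_state].
#' @param dt time step in seconds, `dt > 0` and `dt << tau_eps` for accuracy.
#' @return the updated [noise_state].
#' @export
ou_step <- function(state, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  state$epsilon <- state$epsilon * (1 - dt / state$tau_eps) +
    state$sigma_eps * sqrt(2 * dt / state$tau_eps) * stats::rnorm(1)
  state
}

## synapse classes, [tau (s); gamma]; inhibitory classes carry the negative
## weights of the connection table, the gate itself stays in [0, 1]
.synapse_classes <- list(
  fast_exc    = list(tau = 0.020, gamma = 0.8),
  slow_exc    = list(tau = 0.120, gamma = 0.5),
  fast_inh    = list(tau = 0.003, gamma = 0.8),
  slow_inh    = list(tau = 0.120, gamma = 0.1),
  ig_self_exc = list(tau = 0.001, gamma = 0.8)
)

#' Synapse specification
#'
#' A weighted, delayed, saturating connection of one of the five synapse
#' classes. `tau_syn` and `gamma_sat` default to the class values; the sign
#' of `weight` must be consistent with the class (inhibitory classes carry
#' negative weights).
#'
#' @param weight signed dimensionless weight.
#' @param class_label one of `"fast_exc"`, `"slow_exc"`, `"fast_inh"`,
#'   `"slow_inh"`, `"ig_self_exc"`.
#' @param delay axonal/synaptic delay in seconds, `>= 0`.
#' @param tau_syn,gamma_sat override the class time constant (s) and
#'   saturation parameter (in `[0,1]`).
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(weight, class_label, delay = 0,
                         tau_syn = NULL, gamma_sat = NULL) {
  cls <- .synapse_classes[[class_label]]
  if (is.null(cls)) stop("unknown synapse class: ", class_label)
  tau_syn <- if (is.null(tau_syn)) cls$tau else tau_syn
  gamma_sat <- if (is.null(gamma_sat)) cls$gamma else gamma_sat
  stopifnot(tau_syn > 0, gamma_sat >= 0, gamma_sat <= 1, delay >= 0)
  inh <- grepl("_inh$", class_label)
  if (inh && weight > 0) stop("inhibitory synapse class with positive weight")
  if (!inh && weight < 0) stop("excitatory synapse class with negative weight")
  structure(list(weight = weight, tau_syn = tau_syn, gamma_sat = gamma_sat,
                 delay = delay, class_label = class_label),
            class = "synapse_spec")
}

#' One Euler step of the synaptic gating variable
#'
#' `s <- s + dt*(-s/tau + gamma*(1-s)*r(t - delay))`. The gate is the
#' saturating transmitter-activation state in `[0, 1]`; it is clamped to
#' that interval only if the explicit Euler update overshoots (attribute
#' `"clamped"` on the result reports whether that happened).
#'
#' @param s_gate current gate value.
#' @param presyn_rate_delayed delayed presynaptic rate in Hz, `>= 0`.
#' @param spec a [synapse_spec].
#' @param dt time step in seconds.
#' @return updated gate value (numeric scalar, attribute `clamped`).
#' @export
synapse_step <- function(s_gate, presyn_rate_delayed, spec, dt) {
  if (any(presyn_rate_delayed < 0)) stop("negative presynaptic rate")
  if (dt <= 0) stop("dt must be > 0")
  s <- s_gate + dt * (-s_gate / spec$tau_syn +
                        spec$gamma_sat * (1 - s_gate) * presyn_rate_delayed)
  clamped <- s < 0 || s > 1
  s <- min(max(s, 0), 1)
  attr(s, "clamped") <- clamped
  s
}

#' Equilibrium gate value under a constant presynaptic rate
#'
#' Solves the gating equation at steady state:
#' `s* = gamma*r*tau / (1 + gamma*r*tau)`, strictly increasing in `r` and
#' always `< 1`.
#'
#' @param rate constant presynaptic rate, Hz.
#' @param spec a [synapse_spec].
#' @return equilibrium gate value.
#' @export
synapse_equilibrium <- function(rate, spec) {
  grt <- spec$gamma_sat * rate * spec$tau_syn
  grt / (1 + grt)
}

#' Total input current to a node
#'
#' Sum of weighted synaptic gates plus base, noise and external currents:
#' `I = sum_j w_j s_j + I_base + eps + I_ext`.
#'
#' @param incoming list of `list(spec = synapse_spec, s_gate = numeric)`
#'   pairs (may be empty).
#' @param i_base constant base current, nA.
#' @param epsilon current OU noise value, nA.
#' @param i_external external (stimulus) current, nA.
#' @return total input current in nA.
#' @export
node_input <- function(incoming = list(), i_base = 0.33, epsilon = 0,
                       i_external = 0) {
  syn <- 0
  for (inc in incoming) syn <- syn + inc$spec$weight * inc$s_gate
  syn + i_base + epsilon + i_external
}
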