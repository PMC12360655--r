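## Hierarchical laminar network: areas, input layers, optional pulvinar
## pathway and hemispheres, built from the fixed connectivity table and
## integrated with the compiled forward-Euler engine.

#' Default pacemaker output gain
#'
#' The scale applied to the pacemaker spiking fraction (per step, divided
#' by dt) before it drives mean-field synapses. Calibrated once so that the
#' isolated population and the full network produce the ~9 Hz baseline
#' rhythm, the ~100 ms inter-burst interval, and the stimulus-driven wave
#' reversal.
#'
#' @return numeric scalar.
#' @export
pacemaker_gain_default <- function() 1

#' Network configuration
#'
#' All weights, time constants and delays default to the fixed parameter
#' table of the model; any field can be overridden.
#'
#' @param n_areas number of cortical areas (`>= 2`; 3 by default).
#' @param pulvinar_enabled add the trans-pulvinar feedforward pathway
#'   (one relay node between each pair of consecutive areas).
#' @param w_pul_l4x pulvino-cortical weight (swept over `[0, 2.2]` in the
#'   pulvinar analyses).
#' @param hemispheres 1 (single stream) or 2 (two fully independent
#'   thalamo-cortical streams, no cross-connections).
#' @param delay_cx inter-areal cortico-cortical delay, seconds.
#' @param delay_pul cortex-pulvinar delay (each leg), seconds.
#' @param fw_isolated isolate the feedforward pathway: infragranular nodes
#'   become passive mean-field relays (no intrinsic rhythmicity) and the
#'   inter-areal infragranular feedback connections are removed.
#' @param w_l4in_l4x weight of the recurrent Layer-4 inhibition (input
#'   adaptation), negative.
#' @param w_igib_igib_fb weight of the inter-areal infragranular feedback.
#' @param w_igib_self pacemaker self-excitation weight.
#' @param w_igib_sgin weight of the infragranular-to-supragranular
#'   inhibitory feedback loop.
#' @param w_ff feedforward weight (supragranular to next area's Layer 4;
#'   also used for the stimulus input layer's projection to the first
#'   area).
#' @param pacemaker_gain pacemaker output gain (see
#'   [pacemaker_gain_default]).
#' @param n_neurons pacemaker population size.
#' @param i_base base current, nA.
#' @param sigma_eps,tau_eps OU noise SD (nA) and time constant (s) for
#'   mean-field nodes.
#' @param ilpr_noise_max upper bound of the uniform white-noise drive to
#'   the top input layer, nA.
#' @param fi defaults for the FI curve, an [fi_params] object.
#' @param izh pacemaker neuron parameters, an [izhikevich_params] object.
#' @param mu_eps_pace,sigma_eps_pace mean and SD of the per-neuron
#'   pacemaker drive.
#' @param pace_noise `"white"` draws the per-neuron Gaussian term anew
#'   each 1 ms step; `"quenched"` freezes it per neuron at trial start
#'   (static heterogeneity).
#' @return object of class `network_config`.
#' @export
network_config <- function(n_areas = 3,
                           pulvinar_enabled = FALSE,
                           w_pul_l4x = 1,
                           hemispheres = 1,
                           delay_cx = 0.012,
                           delay_pul = 0.006,
                           fw_isolated = FALSE,
                           w_l4in_l4x = -1.2,
                           w_igib_igib_fb = 1,
                           w_igib_self = 0.7,
                           w_igib_sgin = 1.5,
                           w_ff = 2,
                           pacemaker_gain = pacemaker_gain_default(),
                           n_neurons = 350,
                           i_base = 0.33,
                           sigma_eps = 0.025,
                           tau_eps = 0.002,
                           ilpr_noise_max = 0.3,
                           fi = fi_params(),
                           izh = izhikevich_params(),
                           mu_eps_pace = 6,
                           sigma_eps_pace = 4,
                           pace_noise = c("quenched", "white")) {
  pace_noise <- match.arg(pace_noise)
  stopifnot(n_areas >= 2, hemispheres %in% c(1, 2),
            w_pul_l4x >= 0, w_pul_l4x <= 2.2,
            delay_cx >= 0, delay_pul >= 0)
  structure(as.list(environment()), class = "network_config")
}

#' Read a network configuration from a YAML or JSON file
#'
#' The file holds any subset of the [network_config] arguments.
#'
#' @param path file path; extension `.yaml`/`.yml` (requires the yaml
#'   package) or `.json`.
#' @return object of class `network_config`.
#' @export
network_config_from_file <- function(path) {
  if (!grepl("\\.ya?ml$", path)) stop("only YAML configs are supported")
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  do.call(network_config, yaml::yaml.load_file(path))
}

## internal: one hemisphere's node and connection tables
.build_stream <- function(cfg, prefix = "") {
  nm <- function(...) paste0(prefix, ...)
  nodes <- data.frame(name = character(), kind = character(),
                      area = integer(), stringsAsFactors = FALSE)
  add_node <- function(name, kind, area = NA_integer_) {
    nodes <<- rbind(nodes, data.frame(name = name, kind = kind, area = area,
                                      stringsAsFactors = FALSE))
  }
  conns <- data.frame(src = character(), tgt = character(),
                      weight = numeric(), class = character(),
                      delay = numeric(), stringsAsFactors = FALSE)
  add_conn <- function(src, tgt, weight, class, delay = 0) {
    conns <<- rbind(conns, data.frame(src = src, tgt = tgt, weight = weight,
                                      class = class, delay = delay,
                                      stringsAsFactors = FALSE))
  }

  ig_kind <- if (cfg$fw_isolated) "mf" else "pace"
  for (i in seq_len(cfg$n_areas)) {
    a <- function(node) nm("Cx", i, ".", node)
    add_node(a("L4X"), "mf", i); add_node(a("L4IN"), "mf", i)
    add_node(a("SGX"), "mf", i); add_node(a("SGIN"), "mf", i)
    add_node(a("IGIB"), ig_kind, i)
    ## local wiring
    add_conn(a("L4X"), a("SGX"), 1, "fast_exc")
    add_conn(a("L4X"), a("L4IN"), 1, "fast_exc")
    add_conn(a("SGX"), a("IGIB"), 1, "fast_exc")
    add_conn(a("IGIB"), a("IGIB"), cfg$w_igib_self, "ig_self_exc")
    add_conn(a("L4IN"), a("L4X"), cfg$w_l4in_l4x, "slow_inh")
    add_conn(a("SGIN"), a("SGX"), -2, "fast_inh")
  }
  ## inter-areal wiring
  for (i in seq_len(cfg$n_areas - 1)) {
    lo <- function(node) nm("Cx", i, ".", node)
    hi <- function(node) nm("Cx", i + 1, ".", node)
    add_conn(lo("SGX"), hi("L4X"), cfg$w_ff, "fast_exc", cfg$delay_cx)
    add_conn(hi("IGIB"), lo("SGIN"), cfg$w_igib_sgin, "fast_exc", cfg$delay_cx)
    if (!cfg$fw_isolated)
      add_conn(hi("IGIB"), lo("IGIB"), cfg$w_igib_igib_fb, "slow_exc",
               cfg$delay_cx)
  }
  ## stimulus input layer (a Layer-4-like pair; feedforward relay to Cx1)
  add_node(nm("ILSt.X"), "mf"); add_node(nm("ILSt.IN"), "mf")
  add_conn(nm("ILSt.X"), nm("ILSt.IN"), 1, "fast_exc")
  add_conn(nm("ILSt.IN"), nm("ILSt.X"), cfg$w_l4in_l4x, "slow_inh")
  add_conn(nm("ILSt.X"), nm("Cx1.L4X"), cfg$w_ff, "fast_exc", cfg$delay_cx)
  ## top-down input layer (white-noise driven, stabilizes the BW pathway)
  add_node(nm("ILPr.X"), "mf"); add_node(nm("ILPr.IN"), "mf")
  add_conn(nm("ILPr.X"), nm("ILPr.IN"), 1, "fast_exc")
  add_conn(nm("ILPr.IN"), nm("ILPr.X"), cfg$w_l4in_l4x, "slow_inh")
  add_conn(nm("ILPr.X"), nm("Cx", cfg$n_areas, ".IGIB"), 1, "fast_exc",
           cfg$delay_cx)
  ## pulvinar pathway: one relay node per consecutive pair of areas
  if (cfg$pulvinar_enabled) {
    for (i in seq_len(cfg$n_areas - 1)) {
      p <- nm("Pul", i)
      add_node(p, "mf")
      add_conn(nm("Cx", i, ".IGIB"), p, 1, "fast_exc", cfg$delay_pul)
      add_conn(p, nm("Cx", i + 1, ".L4X"), cfg$w_pul_l4x, "fast_exc",
               cfg$delay_pul)
    }
  }
  list(nodes = nodes, conns = conns)
}

#' Build the laminar network
#'
#' Instantiates the node set and connection table for a configuration.
#' Deterministic given the configuration.
#'
#' @param config a [network_config].
#' @return object of class `alpha_network` with elements `nodes`
#'   (data.frame: name, kind, area), `conns` (data.frame: src, tgt,
#'   weight, class, tau, gamma, delay) and `config`.
#' @export
alpha_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  if (config$hemispheres == 2) {
    l <- .build_stream(config, "L.")
    r <- .build_stream(config, "R.")
    nodes <- rbind(l$nodes, r$nodes)
    conns <- rbind(l$conns, r$conns)
  } else {
    s <- .build_stream(config)
    nodes <- s$nodes; conns <- s$conns
  }
  bad <- setdiff(unique(c(conns$src, conns$tgt)), nodes$name)
  if (length(bad)) stop("dangling node id(s): ", paste(bad, collapse = ", "))
  cls <- .synapse_classes[conns$class]
  if (any(vapply(cls, is.null, logical(1))))
    stop("unknown synapse class in connection table")
  conns$tau <- vapply(cls, `[[`, numeric(1), "tau")
  conns$gamma <- vapply(cls, `[[`, numeric(1), "gamma")
  structure(list(nodes = nodes, conns = conns, config = config),
            class = "alpha_network")
}

#' @rdname alpha_network
#' @export
build_network <- alpha_network

#' @export
print.alpha_network <- function(x, ...) {
  cfg <- x$config
  cat("Laminar alpha traveling-wave network\n")
  cat(sprintf("  %d area(s) x %d hemisphere(s); pulvinar %s%s\n",
              cfg$n_areas, cfg$hemispheres,
              if (cfg$pulvinar_enabled)
                sprintf("enabled (w = %.2f)", cfg$w_pul_l4x) else "disabled",
              if (cfg$fw_isolated) "; FW pathway isolated" else ""))
  cat(sprintf("  %d nodes (%d pacemaker), %d connections, inter-areal delay %.0f ms\n",
              nrow(x$nodes), sum(x$nodes$kind == "pace"), nrow(x$conns),
              cfg$delay_cx * 1000))
  invisible(x)
}

#' DC step stimulus
#'
#' Constant-amplitude step applied to the stimulus input layer in
#' `[onset, offset)` seconds, zero elsewhere.
#'
#' @param amplitude nA, `>= 0`.
#' @param onset,offset seconds.
#' @return object of class `stimulus_protocol`.
#' @export
make_dc_stimulus <- function(amplitude, onset = 1, offset = 2) {
  stopifnot(amplitude >= 0, offset >= onset)
  structure(list(kind = "dc_step", amplitude = amplitude,
                 onset = onset, offset = offset),
            class = "stimulus_protocol")
}

#' Random step-function stimulus
#'
#' Piecewise-constant sequence updated at 10 Hz (100 ms blocks), each
#' block independently 0 or `amplitude` with probability `p_on`. The
#' sequence is non-rhythmic: its autocorrelation falls to ~0 beyond one
#' block length.
#'
#' @param amplitude nA.
#' @param duration seconds.
#' @param seed RNG seed for the block sequence (`NULL` to draw from the
#'   current RNG state).
#' @param block length of a block, seconds (0.1 = 10 Hz update rate).
#' @param p_on probability a block is ON.
#' @return object of class `stimulus_protocol` with the realized block
#'   `values`.
#' @export
make_random_step_stimulus <- function(amplitude, duration, seed = NULL,
                                      block = 0.1, p_on = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(duration / block)
  vals <- amplitude * (stats::runif(n_blocks) < p_on)
  structure(list(kind = "random_step", amplitude = amplitude,
                 duration = duration, block = block, p_on = p_on,
                 values = vals),
            class = "stimulus_protocol")
}

#' Materialize a stimulus protocol as a per-step current trace
#'
#' @param protocol a `stimulus_protocol` (or `NULL` for rest).
#' @param n_steps number of steps.
#' @param dt step, seconds.
#' @return numeric vector of length `n_steps`.
#' @export
stimulus_trace <- function(protocol, n_steps, dt = 0.001) {
  tt <- (seq_len(n_steps) - 1) * dt
  if (is.null(protocol)) return(numeric(n_steps))
  eps <- 1e-9   # guard against floating-point block/edge jitter
  switch(protocol$kind,
         dc_step = protocol$amplitude *
           as.numeric(tt >= protocol$onset - eps &
                        tt < protocol$offset - eps),
         random_step = {
           idx <- pmin(floor(tt / protocol$block + eps) + 1,
                       length(protocol$values))
           protocol$values[idx]
         },
         none = numeric(n_steps),
         stop("unknown stimulus kind"))
}

#' Simulate the network
#'
#' Forward integration (explicit Euler, 1 ms resolution; pacemaker
#' membranes at 0.5 ms) with per-connection delay buffers initialized at
#' each node's t = 0 rate. Identical `(config, seed)` pairs give
#' bit-identical traces.
#'
#' @param object an `alpha_network`.
#' @param nsim unused (one trace per call); present for the generic.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param duration seconds (`>= 1`).
#' @param stimulus a `stimulus_protocol`, a list of one per hemisphere
#'   (`hemispheres = 2`), or `NULL` for rest.
#' @param ... unused.
#' @return object of class `sim_traces`: `rates` matrix
#'   (steps x nodes, Hz, colnames = node names), `stimulus` trace(s),
#'   `dt`, `network`.
#' @export
simulate.alpha_network <- function(object, nsim = 1, seed = NULL,
                                   duration = 10, stimulus = NULL, ...) {
  stopifnot(duration >= 1)
  cfg <- object$config
  if (!is.null(seed)) set.seed(seed)
  dt <- 0.001
  n_steps <- round(duration / dt)
  nodes <- object$nodes; conns <- object$conns
  idx <- stats::setNames(seq_len(nrow(nodes)) - 1L, nodes$name)

  ## external input matrix: stimulus into IL_St, white noise into IL_Pr
  ext <- matrix(0, n_steps, nrow(nodes))
  stim_of <- function(hemi_prefix, proto) {
    tr <- stimulus_trace(proto, n_steps, dt)
    ext[, idx[paste0(hemi_prefix, "ILSt.X")] + 1L] <<- tr
    tr
  }
  if (cfg$hemispheres == 2) {
    prot <- if (is.null(stimulus) || inherits(stimulus, "stimulus_protocol"))
      list(left = stimulus, right = stimulus) else stimulus
    stim <- list(left = stim_of("L.", prot$left),
                 right = stim_of("R.", prot$right))
    pr_cols <- idx[paste0(c("L.", "R."), "ILPr.X")] + 1L
  } else {
    stim <- stim_of("", stimulus)
    pr_cols <- idx["ILPr.X"] + 1L
  }
  for (cl in pr_cols)
    ext[, cl] <- stats::runif(n_steps, 0, cfg$ilpr_noise_max)

  kind <- as.integer(nodes$kind == "pace")
  nmf <- nrow(nodes)
  ## pulvinar nodes are passive relays without their own OU noise; this
  ## also makes a w = 0 pulvinar exactly equivalent to the cortex-only
  ## model (no extra RNG draws)
  sigma_vec <- rep(cfg$sigma_eps, nmf)
  sigma_vec[grepl("Pul", nodes$name)] <- 0
  out <- cpp_simulate(kind,
                      rep(cfg$fi$lambda_slope, nmf),
                      rep(cfg$fi$beta_offset, nmf),
                      rep(cfg$fi$theta_curvature, nmf),
                      rep(cfg$i_base, nmf),
                      sigma_vec,
                      rep(cfg$tau_eps, nmf),
                      unname(idx[conns$src]), unname(idx[conns$tgt]),
                      as.integer(round(conns$delay / dt)),
                      conns$weight, conns$tau, conns$gamma,
                      ext, dt, n_steps,
                      cfg$n_neurons, cfg$izh$a, cfg$izh$b, cfg$izh$c,
                      cfg$izh$d, cfg$mu_eps_pace, cfg$sigma_eps_pace,
                      cfg$pacemaker_gain,
                      as.integer(identical(cfg$pace_noise, "quenched")),
                      1e4)
  rates <- out$rates
  colnames(rates) <- nodes$name
  structure(list(rates = rates, stimulus = stim, dt = dt,
                 network = object, clamped = out$clamped),
            class = "sim_traces")
}

#' @export
print.sim_traces <- function(x, ...) {
  cat(sprintf("Simulated traces: %d nodes x %.1f s at %.0f Hz\n",
              ncol(x$rates), nrow(x$rates) * x$dt, 1 / x$dt))
  invisible(x)
}

#' Extract rate traces for a node type across areas
#'
#' @param traces a `sim_traces` object.
#' @param node node label, e.g. `"SGX"`, `"IGIB"`, `"L4X"`.
#' @param hemi `""` for single-stream, `"L."` or `"R."` otherwise.
#' @return matrix steps x areas.
#' @export
node_rates <- function(traces, node = "IGIB", hemi = "") {
  n_areas <- traces$network$config$n_areas
  cols <- paste0(hemi, "Cx", seq_len(n_areas), ".", node)
  traces$rates[, cols, drop = FALSE]
}

#' Source-level phase lags between the lowest and highest area
#'
#' Band-limited analytic phase differences of the supragranular and
#' infragranular compartments between Cx_1 and Cx_N. Positive values mean
#' the first (lowest) area leads, the forward-wave configuration; negative
#' values mean the highest area leads (backward).
#'
#' @param traces a `sim_traces` object (>= 3 s of data).
#' @param band numeric length-2 band in Hz.
#' @param burn_in_s seconds discarded before averaging.
#' @return list with circular-mean phase differences `sgx` and `igib`
#'   (radians, Cx1 relative to CxN) and per-pair vectors `sgx_by_area`,
#'   `igib_by_area` (phase of area i relative to area i+1).
#' @export
source_phase_lags <- function(traces, band = c(7, 13), burn_in_s = 1) {
  stopifnot(nrow(traces$rates) * traces$dt >= 3)
  fs <- 1 / traces$dt
  i0 <- round(burn_in_s / traces$dt)
  lag_of <- function(xm) {
    ph <- apply(xm, 2, function(x) {
      Arg(analytic_signal(bandpass_fir(x - mean(x), band, fs)))
    })
    ph <- ph[-seq_len(i0), , drop = FALSE]
    n <- ncol(ph)
    pair <- vapply(seq_len(n - 1), function(i)
      Arg(mean(exp(1i * (ph[, i] - ph[, i + 1])))), numeric(1))
    list(total = Arg(mean(exp(1i * (ph[, 1] - ph[, n])))), pair = pair)
  }
  sg <- lag_of(node_rates(traces, "SGX"))
  ig <- lag_of(node_rates(traces, "IGIB"))
  list(sgx = sg$total, igib = ig$total,
       sgx_by_area = sg$pair, igib_by_area = ig$pair)
}

#' Write simulated traces to CSV
#'
#' Plain-text export: one column per node plus time and stimulus.
#'
#' @param traces a `sim_traces` object.
#' @param path output file.
#' @export
write_traces_csv <- function(traces, path) {
  tt <- (seq_len(nrow(traces$rates)) - 1) * traces$dt
  stim <- if (is.list(traces$stimulus)) traces$stimulus$left else traces$stimulus
  df <- data.frame(time = tt, stimulus = stim, traces$rates,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
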