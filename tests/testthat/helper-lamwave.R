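# shared fixtures: all synthetic, generated in code at test time

quiet_plot <- function(expr) {
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  force(expr)
}

# a minimal fake sim_traces object carrying prescribed per-node rates,
# for testing analysis functions without running the integrator
fake_traces <- function(rates, n_areas = 3, dt = 0.001) {
  cfg <- network_config(n_areas = n_areas)
  structure(list(rates = rates, stimulus = numeric(nrow(rates)),
                 dt = dt, network = list(config = cfg)),
            class = "sim_traces")
}

# node-name layout of one 3-area stream, matching the builder
stream_node_names <- function(n_areas = 3) {
  c(as.vector(vapply(seq_len(n_areas), function(i)
    paste0("Cx", i, ".", c("L4X", "L4IN", "SGX", "SGIN", "IGIB")),
    character(5))),
    "ILSt.X", "ILSt.IN", "ILPr.X", "ILPr.IN")
}
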