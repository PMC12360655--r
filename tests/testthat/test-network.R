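# Network construction, stimulus protocols, simulation invariants

test_that("default 3-area build enumerates the fixed wiring", {
  net <- alpha_network(network_config())
  expect_equal(nrow(net$nodes), 19)   # 3 x 5 laminar + 2 x 2 input-layer
  expect_equal(sum(net$nodes$kind == "pace"), 3)
  expect_setequal(net$nodes$name, stream_node_names())

  cn <- net$conns
  pick <- function(src, tgt) cn[cn$src == src & cn$tgt == tgt, ]
  # local wiring, one spot check per class
  expect_equal(pick("Cx1.L4X", "Cx1.SGX")$weight, 1)
  expect_equal(pick("Cx1.L4X", "Cx1.SGX")$class, "fast_exc")
  expect_equal(pick("Cx2.IGIB", "Cx2.IGIB")$weight, 0.7)
  expect_equal(pick("Cx2.IGIB", "Cx2.IGIB")$class, "ig_self_exc")
  expect_equal(pick("Cx1.L4IN", "Cx1.L4X")$weight, -1.2)
  expect_equal(pick("Cx1.L4IN", "Cx1.L4X")$class, "slow_inh")
  expect_equal(pick("Cx3.SGIN", "Cx3.SGX")$weight, -2)
  # inter-areal
  ff <- pick("Cx1.SGX", "Cx2.L4X")
  expect_equal(ff$weight, 2); expect_equal(ff$delay, 0.012)
  fb1 <- pick("Cx2.IGIB", "Cx1.SGIN")
  expect_equal(fb1$weight, 1.5); expect_equal(fb1$class, "fast_exc")
  fb2 <- pick("Cx2.IGIB", "Cx1.IGIB")
  expect_equal(fb2$weight, 1); expect_equal(fb2$class, "slow_exc")
  # synapse class constants
  expect_equal(unique(cn$tau[cn$class == "fast_exc"]), 0.020)
  expect_equal(unique(cn$tau[cn$class == "slow_exc"]), 0.120)
  expect_equal(unique(cn$tau[cn$class == "fast_inh"]), 0.003)
  expect_equal(unique(cn$gamma[cn$class == "slow_inh"]), 0.1)
})

test_that("pulvinar adds one relay per area pair; hemispheres double without crossing", {
  net <- alpha_network(network_config(pulvinar_enabled = TRUE,
                                      w_pul_l4x = 1.5))
  expect_equal(nrow(net$nodes), 21)
  for (p in c("Pul1", "Pul2")) {
    expect_equal(sum(net$conns$tgt == p), 1)
    expect_equal(sum(net$conns$src == p), 1)
  }
  pr <- net$conns[net$conns$src == "Pul1", ]
  expect_equal(pr$tgt, "Cx2.L4X")
  expect_equal(pr$weight, 1.5)
  expect_equal(pr$delay, 0.006)
  expect_equal(net$conns[net$conns$tgt == "Pul1", "src"], "Cx1.IGIB")

  base <- alpha_network(network_config())
  two <- alpha_network(network_config(hemispheres = 2))
  expect_equal(nrow(two$nodes), 2 * nrow(base$nodes))
  expect_equal(nrow(two$conns), 2 * nrow(base$conns))
  crosses <- xor(grepl("^L\\.", two$conns$src), grepl("^L\\.", two$conns$tgt))
  expect_false(any(crosses))
})

test_that("stimulus protocols materialize correctly", {
  dc <- make_dc_stimulus(1.2, 1, 2)
  tr <- stimulus_trace(dc, 3000)
  expect_equal(unique(tr[1:1000]), 0)
  expect_equal(unique(tr[1001:2000]), 1.2)
  expect_equal(unique(tr[2001:3000]), 0)
  expect_identical(stimulus_trace(make_dc_stimulus(0, 1, 2), 3000),
                   numeric(3000))

  rs <- make_random_step_stimulus(1.5, 20, seed = 4)
  expect_true(all(rs$values %in% c(0, 1.5)))
  tr <- stimulus_trace(rs, 20000)
  # block structure: constant over 100 ms
  blocks <- matrix(tr, nrow = 100)
  expect_true(all(apply(blocks, 2, function(b) length(unique(b)) == 1)))
  # non-rhythmic: autocorrelation near zero beyond one block
  x <- tr - mean(tr)
  ac150 <- sum(x[-(1:150)] * x[seq_len(length(x) - 150)]) / sum(x^2)
  expect_lt(abs(ac150), 0.15)
})

test_that("simulation is bit-reproducible and bounded at rest", {
  net <- alpha_network(network_config())
  a <- simulate(net, duration = 2, seed = 5)
  b <- simulate(net, duration = 2, seed = 5)
  expect_identical(a$rates, b$rates)
  for (s in 1:3) {
    tr <- simulate(net, duration = 4, seed = 100 + s)
    expect_true(all(is.finite(tr$rates)))
    expect_true(all(tr$rates >= 0))
    expect_lt(max(tr$rates[, net$nodes$kind == "mf"]), 1e4)
  }
})

test_that("an input step first reaches Cx1 after one inter-areal delay, Cx2 after two", {
  # deterministic network: no OU noise, no top-down noise, passive relays
  cfg <- network_config(fw_isolated = TRUE, sigma_eps = 0,
                        ilpr_noise_max = 0)
  net <- alpha_network(cfg)
  rest <- simulate(net, duration = 2, seed = 1)
  stim <- simulate(net, duration = 2, seed = 1,
                   stimulus = make_dc_stimulus(1.2, 1, 2))
  dif <- abs(stim$rates - rest$rates) > 1e-9
  first_change <- function(node) which(dif[, node])[1]
  # stimulus enters the input relay at step 1001
  expect_equal(first_change("ILSt.X"), 1001)
  # one synaptic delay (12 ms) + one Euler step to Cx1 Layer 4
  expect_equal(first_change("Cx1.L4X"), 1014)
  # and a second inter-areal hop to Cx2 Layer 4
  expect_gte(first_change("Cx2.L4X"), 1027)
})

test_that("source-level phase lags recover imposed lags and vanish for duplicates", {
  nms <- stream_node_names()
  n <- 6000
  tt <- (seq_len(n) - 1) / 1000
  mk <- function(lags) {
    rates <- matrix(1, n, length(nms), dimnames = list(NULL, nms))
    for (a in 1:3) {
      ph <- 2 * pi * 10 * tt + lags[a]
      for (nd in c("SGX", "IGIB"))
        rates[, paste0("Cx", a, ".", nd)] <- 10 + sin(ph)
    }
    fake_traces(rates)
  }
  # identical traces -> zero lag
  z <- source_phase_lags(mk(c(0, 0, 0)))
  expect_lt(abs(z$sgx), 1e-6)
  expect_lt(abs(z$igib), 1e-6)
  # imposed 0.7 rad per area, lowest area leading
  l <- source_phase_lags(mk(c(1.4, 0.7, 0)))
  expect_equal(l$sgx, 1.4, tolerance = 0.05)
  expect_equal(l$igib_by_area, c(0.7, 0.7), tolerance = 0.05)
})

test_that("the resting network is backward-ordered and stimulation activates SG rhythmically", {
  net <- alpha_network(network_config())
  rest <- simulate(net, duration = 5, seed = 31)
  sg <- node_rates(rest, "SGX")
  expect_lt(mean(sg[1001:5000, 1:2]), 2)   # superficial activity largely absent
  lag <- source_phase_lags(rest)
  expect_true(all(lag$igib_by_area < 0))   # higher areas lead: backward gradient

  stim <- simulate(net, duration = 5, seed = 32,
                   stimulus = make_dc_stimulus(1.2, 1, 5))
  sg2 <- node_rates(stim, "SGX")
  expect_gt(mean(sg2[2001:5000, ]), 10)
  pk <- spectral_peak(rowMeans(sg2[2001:5000, ]), 1000)
  expect_gt(pk, 7); expect_lt(pk, 12)
})

test_that("config round-trips through YAML", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(n_areas = 4, w_ff = 1.5,
                                pulvinar_enabled = TRUE)), path)
  cfg <- network_config_from_file(path)
  expect_equal(cfg$n_areas, 4)
  expect_equal(cfg$w_ff, 1.5)
  expect_true(cfg$pulvinar_enabled)
  expect_equal(cfg$delay_cx, 0.012)   # untouched defaults remain
})

test_that("trace CSV export writes all node columns", {
  net <- alpha_network(network_config())
  tr <- simulate(net, duration = 1, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_traces_csv(tr, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(df), 1000)
  expect_true(all(stream_node_names() %in% names(df)))
})
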