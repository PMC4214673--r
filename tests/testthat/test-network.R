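test_that("the wiring matches the glomerular microcircuit", {
  net <- build_glomerular_layer(network_config(n_glomeruli = 16))
  expect_equal(net$n_neurons, 64)
  W <- net$W
  type <- net$type
  glom <- net$glom
  # 240 SA->PG and 240 SA->ET inter-glomerular edges (16 * 15 pairs)
  sa_pg <- sum(W[type == "PG", type == "SA"] != 0)
  sa_et <- sum(W[type == "ET", type == "SA"] != 0)
  expect_equal(sa_pg, 240)
  expect_equal(sa_et, 240)
  # no SA self-glomerulus efferents
  for (g in seq_len(16)) {
    expect_equal(W[type == "PG" & glom == g, type == "SA" & glom == g], 0)
    expect_equal(W[type == "ET" & glom == g, type == "SA" & glom == g], 0)
  }
  # PG->MC is the only inhibitory synapse
  expect_true(all(W[type == "MC", type == "PG"] <= 0))
  neg <- which(W < 0, arr.ind = TRUE)
  expect_true(all(type[neg[, "row"]] == "MC" & type[neg[, "col"]] == "PG"))
  # the ET/SA sub-network has no afferents from MC or PG
  expect_true(all(W[type %in% c("ET", "SA"), type %in% c("MC", "PG")] == 0))
  expect_error(build_glomerular_layer(network_config(n_glomeruli = 0)),
               "n_glomeruli")
})

test_that("a single glomerulus has the local loop but no lateral edges", {
  net <- build_glomerular_layer(network_config(n_glomeruli = 1))
  W <- net$W
  type <- net$type
  expect_equal(net$n_neurons, 4)
  expect_lt(W[type == "MC", type == "PG"], 0)   # PG -| MC
  expect_gt(W[type == "PG", type == "MC"], 0)   # MC -> PG
  expect_gt(W[type == "PG", type == "ET"], 0)   # ET -> PG
  expect_gt(W[type == "SA", type == "ET"], 0)   # ET -> SA
  expect_equal(sum(W != 0), 4)                  # nothing else
})

test_that("exponential synapse follows its closed form", {
  expect_equal(synaptic_current(numeric(0), t = c(0, 5, 50), weight = 3),
               c(0, 0, 0))
  w <- 7
  tau <- 10
  expect_equal(synaptic_current(100, t = 100 + tau, weight = w, tau = tau),
               w / exp(1))
  # inhibitory contributions are non-positive at all times
  cur <- synaptic_current(c(10, 20, 30), t = seq(0, 50, by = 1),
                          weight = 5, sign = -1)
  expect_true(all(cur <= 0))
  # linear superposition of two spikes
  two <- synaptic_current(c(10, 20), t = 25, weight = w)
  expect_equal(two, w * (exp(-15 / 10) + exp(-5 / 10)))
})

test_that("a zero stimulus leaves the whole network silent", {
  net <- build_glomerular_layer(network_config(n_glomeruli = 4))
  rec <- run_stimulus(net, rep(0, 4), duration = 300)
  expect_equal(nrow(rec$times), 0)
  expect_true(all(rec$counts == 0))
})

test_that("stimulus validation rejects bad input", {
  net <- build_glomerular_layer(network_config(n_glomeruli = 4))
  expect_error(run_stimulus(net, rep(10, 3)), "length")
  expect_error(run_stimulus(net, c(10, NA, 5, 1)), "non-finite")
})

test_that("identical configuration and stimulus give identical trains", {
  cfg <- network_config(n_glomeruli = 4)
  stim <- stimulus_from_odor(generate_odor_panel(1, 4, seed = 9)[1, ], 1)
  r1 <- run_stimulus(build_glomerular_layer(cfg), stim)
  r2 <- run_stimulus(build_glomerular_layer(cfg), stim)
  expect_identical(r1$times, r2$times)
})

test_that("with sa_weight = 0 each glomerulus behaves as if isolated", {
  panel <- generate_odor_panel(1, 6, seed = 4)
  stim <- stimulus_from_odor(panel[1, ], 1.2)
  cfg <- network_config(n_glomeruli = 6, sa_weight = 0)
  rec <- run_stimulus(build_glomerular_layer(cfg), stim)
  cfg1 <- network_config(n_glomeruli = 1, sa_weight = 0)
  net1 <- build_glomerular_layer(cfg1)
  for (g in c(1, 3, 6)) {
    solo <- run_stimulus(net1, stim[g])
    for (tp in c("MC", "ET", "PG", "SA")) {
      full_idx <- which(rec$type == tp & rec$glom == g)
      solo_idx <- which(solo$type == tp)
      expect_identical(spike_times(rec, full_idx),
                       spike_times(solo, solo_idx))
    }
  }
})

test_that("stronger lateral weights monotonically reduce MC output", {
  panel <- generate_odor_panel(1, 8, seed = 2)
  stim <- stimulus_from_odor(panel[1, ], 1.4)
  totals <- vapply(c(0, 10, 20, 30), function(w) {
    net <- build_glomerular_layer(network_config(n_glomeruli = 8,
                                                 sa_weight = w))
    sum(run_stimulus(net, stim, duration = 500)$counts[net$type == "MC"])
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("ET and SA trains are unaffected by the MC/PG side", {
  panel <- generate_odor_panel(1, 5, seed = 8)
  stim <- stimulus_from_odor(panel[1, ], 1)
  base <- network_config(n_glomeruli = 5)
  cut <- network_config(n_glomeruli = 5, w_mc_pg = 0, w_pg_mc = 0,
                        w_orn_mc = 0)
  r1 <- run_stimulus(build_glomerular_layer(base), stim)
  r2 <- run_stimulus(build_glomerular_layer(cut), stim)
  et_sa1 <- r1$times[r1$times$neuron_id %in% which(r1$type %in% c("ET", "SA")), ]
  et_sa2 <- r2$times[r2$times$neuron_id %in% which(r2$type %in% c("ET", "SA")), ]
  rownames(et_sa1) <- rownames(et_sa2) <- NULL
  expect_identical(et_sa1, et_sa2)
})

test_that("the mean-rate readout converts counts to Hz per glomerulus", {
  rec <- structure(list(
    counts = c(10, 5, 0, 2, 4, 1, 7, 3),
    type = rep(c("MC", "ET", "PG", "SA"), 2),
    glom = rep(1:2, each = 4),
    duration = 500
  ), class = "spike_record")
  expect_equal(mean_rate_readout(rec, "MC"), c(20, 8))
  expect_equal(mean_rate_readout(rec, "ET"), c(10, 2))
  # doubling every count doubles every rate
  rec2 <- rec
  rec2$counts <- rec$counts * 2
  expect_equal(mean_rate_readout(rec2, "MC"),
               2 * mean_rate_readout(rec, "MC"))
  # empty train gives zero
  rec$counts[] <- 0
  expect_equal(mean_rate_readout(rec, "ET"), c(0, 0))
})

test_that("an exposure of 500 ms at dt 0.1 takes exactly 5000 steps", {
  net <- build_glomerular_layer(network_config(n_glomeruli = 2))
  rec <- run_stimulus(net, c(40, 40), duration = 500)
  # spike times are end-of-step multiples of dt within (0, 500]
  steps <- rec$times$time_ms / 0.1
  expect_equal(steps, round(steps))
  expect_true(all(rec$times$time_ms > 0 & rec$times$time_ms <= 500))
})

test_that("spike trains export as two-column delimited text", {
  net <- build_glomerular_layer(network_config(n_glomeruli = 2))
  rec <- run_stimulus(net, c(35, 20), duration = 200)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spike_record(rec, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(back), c("time_ms", "neuron_id"))
  expect_equal(nrow(back), nrow(rec$times))
})
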