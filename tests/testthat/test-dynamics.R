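test_that("resting state with zero input is a fixed point of stepLif", {
  p <- Population("E", 5L, "excitatory")
  st <- stepLif(rep(p@vRest, 5), rep(0L, 5), p, input = 0, dt = 0.1)
  expect_equal(st$v, rep(p@vRest, 5))
  expect_length(st$spiked, 0)
})

test_that("suprathreshold initialisation spikes, resets and becomes refractory", {
  p <- Population("E", 3L, "excitatory", tRef = 2)
  st <- stepLif(c(-53, -70, -50), rep(0L, 3), p, input = 0, dt = 0.1)
  expect_equal(st$spiked, c(1L, 3L))
  expect_equal(st$v[c(1, 3)], rep(p@vReset, 2))
  expect_equal(st$refrac[c(1, 3)], rep(20L, 2))
  # refractory neurons ignore input and stay clamped
  st2 <- stepLif(st$v, st$refrac, p, input = 200, dt = 0.1)
  expect_equal(st2$v[c(1, 3)], rep(p@vReset, 2))
  expect_length(st2$spiked, 1) # only the non-refractory neuron fires
})

test_that("simulated spike times match the closed-form LIF first passage", {
  for (tauM in c(8, 10, 20)) {
    for (I in c(2.5, 3, 4)) {
      tstar <- lifFirstPassage(tauM, I)
      net <- singleNeuronNet(tauM = tauM, tRef = 2)
      drv <- makeConstantDrive(I, 0, 500, "n")
      r <- runSimulation(net, list(drv), SimulationConfig(dt = 0.1,
                                                          duration = 500,
                                                          seed = 1L))
      ts <- spikeEvents(r)$time
      expect_gt(length(ts), 3)
      expect_lt(abs(ts[1] - tstar), 0.1 + 1e-9)
      # interspike interval = first passage + refractory period
      expect_lt(max(abs(diff(ts) - (tstar + 2))), 0.1 + 1e-9)
    }
  }
})

test_that("leak-only network produces an empty raster", {
  net <- singleNeuronNet()
  r <- runSimulation(net, list(), SimulationConfig(duration = 200, seed = 1L))
  expect_equal(nrow(spikeEvents(r)), 0)
})

test_that("identical config and seed reproduce the raster bit-exactly", {
  net <- buildOscillator()
  cfg <- SimulationConfig(duration = 500, seed = 99L)
  r1 <- runSimulation(net, list(), cfg)
  r2 <- runSimulation(net, list(), cfg)
  expect_identical(spikeEvents(r1), spikeEvents(r2))
})

test_that("every neuron respects its refractory period", {
  net <- buildOscillator()
  r <- runSimulation(net, list(makeConstantDrive(1.5, 0, 1000, "osc_E")),
                     SimulationConfig(duration = 1000, seed = 3L))
  ev <- spikeEvents(r)
  tref <- c(osc_E = 2, osc_I = 1)
  for (popname in unique(ev$population)) {
    sub <- ev[ev$population == popname, ]
    isi <- unlist(tapply(sub$time, sub$neuron,
                         function(t) if (length(t) > 1) diff(sort(t)) else NULL))
    if (length(isi)) expect_gte(min(isi), tref[[popname]])
  }
})

test_that("drives targeting unknown populations fail before stepping", {
  net <- singleNeuronNet()
  drv <- makeConstantDrive(1, 0, 100, "nonexistent")
  expect_error(runSimulation(net, list(drv), SimulationConfig(duration = 100)),
               "unknown population")
})

test_that("subthreshold PSP amplitude is linear in synaptic weight", {
  # threshold far away: target never spikes; one presynaptic spike only
  psp <- function(w) {
    pops <- list(
      Population("src", 1L, "excitatory"),
      Population("tgt", 1L, "excitatory", vThresh = 1000))
    net <- NetworkSpec(pops, list(Connection("src", "tgt", w, 1, 1, 3)))
    drv <- makeConstantDrive(20, 0, 1.2, "src") # exactly one spike
    cfg <- SimulationConfig(duration = 100, seed = 1L, recordVoltages = TRUE)
    r <- runSimulation(net, list(drv), cfg)
    expect_equal(nrow(spikeEvents(r)), 1)
    max(voltageTraces(r)[, "tgt"]) - (-70)
  }
  expect_equal(psp(1.0) * 2, psp(2.0), tolerance = 1e-10)
})

test_that("poisson background matches its analytic statistics", {
  ev <- poissonBackground(10, 100, 10000, seed = 5L)
  # mean 10 Hz * 100 neurons * 10 s = 10000 events, sd = 100
  expect_lt(abs(nrow(ev) - 10000), 3 * 100)
  # cross-check the mean against an independent cumulative-exponential sampler
  set.seed(7)
  indep <- sum(vapply(1:100, function(i) length(cumExpPoisson(10, 10000)), 1))
  expect_lt(abs(nrow(ev) - indep), 6 * 100)
  expect_equal(nrow(poissonBackground(0, 50, 1000)), 0)
  expect_identical(poissonBackground(5, 10, 1000, seed = 2L),
                   poissonBackground(5, 10, 1000, seed = 2L))
  expect_error(poissonBackground(-1, 10, 100), "rate")
})

test_that("rasters round-trip through the delimited text format", {
  net <- buildOscillator()
  r <- runSimulation(net, list(), SimulationConfig(duration = 300, seed = 11L))
  path <- tempfile(fileext = ".tsv")
  writeRaster(r, path)
  r2 <- readRaster(path)
  expect_equal(spikeEvents(r2), spikeEvents(r))
  expect_equal(r2@popSizes, r@popSizes)
  expect_equal(r2@duration, r@duration)
  expect_equal(r2@seed, r@seed)
})
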