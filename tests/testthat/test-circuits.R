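test_that("the oscillator builder produces a labelled four-loop E-I circuit", {
  net <- buildOscillator()
  lb <- networkLabels(net)
  expect_setequal(names(lb), c("oscillator_E", "oscillator_I"))
  pairs <- vapply(connections(net),
                  function(cn) paste(cn@source, cn@target), character(1))
  expect_setequal(pairs, c("osc_E osc_E", "osc_E osc_I",
                           "osc_I osc_E", "osc_I osc_I"))
  expect_length(validateNetwork(net), 0)
  # Dale's law by construction: all stored weights are magnitudes
  expect_true(all(vapply(connections(net), function(cn) cn@weight >= 0, TRUE)))
})

test_that("the default oscillator under sustained drive shows a fast population rhythm", {
  net <- buildOscillator()
  r <- runSimulation(net, list(makeConstantDrive(1.0, 0, 3000, "osc_E")),
                     SimulationConfig(duration = 3000, seed = 21L))
  sp <- powerSpectrum(populationRate(r, "osc_E", 2))
  expect_true(sp@hasPeak)
  expect_gt(sp@peakFrequency, 20)
})

test_that("the encoder wires mono- and di-synaptic routes onto the I population", {
  net <- buildEncoder(2, ratios = c(0.5, 4))
  pairs <- vapply(connections(net),
                  function(cn) paste(cn@source, cn@target), character(1))
  for (k in 1:2) {
    expect_true(sprintf("src_%d osc_I", k) %in% pairs)    # mono-synaptic
    expect_true(sprintf("src_%d relay_%d", k, k) %in% pairs)
    expect_true(sprintf("relay_%d osc_I", k) %in% pairs)  # di-synaptic
  }
  expect_length(validateNetwork(net), 0)
  # di route latency strictly exceeds the mono route latency
  d <- function(s, t) {
    i <- which(pairs == paste(s, t))
    connections(net)[[i]]@delay
  }
  expect_gt(d("src_1", "relay_1") + d("relay_1", "osc_I"), d("src_1", "osc_I"))
})

test_that("a zero ratio routes all I-directed weight through the relay", {
  net <- buildEncoder(2, ratios = c(0, 1))
  conns <- connections(net)
  pairs <- vapply(conns, function(cn) paste(cn@source, cn@target), character(1))
  wMono1 <- conns[[which(pairs == "src_1 osc_I")]]@weight
  wMono2 <- conns[[which(pairs == "src_2 osc_I")]]@weight
  expect_equal(wMono1, 0)
  expect_gt(wMono2, 0)
})

test_that("indistinguishable engram parameterisations are rejected", {
  expect_error(buildEncoder(2, ratios = c(1, 1)), "duplicate")
  ws <- list(EngramWeightSet(1, 0.2, 0.1), EngramWeightSet(2, 0.2, 0.1))
  expect_error(buildRouter(weightSets = ws), "duplicate")
})

test_that("the router contains an oscillator part plus interconnected E-I readout parts", {
  net <- buildRouter()
  lb <- networkLabels(net)
  for (k in 1:3) {
    expect_true(sprintf("engram_%d_E", k) %in% names(lb))
    expect_true(sprintf("engram_%d_I", k) %in% names(lb))
  }
  pairs <- vapply(connections(net),
                  function(cn) paste(cn@source, cn@target), character(1))
  for (k in 1:3) {
    expect_true(sprintf("osc_E part%d_E", k) %in% pairs)
    expect_true(sprintf("osc_E part%d_I", k) %in% pairs)
    expect_true(sprintf("part%d_E part%d_I", k, k) %in% pairs)
    expect_true(sprintf("part%d_I part%d_E", k, k) %in% pairs)
  }
  expect_length(validateNetwork(net), 0)
  # single-readout router is structurally valid
  net1 <- buildRouter(weightSets = list(EngramWeightSet(1, 0.2, 0.1)))
  expect_length(validateNetwork(net1), 0)
})

test_that("validateNetwork reports reference, Dale and delay violations", {
  net <- buildOscillator()
  bad <- net
  bad@connections[[1]] <- Connection("ghost", "osc_E", 0.1)
  v <- validateNetwork(bad)
  expect_length(grep("does not exist", v), 1)
  # negative-magnitude weight smuggled past the constructor
  bad2 <- net
  slot(bad2@connections[[2]], "weight", check = FALSE) <- -1
  expect_length(grep("Dale", validateNetwork(bad2)), 1)
  # sub-step delay
  bad3 <- net
  slot(bad3@connections[[3]], "delay", check = FALSE) <- 0.01
  expect_length(grep("below one step", validateNetwork(bad3, dt = 0.1)), 1)
  # oscillator role set missing a recurrent class
  bad4 <- net
  bad4@connections <- net@connections[-1]
  expect_length(grep("missing recurrent", validateNetwork(bad4)), 1)
})

test_that("permuting weight sets permutes which part wins (relabeling equivariance)", {
  osc <- defaultConfig("t2s")$network$oscillator
  oscP <- do.call(oscillatorParams, osc)
  fwd <- list(EngramWeightSet(1, 0.28, 0.19), EngramWeightSet(2, 0.24, 0.15),
              EngramWeightSet(3, 0.20, 0.12))
  rev <- list(EngramWeightSet(1, 0.20, 0.12), EngramWeightSet(2, 0.24, 0.15),
              EngramWeightSet(3, 0.28, 0.19))
  winnerAt <- function(ws, f, seed) {
    net <- buildRouter(oscP, ws, partParams())
    drv <- list(makeOscillatoryDrive(f, 4, 1000, 4000, "osc_I",
                                     relay = "relay_input"),
                makeConstantDrive(0.5, 0, 4000, "osc_I"))
    r <- runSimulation(net, drv, SimulationConfig(duration = 4000, seed = seed))
    act <- vapply(1:3, function(k) {
      e <- mean(populationRate(r, sprintf("part%d_E", k), 10, 1000, 4000)@rate)
      b <- mean(populationRate(r, sprintf("part%d_E", k), 10, 0, 1000)@rate)
      max(0, e - b)
    }, 1)
    which.max(act)
  }
  # the medium-band pair sits at index 2 in both orders; the winning INDEX
  # under the reversed order must be the reversed index of the forward winner
  expect_equal(winnerAt(fwd, 31, 4242L), 2)
  expect_equal(winnerAt(rev, 31, 4242L), 2)
  expect_equal(winnerAt(fwd, 20, 777L), 1)
  expect_equal(winnerAt(rev, 20, 777L), 3)
})

test_that("distinct mono/di ratios shift the oscillation frequency in order", {
  cfg <- defaultConfig("s2t")
  oscP <- do.call(oscillatorParams, cfg$network$oscillator)
  encP <- do.call(encoderParams, cfg$network$encoder)
  peak <- function(ratio, seed) {
    net <- buildEncoder(1, ratio, oscP, encP)
    r <- runSimulation(net, list(makeConstantDrive(3, 1000, 3500, "src_1")),
                       SimulationConfig(duration = 3500, seed = seed))
    sp <- powerSpectrum(populationRate(r, "osc_E", 2, from = 1000, to = 3500))
    sp@peakFrequency
  }
  fLow <- mean(vapply(1:2, function(s) peak(12, 100L + s), 1))
  fHigh <- mean(vapply(1:2, function(s) peak(0.3, 100L + s), 1))
  expect_gt(fHigh, fLow + 5)
})
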