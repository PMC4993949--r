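cfg1s <- SimulationConfig(dt = 0.1, duration = 1000)

test_that("constant drives render exactly within their window", {
  d <- makeConstantDrive(1.0, 0, 1, "x")
  out <- renderDrive(d, SimulationConfig(dt = 0.1, duration = 1))
  expect_equal(out, rep(1.0, 10))
  # window clipping: offset beyond duration truncates silently
  d2 <- makeConstantDrive(2.5, 500, 5000, "x")
  out2 <- renderDrive(d2, cfg1s)
  expect_length(out2, 10000)
  expect_true(all(out2[1:5000] == 0))
  expect_true(all(out2[5001:10000] == 2.5))
})

test_that("oscillatory drives are half-rectified with exact zeros", {
  d <- makeOscillatoryDrive(20, 1.0, 0, 1000, "x", pathway = "mono_synaptic")
  out <- renderDrive(d, cfg1s)
  # half period of 20 Hz = 25 ms -> sample index 251 is sin(pi) = 0
  expect_equal(out[251], 0)
  expect_true(all(out >= 0))
  # second half of each cycle fully rectified to zero
  expect_true(all(out[252:500] == 0))
  expect_equal(max(out), 1.0, tolerance = 1e-4)
})

test_that("zero amplitude and pre-onset samples are identically zero", {
  d <- makeOscillatoryDrive(10, 0, 0, 1000, "x", pathway = "mono_synaptic")
  expect_true(all(renderDrive(d, cfg1s) == 0))
  d2 <- makeOscillatoryDrive(10, 3, 500, 1000, "x", pathway = "mono_synaptic")
  out <- renderDrive(d2, cfg1s)
  expect_true(all(out[1:5000] == 0))
  expect_gt(max(out[5001:10000]), 0)
})

test_that("the rendered rectified sinusoid has its spectral peak at the drive frequency", {
  d <- makeOscillatoryDrive(20, 1.0, 0, 4000, "x", pathway = "mono_synaptic")
  wave <- renderDrive(d, SimulationConfig(dt = 0.1, duration = 4000))
  tr <- new("RateTrace", population = "wave", binWidth = 0.1, rate = wave)
  sp <- powerSpectrum(tr, band = c(2, 80))
  expect_true(sp@hasPeak)
  expect_equal(sp@peakFrequency, 20, tolerance = sp@resolution / 20)
})

test_that("delivered charge scales linearly with amplitude and drives superpose", {
  mk <- function(a) sum(renderDrive(makeConstantDrive(a, 100, 900, "x"), cfg1s))
  expect_equal(mk(2) / mk(1), 2)
  expect_equal(mk(0), 0)
  # superposition: two drives on one target sum sample-by-sample
  a <- renderDrive(makeConstantDrive(1, 0, 500, "x"), cfg1s)
  b <- renderDrive(makeConstantDrive(2, 250, 750, "x"), cfg1s)
  ab <- renderDrive(makeConstantDrive(3, 250, 500, "x"), cfg1s)
  expect_equal((a + b)[2501:5000], ab[2501:5000])
})

test_that("drive validation rejects inverted windows and negative amplitudes", {
  expect_error(makeOscillatoryDrive(10, 1, 500, 400, "x"), "offset")
  expect_error(makeConstantDrive(-1, 0, 100, "x"), "amplitude")
  expect_error(makeOscillatoryDrive(-5, 1, 0, 100, "x"), "frequency")
})
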