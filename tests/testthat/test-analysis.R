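test_that("population rate follows its defining arithmetic", {
  # 100 neurons each spiking once inside one 10 ms bin -> 100 Hz there
  ev <- data.frame(population = "p", neuron = 0:99,
                   time = seq(20, 29.9, length.out = 100))
  r <- makeRaster(ev, 100, c(p = 100L))
  tr <- populationRate(r, "p", 10)
  expect_equal(tr@rate[3], 100)
  expect_equal(sum(tr@rate[-3]), 0)
  # empty raster -> all-zero trace
  r0 <- makeRaster(ev[0, ], 100, c(p = 100L))
  expect_true(all(populationRate(r0, "p", 10)@rate == 0))
})

test_that("rate conservation: binned rates recover the exact spike count", {
  bg <- poissonBackground(20, 50, 2000, seed = 9L)
  ev <- data.frame(population = "p", neuron = bg$neuron, time = bg$time)
  r <- makeRaster(ev, 2000, c(p = 50L))
  tr <- populationRate(r, "p", 10)
  expect_equal(sum(tr@rate) * 10 / 1000 * 50, nrow(ev))
  # Poisson rate estimator close to the generating rate
  se <- sqrt(20 / (50 * 2)) # rate / sqrt(N neurons x T seconds)
  expect_lt(abs(mean(tr@rate) - 20), 3 * se)
})

test_that("spectra of known sinusoids peak at the right frequency", {
  sp <- powerSpectrum(sineTrace(40))
  expect_true(sp@hasPeak)
  expect_equal(sp@peakFrequency, 40, tolerance = sp@resolution / 40)
  # two-tone: larger-amplitude 10 Hz wins over 40 Hz
  sp2 <- powerSpectrum(sineTrace(10, amp = 10, freq2 = 40, amp2 = 5))
  expect_equal(sp2@peakFrequency, 10, tolerance = sp2@resolution / 10)
  # flat trace -> flagged, no peak
  flat <- new("RateTrace", population = "c", binWidth = 2, rate = rep(7, 2000))
  expect_false(powerSpectrum(flat)@hasPeak)
  # band beyond Nyquist rejected
  expect_error(powerSpectrum(sineTrace(10), band = c(2, 400)), "Nyquist")
})

test_that("peak frequency is recovered within resolution at SNR >= 10 across a grid", {
  set.seed(202)
  for (f in c(8, 17, 33, 61)) {
    for (rep in 1:3) {
      tr <- sineTrace(f, amp = 10, noise_sd = 10 / sqrt(10))
      sp <- powerSpectrum(tr)
      expect_true(sp@hasPeak)
      expect_lte(abs(sp@peakFrequency - f), sp@resolution)
    }
  }
})

test_that("activation delay finds sustained ignition and flags silence", {
  # burst beginning exactly at onset -> delay 0
  ev <- data.frame(population = "p",
                   neuron = rep(0:9, each = 60),
                   time = rep(seq(1000, 1590, by = 10), times = 10))
  r <- makeRaster(ev, 2000, c(p = 10L))
  d <- activationDelay(r, "p", onset = 1000)
  expect_true(d@responded)
  expect_equal(d@delay, 0)
  # silent population -> no-response flag
  r0 <- makeRaster(ev[0, ], 2000, c(p = 10L))
  d0 <- activationDelay(r0, "p", onset = 1000)
  expect_false(d0@responded)
  expect_true(is.na(d0@delay))
  # onset without a baseline window is rejected
  expect_error(activationDelay(r, "p", onset = 0), "baseline")
})

test_that("raising the delay threshold never shortens the measured delay", {
  set.seed(77)
  bg <- poissonBackground(5, 20, 3000, seed = 31L)
  burst <- data.frame(neuron = rep(0:19, each = 100),
                      time = runif(2000, 1300, 2800))
  ev <- rbind(data.frame(population = "p", neuron = bg$neuron, time = bg$time),
              data.frame(population = "p", neuron = burst$neuron,
                         time = burst$time))
  r <- makeRaster(ev, 3000, c(p = 20L))
  delays <- vapply(c(1.5, 2, 3, 4), function(k) {
    d <- activationDelay(r, "p", onset = 1000, k = k)
    if (d@responded) d@delay else Inf
  }, 1)
  expect_true(all(diff(delays) >= 0))
})

test_that("selectivity matrix normalises active rows and flags silent ones", {
  bg <- poissonBackground(2, 10, 3000, seed = 12L)
  active <- rbind(
    data.frame(population = "a", neuron = bg$neuron, time = bg$time),
    data.frame(population = "b", neuron = rep(0:9, 40),
               time = sort(runif(400, 1000, 3000))))
  r1 <- makeRaster(active, 3000, c(a = 10L, b = 10L))
  r0 <- makeRaster(active[0, ], 3000, c(a = 10L, b = 10L))
  sm <- selectivityMatrix(list(on = r1, off = r0), c("a", "b"),
                          window = c(1000, 3000))
  expect_equal(rowSums(activationMatrix(sm))[["on"]], 1)
  expect_true(sm@silent[["off"]])
  expect_true(is.na(rowWinners(sm)[2]))
  expect_equal(rowWinners(sm)[[1]], 2L)
  expect_true(all(activationMatrix(sm) >= 0))
  expect_error(selectivityMatrix(list(r1), c("a"), window = c(0, 9000)),
               "duration")
})

test_that("spectrum decoding picks the nearest reference and refuses no-peak input", {
  calib <- data.frame(id = 1:3, peakFrequency = c(20, 31, 44),
                      peakPower = c(0.25, 0.33, 0.12))
  spec <- new("SpectrumResult", frequencies = numeric(), power = numeric(),
              peakFrequency = 31, peakPower = 0.33, hasPeak = TRUE,
              resolution = 1)
  out <- decodeEngram(spec, calib)
  expect_equal(out$id, 2)
  expect_equal(out$distance, 0)
  # single-entry calibration always decodes to that entry
  out1 <- decodeEngram(spec, calib[1, ])
  expect_equal(out1$id, 1)
  expect_gt(out1$distance, 0)
  # no-peak spectra are refused explicitly
  nopeak <- new("SpectrumResult", frequencies = numeric(), power = numeric(),
                peakFrequency = NA_real_, peakPower = NA_real_,
                hasPeak = FALSE, resolution = NA_real_)
  ref <- decodeEngram(nopeak, calib)
  expect_true(ref$noOscillation)
  expect_true(is.na(ref$id))
})
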