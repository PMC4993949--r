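# Experiment-level behaviour is exercised on reduced problem sizes here;
# the full default runs back the acceptance suite (test-acceptance.R).

test_that("temporal-to-spatial aggregates are recomputable from per-seed records", {
  cfg <- tinyT2sConfig()
  rep <- runTemporalToSpatial(cfg)
  nS <- cfg$experiment$n_seeds
  expect_length(rep@perSeed, nS)
  recomputed <- Reduce(`+`, lapply(rep@perSeed, `[[`, "activation")) / nS
  rs <- rowSums(recomputed)
  recomputed[rs > 0, ] <- recomputed[rs > 0, , drop = FALSE] / rs[rs > 0]
  expect_equal(unname(rep@aggregate$activation), unname(recomputed))
  delays <- do.call(rbind, lapply(rep@perSeed, `[[`, "delays"))
  expect_equal(rep@aggregate$mean_delay, colMeans(delays, na.rm = TRUE))
  # active rows of the aggregated matrix are normalised
  act <- rep@aggregate$activation
  for (i in seq_len(nrow(act)))
    if (sum(act[i, ]) > 0) expect_equal(sum(act[i, ]), 1)
})

test_that("experiments are deterministic for a fixed config and seed set", {
  cfg <- defaultConfig("sweep")
  cfg$network$ratios <- c(0.3, 6)
  cfg$experiment$n_seeds <- 1L
  cfg$simulation$duration <- 2000
  cfg$drives$source <- list(amplitude = 3, onset = 500, offset = 2000)
  tm1 <- calibrateWeightFrequencyMap(cfg)
  tm2 <- calibrateWeightFrequencyMap(cfg)
  expect_identical(tm1@peakFrequency, tm2@peakFrequency)
  expect_identical(tm1@peakPower, tm2@peakPower)
})

test_that("single-point and degenerate sweeps are handled", {
  cfg <- defaultConfig("sweep")
  cfg$network$ratios <- c(0.5)
  expect_error(calibrateWeightFrequencyMap(cfg), ">= 2")
})

test_that("a single-engram round trip recovers identity whenever it oscillates", {
  cfg <- defaultConfig("roundtrip")
  cfg$network$ratios <- c(1.5)
  cfg$network$weight_sets <- cfg$network$weight_sets[2]
  cfg$experiment$n_seeds <- 2L
  rep <- runRoundTrip(cfg)
  ok <- vapply(rep@perSeed, function(x) !isTRUE(x$no_oscillation), TRUE)
  expect_true(all(vapply(rep@perSeed[ok], function(x) x$correct, TRUE)))
  expect_equal(rep@aggregate$chance, 1)
})

test_that("spatial-to-temporal reports per-engram spectra with sane structure", {
  cfg <- defaultConfig("s2t")
  cfg$experiment$n_seeds <- 3L
  cfg$experiment$n_calibration_seeds <- 2L
  cfg$network$ratios <- c(12, 0.3)
  cfg$simulation$duration <- 3000
  cfg$drives$source$offset <- 3000
  rep <- runSpatialToTemporal(cfg)
  expect_length(rep@perSeed, 2 * 3)
  a <- rep@aggregate
  expect_length(a$mean_peak_frequency, 2)
  expect_true(a$mean_peak_frequency[1] < a$mean_peak_frequency[2])
  expect_true(is.finite(a$decoding_accuracy))
  expect_equal(a$n_held_out, 2)
})
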