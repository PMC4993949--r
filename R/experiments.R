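## Turn-key experiment drivers for the two conversions and their
## composition. Trial seeds are derived deterministically from the config's
## base seed by counter, so every experiment is reproducible bit-exactly
## and every aggregate is recomputable from the stored per-seed records.

trialSeed <- function(base, i, j) as.integer(base + 10000L * i + j)

weightSetsFromConfig <- function(cfg) {
  lapply(cfg$network$weight_sets,
         function(w) EngramWeightSet(w$index, w$wE, w$wI))
}

routerFromConfig <- function(cfg) {
  buildRouter(do.call(oscillatorParams, cfg$network$oscillator),
              weightSetsFromConfig(cfg),
              do.call(partParams, cfg$network$part))
}

# the round-trip config carries separate oscillator sections for the
# encoder and the router; single-circuit configs use `oscillator` for both
encoderFromConfig <- function(cfg, ratios = cfg$network$ratios) {
  oscSection <- if (cfg$experiment$name == "round_trip")
    cfg$network$encoder_oscillator else cfg$network$oscillator
  buildEncoder(length(ratios), ratios,
               do.call(oscillatorParams, oscSection),
               do.call(encoderParams, cfg$network$encoder))
}

routerDrives <- function(cfg, frequency) {
  d1 <- cfg$drives$input1; d2 <- cfg$drives$input2
  list(
    makeOscillatoryDrive(frequency, d1$amplitude, d1$onset, d1$offset,
                         target = "osc_I", pathway = "di_synaptic",
                         relay = "relay_input"),
    makeConstantDrive(d2$amplitude, d2$onset, d2$offset,
                      target = "osc_I", pathway = "mono_synaptic"))
}

sourceDrive <- function(cfg, k) {
  ds <- cfg$drives$source
  makeConstantDrive(ds$amplitude, ds$onset, ds$offset,
                    target = sprintf("src_%d", k),
                    pathway = "mono_synaptic")
}

simConfig <- function(cfg, seed) {
  SimulationConfig(dt = cfg$simulation$dt, duration = cfg$simulation$duration,
                   seed = seed,
                   recordVoltages = isTRUE(cfg$simulation$record_voltages))
}

oscSpectrum <- function(cfg, raster, from, to) {
  trace <- populationRate(raster, "osc_E", cfg$analysis$rate_bin,
                          from = from, to = to)
  powerSpectrum(trace, band = cfg$analysis$band)
}

#' Temporal-to-spatial routing experiment
#'
#' For every drive-frequency condition and every seed: build the default
#' router, apply the oscillatory di-synaptic Input1 at that frequency plus
#' the constant mono-synaptic Input2, simulate, and quantify which engram
#' readout part ignites (selectivity matrix) and how fast (activation
#' delay of the condition-matched part). Conditions are matched to parts
#' in ascending frequency order: condition i targets part i.
#'
#' @param cfg effective config (see [defaultConfig()]), experiment
#'   `temporal_to_spatial`.
#' @param quiet suppress progress messages.
#' @return An [ExperimentReport-class]. Aggregate fields: the seed-averaged
#'   selectivity matrix and its row winners, the per-condition mean delay
#'   of the matched part, per-row counts of seeds with positive winner
#'   margin. Pass flags: `winners_correct`, `margins_positive`,
#'   `delay_within_200ms`.
#' @export
runTemporalToSpatial <- function(cfg = defaultConfig("t2s"), quiet = TRUE) {
  conds <- sort(cfg$experiment$conditions)
  nS <- cfg$experiment$n_seeds
  net <- routerFromConfig(cfg)
  K <- length(cfg$network$weight_sets)
  parts <- sprintf("part%d_E", vapply(weightSetsFromConfig(cfg),
                                      function(w) w@index, integer(1)))
  d1 <- cfg$drives$input1
  win <- c(d1$onset, min(d1$offset, cfg$simulation$duration))
  dl <- cfg$analysis$delay

  perSeed <- vector("list", nS)
  for (j in seq_len(nS)) {
    rasters <- vector("list", length(conds))
    for (i in seq_along(conds)) {
      if (!quiet) message(sprintf("t2s: condition %g Hz, seed %d", conds[i], j))
      rasters[[i]] <- runSimulation(
        net, routerDrives(cfg, conds[i]),
        simConfig(cfg, trialSeed(cfg$experiment$base_seed, i, j)))
    }
    sm <- selectivityMatrix(rasters, parts, win, baseline = c(0, win[1]))
    act <- sm@activation
    margins <- delays <- rep(NA_real_, length(conds))
    for (i in seq_along(conds)) {
      if (i > K) next
      margins[i] <- act[i, i] - if (K > 1) max(act[i, -i]) else 0
      dm <- activationDelay(rasters[[i]], parts[i], onset = win[1],
                            binWidth = dl$bin, k = dl$k, m = dl$m,
                            floorRate = dl$floor_rate)
      delays[i] <- if (dm@responded) dm@delay else NA_real_
    }
    perSeed[[j]] <- list(seed_block = j, activation = unname(act),
                         winners = sm@winners, margins = margins,
                         delays = delays)
  }

  actMean <- Reduce(`+`, lapply(perSeed, `[[`, "activation")) / nS
  rs <- rowSums(actMean)
  actMean[rs > 0, ] <- actMean[rs > 0, , drop = FALSE] / rs[rs > 0]
  winners <- apply(actMean, 1, which.max)
  marginCounts <- colSums(do.call(rbind, lapply(perSeed, `[[`, "margins")) > 0,
                          na.rm = TRUE)
  delayMat <- do.call(rbind, lapply(perSeed, `[[`, "delays"))
  meanDelay <- colMeans(delayMat, na.rm = TRUE)
  respondedCount <- colSums(!is.na(delayMat))
  matched <- seq_len(min(K, length(conds)))

  passed <- c(
    winners_correct = all(winners[matched] == matched),
    margins_positive = all(marginCounts[matched] >= ceiling(0.8 * nS)),
    delay_within_200ms = all(is.finite(meanDelay[matched]) &
                               meanDelay[matched] <= 200))
  new("ExperimentReport", experiment = "temporal_to_spatial",
      configHash = configHash(cfg), seeds = seq_len(nS),
      perSeed = perSeed,
      aggregate = list(conditions = conds, parts = parts,
                       activation = actMean, winners = as.integer(winners),
                       margin_positive_count = as.numeric(marginCounts),
                       mean_delay = as.numeric(meanDelay),
                       responded_count = as.numeric(respondedCount)),
      passed = passed)
}

#' Spatial-to-temporal encoding experiment
#'
#' For every engram source and every seed: activate only that source with
#' sustained drive on the default encoder, simulate, and measure the
#' oscillator's rate spectrum. The first `n_calibration_seeds` per engram
#' form the decoding references (mean peak frequency/power); the remaining
#' held-out seeds are decoded by nearest reference.
#'
#' @param cfg effective config (see [defaultConfig()]), experiment
#'   `spatial_to_temporal`.
#' @param quiet suppress progress messages.
#' @return An [ExperimentReport-class]. Aggregate fields: per-engram mean
#'   and sd of peak frequency and power, the spectral resolution, minimal
#'   pairwise peak separation, decoding accuracy on held-out seeds. Pass
#'   flags: `frequencies_separated`, `decoding_accuracy_90`.
#' @export
runSpatialToTemporal <- function(cfg = defaultConfig("s2t"), quiet = TRUE) {
  ratios <- cfg$network$ratios
  K <- length(ratios)
  nS <- cfg$experiment$n_seeds
  nCal <- cfg$experiment$n_calibration_seeds
  stopifnot(K >= 1, nS > nCal)
  net <- encoderFromConfig(cfg)
  ds <- cfg$drives$source
  win <- c(ds$onset, min(ds$offset, cfg$simulation$duration))

  perSeed <- list()
  resolution <- NA_real_
  for (k in seq_len(K)) {
    for (j in seq_len(nS)) {
      if (!quiet) message(sprintf("s2t: engram %d, seed %d", k, j))
      raster <- runSimulation(
        net, list(sourceDrive(cfg, k)),
        simConfig(cfg, trialSeed(cfg$experiment$base_seed, k, j)))
      spec <- oscSpectrum(cfg, raster, win[1], win[2])
      resolution <- spec@resolution
      perSeed[[length(perSeed) + 1L]] <-
        list(engram = k, seed_block = j,
             peak_frequency = spec@peakFrequency,
             peak_power = spec@peakPower, has_peak = spec@hasPeak)
    }
  }
  ps <- do.call(rbind, lapply(perSeed, function(x)
    data.frame(engram = x$engram, seed_block = x$seed_block,
               f = x$peak_frequency, p = x$peak_power, ok = x$has_peak)))

  agg <- do.call(rbind, lapply(split(ps, ps$engram), function(d) {
    dd <- d[d$ok, ]
    data.frame(engram = d$engram[1], mean_f = mean(dd$f), sd_f = stats::sd(dd$f),
               mean_p = mean(dd$p), sd_p = stats::sd(dd$p),
               n_with_peak = nrow(dd))
  }))
  sep <- if (K > 1) min(stats::dist(agg$mean_f)) else Inf

  calib <- do.call(rbind, lapply(split(ps[ps$seed_block <= nCal, ],
                                       ps$engram[ps$seed_block <= nCal]),
    function(d) data.frame(id = d$engram[1],
                           peakFrequency = mean(d$f[d$ok]),
                           peakPower = mean(d$p[d$ok]))))
  held <- ps[ps$seed_block > nCal, ]
  decoded <- vapply(seq_len(nrow(held)), function(r) {
    if (!held$ok[r]) return(NA_integer_)
    spec <- new("SpectrumResult", frequencies = numeric(), power = numeric(),
                peakFrequency = held$f[r], peakPower = held$p[r],
                hasPeak = TRUE, resolution = resolution)
    as.integer(decodeEngram(spec, calib)$id)
  }, integer(1))
  accuracy <- mean(!is.na(decoded) & decoded == held$engram)

  passed <- c(frequencies_separated = is.finite(sep) && sep > resolution,
              decoding_accuracy_90 = accuracy >= 0.9)
  new("ExperimentReport", experiment = "spatial_to_temporal",
      configHash = configHash(cfg), seeds = seq_len(nS), perSeed = perSeed,
      aggregate = list(ratios = ratios,
                       mean_peak_frequency = agg$mean_f,
                       sd_peak_frequency = agg$sd_f,
                       mean_peak_power = agg$mean_p,
                       sd_peak_power = agg$sd_p,
                       n_with_peak = agg$n_with_peak,
                       resolution = resolution,
                       min_pairwise_separation = as.numeric(sep),
                       decoding_accuracy = accuracy,
                       n_held_out = nrow(held)),
      passed = passed)
}

#' Round-trip identity-recovery experiment
#'
#' Composes the two conversions: activate engram source k on the encoder,
#' measure the oscillator's dominant frequency, replay that frequency as a
#' clean oscillatory Input1 to the router, and ask whether readout part k
#' wins the selectivity row. A trial whose encoder run produces no
#' oscillation counts as a failure, not an error.
#'
#' @param cfg effective config (see [defaultConfig()]), experiment
#'   `round_trip`.
#' @param quiet suppress progress messages.
#' @return An [ExperimentReport-class]. Aggregate fields: accuracy, trial
#'   count, chance level, one-sided binomial p-value against chance. Pass
#'   flags: `accuracy_90`, `above_chance_p01`.
#' @export
runRoundTrip <- function(cfg = defaultConfig("roundtrip"), quiet = TRUE) {
  ratios <- cfg$network$ratios
  K <- length(ratios)
  nS <- cfg$experiment$n_seeds
  encNet <- encoderFromConfig(cfg)
  routNet <- routerFromConfig(cfg)
  parts <- sprintf("part%d_E", vapply(weightSetsFromConfig(cfg),
                                      function(w) w@index, integer(1)))
  ds <- cfg$drives$source
  encWin <- c(ds$onset, min(ds$offset, cfg$simulation$duration))
  d1 <- cfg$drives$input1
  routWin <- c(d1$onset, min(d1$offset, cfg$simulation$duration))

  perSeed <- list()
  for (k in seq_len(K)) {
    for (j in seq_len(nS)) {
      if (!quiet) message(sprintf("roundtrip: engram %d, seed %d", k, j))
      base <- cfg$experiment$base_seed
      enc <- runSimulation(encNet, list(sourceDrive(cfg, k)),
                           simConfig(cfg, trialSeed(base, k, j)))
      spec <- oscSpectrum(cfg, enc, encWin[1], encWin[2])
      if (!spec@hasPeak) {
        perSeed[[length(perSeed) + 1L]] <-
          list(engram = k, seed_block = j, replay_frequency = NA_real_,
               winner = NA_integer_, correct = FALSE, no_oscillation = TRUE)
        next
      }
      rout <- runSimulation(
        routNet, routerDrives(cfg, spec@peakFrequency),
        simConfig(cfg, trialSeed(base, K + k, j)))
      sm <- selectivityMatrix(list(rout), parts, routWin,
                              baseline = c(0, routWin[1]))
      winner <- sm@winners[1]
      perSeed[[length(perSeed) + 1L]] <-
        list(engram = k, seed_block = j,
             replay_frequency = spec@peakFrequency,
             winner = winner, correct = !is.na(winner) && winner == k,
             no_oscillation = FALSE)
    }
  }
  correct <- vapply(perSeed, function(x) isTRUE(x$correct), logical(1))
  nTrials <- length(correct)
  accuracy <- mean(correct)
  pval <- stats::binom.test(sum(correct), nTrials, p = 1 / K,
                            alternative = "greater")$p.value
  passed <- c(accuracy_90 = accuracy >= 0.9,
              above_chance_p01 = pval < 0.01)
  new("ExperimentReport", experiment = "round_trip",
      configHash = configHash(cfg), seeds = seq_len(nS), perSeed = perSeed,
      aggregate = list(accuracy = accuracy, n_trials = nTrials,
                       chance = 1 / K, binomial_p = pval),
      passed = passed)
}

#' Calibration sweep: mono/di ratio to oscillation frequency and power
#'
#' For each sweep ratio, builds a single-source encoder, drives the source
#' for several seeds, and records the seed-averaged oscillation peak
#' frequency and power. The returned map carries the largest contiguous
#' regime over which peak frequency is strictly monotone in the ratio;
#' the package's default encoder ratios are drawn from this regime.
#'
#' @param cfg effective config (see [defaultConfig()]), experiment `sweep`.
#' @param quiet suppress progress messages.
#' @return A [TransferMap-class].
#' @export
calibrateWeightFrequencyMap <- function(cfg = defaultConfig("sweep"),
                                        quiet = TRUE) {
  ratios <- sort(cfg$network$ratios)
  if (length(ratios) < 2) stop("sweep needs >= 2 ratio values")
  nS <- cfg$experiment$n_seeds
  ds <- cfg$drives$source
  win <- c(ds$onset, min(ds$offset, cfg$simulation$duration))
  f <- p <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    net <- encoderFromConfig(cfg, ratios = ratios[i])
    fs <- ps <- rep(NA_real_, nS)
    for (j in seq_len(nS)) {
      if (!quiet) message(sprintf("sweep: ratio %g, seed %d", ratios[i], j))
      raster <- runSimulation(
        net, list(sourceDrive(cfg, 1L)),
        simConfig(cfg, trialSeed(cfg$experiment$base_seed, i, j)))
      spec <- oscSpectrum(cfg, raster, win[1], win[2])
      if (spec@hasPeak) { fs[j] <- spec@peakFrequency; ps[j] <- spec@peakPower }
    }
    f[i] <- mean(fs, na.rm = TRUE); p[i] <- mean(ps, na.rm = TRUE)
  }
  new("TransferMap", control = ratios, peakFrequency = f, peakPower = p,
      regime = monotoneRegime(f))
}

# indices of the largest contiguous run over which x is strictly monotone
monotoneRegime <- function(x) {
  n <- length(x)
  if (n < 2) return(seq_len(n))
  s <- sign(diff(x))
  s[is.na(s)] <- 0
  best_start <- 1L; best_len <- 1L
  i <- 1L
  while (i <= n - 1L) {
    if (s[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n - 1L && s[j + 1L] == s[i]) j <- j + 1L
    if (j - i + 2L > best_len) { best_start <- i; best_len <- j - i + 2L }
    i <- j + 1L
  }
  seq.int(best_start, best_start + best_len - 1L)
}
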