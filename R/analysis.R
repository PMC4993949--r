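## Quantification of simulated activity. The oscillation measure throughout
## is the Welch power spectral density of the z-scored population rate
## (Hann window, 1 s segments, 50% overlap, band 2-80 Hz by default), whose
## peak defines the oscillation's frequency and power.

#' Binned population firing rate
#'
#' Rate per bin is `count / (binWidth_s * size)` in Hz, i.e. the mean
#' per-neuron rate. Summing `rate * binWidth * size` over bins recovers
#' the spike count exactly.
#'
#' @param raster a [SpikeRaster-class].
#' @param population population name.
#' @param binWidth bin width (ms).
#' @param from,to window to bin (ms); defaults to the full raster.
#' @return A [RateTrace-class].
#' @export
populationRate <- function(raster, population, binWidth = 2,
                           from = 0, to = raster@duration) {
  if (!population %in% names(raster@popSizes))
    stop(sprintf("population '%s' not present in raster", population))
  size <- raster@popSizes[[population]]
  n_bins <- floor((to - from) / binWidth + 1e-9)
  ev <- raster@events
  t <- ev$time[ev$population == population]
  t <- t[t >= from & t < from + n_bins * binWidth]
  counts <- if (length(t))
    tabulate(floor((t - from) / binWidth) + 1L, nbins = n_bins)
  else rep(0L, n_bins)
  new("RateTrace", population = population, binWidth = binWidth,
      rate = counts / (binWidth / 1000) / size)
}

# Welch-averaged one-sided periodogram: Hann window, mean-detrended
# segments, 50% overlap. Returns frequencies (DC excluded) and PSD.
welchPsd <- function(x, fs, segLength, overlap = 0.5) {
  n <- length(x)
  nseg <- min(segLength, n)
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  U <- sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * U * fs)
  half <- floor(nseg / 2)
  list(frequencies = (seq_len(half)) * fs / nseg,
       power = 2 * psd[2:(half + 1L)],
       resolution = fs / nseg)
}

#' Welch power spectrum of a rate trace
#'
#' The trace is z-scored (making peak power comparable across conditions),
#' split into 1 s Hann-windowed segments with 50% overlap, and the averaged
#' one-sided periodogram is restricted to `band`. The peak is flagged
#' absent when the trace is flat or the maximal power does not rise above
#' `peakFloor` times the median in-band power (the white-noise floor).
#'
#' @param trace a [RateTrace-class]; at least 2 s of data is recommended
#'   for <= 1 Hz resolution.
#' @param band analysis band (Hz), default 2-80 Hz; must respect Nyquist.
#' @param segSeconds Welch segment length (s).
#' @param peakFloor peak-to-median power ratio below which the spectrum is
#'   declared peakless.
#' @return A [SpectrumResult-class].
#' @export
powerSpectrum <- function(trace, band = c(2, 80), segSeconds = 1,
                          peakFloor = 8) {
  fs <- 1000 / trace@binWidth
  if (band[2] > fs / 2)
    stop(sprintf("band upper edge %.1f Hz exceeds Nyquist %.1f Hz",
                 band[2], fs / 2))
  x <- trace@rate
  if (length(x) < 4 || stats::sd(x) == 0)
    return(new("SpectrumResult", frequencies = numeric(),
               power = numeric(), peakFrequency = NA_real_,
               peakPower = NA_real_, hasPeak = FALSE,
               resolution = NA_real_))
  x <- (x - mean(x)) / stats::sd(x)
  w <- welchPsd(x, fs, segLength = round(segSeconds * fs))
  keep <- w$frequencies >= band[1] & w$frequencies <= band[2]
  freqs <- w$frequencies[keep]
  pow <- w$power[keep]
  i <- which.max(pow)
  hasPeak <- length(pow) > 0 && pow[i] > peakFloor * stats::median(pow)
  new("SpectrumResult", frequencies = freqs, power = pow,
      peakFrequency = if (length(pow)) freqs[i] else NA_real_,
      peakPower = if (length(pow)) pow[i] else NA_real_,
      hasPeak = hasPeak, resolution = w$resolution)
}

#' Latency from drive onset to sustained firing
#'
#' A population counts as activated at the start of the first run of at
#' least `m` consecutive `binWidth` bins whose rate reaches `k` times the
#' pre-onset baseline rate (with an absolute floor of `floorRate`, so that
#' silent baselines do not make single stray spikes count as ignition).
#'
#' @param raster a [SpikeRaster-class].
#' @param population population name.
#' @param onset drive onset (ms); needs a pre-onset baseline window.
#' @param binWidth rate bin (ms), default 10.
#' @param k rate-threshold multiple of baseline, default 3.
#' @param m consecutive bins required, default 3.
#' @param floorRate absolute minimum threshold rate (Hz), default 2.
#' @return A [DelayMeasurement-class]; delay is `NA` with
#'   `responded = FALSE` when the criterion is never met.
#' @export
activationDelay <- function(raster, population, onset, binWidth = 10,
                            k = 3, m = 3, floorRate = 2) {
  if (onset < binWidth)
    stop("onset leaves no pre-onset baseline window")
  if (onset > raster@duration)
    stop("onset outside the simulation window")
  base <- populationRate(raster, population, binWidth, from = 0, to = onset)
  post <- populationRate(raster, population, binWidth,
                         from = onset, to = raster@duration)
  threshold <- max(k * mean(base@rate), floorRate)
  hit <- post@rate >= threshold
  run <- 0L
  for (b in seq_along(hit)) {
    run <- if (hit[b]) run + 1L else 0L
    if (run >= m) {
      t0 <- onset + (b - run) * binWidth
      return(new("DelayMeasurement", population = population, onset = onset,
                 responseTime = t0, delay = t0 - onset, responded = TRUE))
    }
  }
  new("DelayMeasurement", population = population, onset = onset,
      responseTime = NA_real_, delay = NA_real_, responded = FALSE)
}

#' Condition x engram-part selectivity matrix
#'
#' For each drive condition and each readout part, the evoked activation
#' is the part's mean rate inside the drive window minus its pre-onset
#' baseline rate, floored at zero; rows are normalised to sum to one and
#' the per-row winner is the argmax. All-zero rows are flagged silent,
#' rows whose top two entries coincide are flagged tied.
#'
#' @param rasters list of [SpikeRaster-class], one per condition.
#' @param parts character vector of readout population names (columns).
#' @param window `c(start, end)` drive window (ms).
#' @param baseline `c(start, end)` baseline window (ms).
#' @return A [SelectivityMatrix-class].
#' @export
selectivityMatrix <- function(rasters, parts, window, baseline = c(0, window[1])) {
  stopifnot(length(rasters) >= 1, length(parts) >= 1)
  for (r in rasters)
    if (window[2] > r@duration + 1e-9)
      stop("drive window extends past a raster's duration")
  act <- matrix(0, length(rasters), length(parts),
                dimnames = list(names(rasters), parts))
  for (i in seq_along(rasters)) {
    for (j in seq_along(parts)) {
      evoked <- mean(populationRate(rasters[[i]], parts[j], 10,
                                    from = window[1], to = window[2])@rate)
      base <- mean(populationRate(rasters[[i]], parts[j], 10,
                                  from = baseline[1], to = baseline[2])@rate)
      act[i, j] <- max(0, evoked - base)
    }
  }
  rs <- rowSums(act)
  silent <- rs == 0
  act[!silent, ] <- act[!silent, , drop = FALSE] / rs[!silent]
  winners <- rep(NA_integer_, nrow(act))
  tied <- rep(FALSE, nrow(act))
  for (i in which(!silent)) {
    o <- order(act[i, ], decreasing = TRUE)
    winners[i] <- o[1]
    tied[i] <- length(o) > 1 && act[i, o[1]] - act[i, o[2]] < 1e-12
  }
  new("SelectivityMatrix", activation = act, winners = winners,
      silent = silent, tied = tied)
}

#' Decode engram identity from an oscillation spectrum
#'
#' Nearest-reference classification in standardised (peak frequency, peak
#' power) space: both coordinates are centred and scaled by the spread of
#' the calibration references, and the reference with the smallest
#' Euclidean distance wins. Peakless spectra are refused.
#'
#' @param spectrum a [SpectrumResult-class].
#' @param calibration `data.frame` with columns `id`, `peakFrequency`,
#'   `peakPower` — one reference per engram.
#' @return list with `id` (NA when refused), `distance`, and
#'   `noOscillation` flag.
#' @export
decodeEngram <- function(spectrum, calibration) {
  stopifnot(nrow(calibration) >= 1,
            all(c("id", "peakFrequency", "peakPower") %in% names(calibration)))
  if (!spectrum@hasPeak)
    return(list(id = NA, distance = NA_real_, noOscillation = TRUE))
  sc <- function(v) { s <- stats::sd(v); if (is.na(s) || s == 0) 1 else s }
  fm <- mean(calibration$peakFrequency); fsd <- sc(calibration$peakFrequency)
  pm <- mean(calibration$peakPower); psd <- sc(calibration$peakPower)
  d <- sqrt(((calibration$peakFrequency - spectrum@peakFrequency) / fsd)^2 +
            ((calibration$peakPower - spectrum@peakPower) / psd)^2)
  i <- which.min(d)
  list(id = calibration$id[i], distance = d[i], noOscillation = FALSE)
}
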