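## Stochastic LIF dynamics. The per-step update is
##   dV/dt = (vRest - V)/tauM + I(t)
## integrated by forward Euler; threshold crossings are detected at the end
## of each step, spiking neurons are reset and clamped for tRef. Synaptic
## events add w/tauSyn to an exponentially decaying input-current trace, so
## one event injects w millivolts of depolarising charge in total.

#' One forward-Euler LIF step for a population
#'
#' Pure-R single-step update, the reference semantics of the compiled
#' engine: refractory neurons ignore all input and stay clamped at the
#' reset potential; all others integrate the leak plus `input` and any
#' neuron at or above threshold is reported, reset and made refractory.
#'
#' @param v membrane potentials (mV), one per neuron.
#' @param refrac remaining refractory steps per neuron (integer, >= 0).
#' @param pop the [Population-class] supplying the membrane constants.
#' @param input per-neuron drive this step (mV/ms); scalar inputs recycle.
#' @param dt integration step (ms).
#' @return list with updated `v`, `refrac`, and `spiked` (1-based indices
#'   of neurons that fired this step).
#' @examples
#' p <- Population("E", 3, "excitatory")
#' st <- stepLif(rep(-70, 3), rep(0L, 3), p, input = 2.0, dt = 0.1)
#' @export
stepLif <- function(v, refrac, pop, input, dt) {
  stopifnot(length(v) == pop@size, length(refrac) == pop@size)
  input <- rep_len(as.numeric(input), pop@size)
  active <- refrac == 0L
  refrac[!active] <- refrac[!active] - 1L
  v[!active] <- pop@vReset
  v[active] <- v[active] +
    dt * ((pop@vRest - v[active]) / pop@tauM + input[active])
  if (any(!is.finite(v)))
    stop("non-finite membrane potential (pathological weights?)")
  spiked <- which(active & v >= pop@vThresh)
  if (length(spiked)) {
    v[spiked] <- pop@vReset
    refrac[spiked] <- as.integer(round(pop@tRef / dt))
  }
  list(v = v, refrac = refrac, spiked = spiked)
}

#' Homogeneous Poisson background events
#'
#' Independent homogeneous Poisson spike trains, one per neuron, over
#' `[0, duration]`.
#'
#' @param rate per-neuron event rate (Hz).
#' @param size neuron count.
#' @param duration window length (ms).
#' @param seed integer seed; the same seed reproduces the event list.
#' @return `data.frame` with 0-based `neuron` and `time` (ms), time-sorted.
#' @export
poissonBackground <- function(rate, size, duration, seed = 1L) {
  if (rate < 0) stop("rate must be >= 0")
  set.seed(as.integer(seed))
  counts <- stats::rpois(size, rate * duration / 1000)
  neuron <- rep.int(seq_len(size) - 1L, counts)
  time <- stats::runif(sum(counts), 0, duration)
  o <- order(time, neuron)
  data.frame(neuron = neuron[o], time = time[o])
}

#' Run a full network simulation
#'
#' Time-stepped run of a validated [NetworkSpec-class] under a set of
#' external drives. Connectivity (Bernoulli synapse masks) and all Poisson
#' background noise are drawn from the configuration seed, so an identical
#' (network, drives, config) triple reproduces the raster bit-exactly.
#' Synaptic events are delivered after their conduction delay and decay
#' exponentially with the connection's `tauSyn`; di-synaptic drives are
#' injected into their relay population (see [DriveSpec-class]).
#'
#' @param network a [NetworkSpec-class]; must pass [validateNetwork()].
#' @param drives list of [DriveSpec-class] objects (possibly empty).
#' @param config a [SimulationConfig-class].
#' @return A [SpikeRaster-class]. When `config@recordVoltages` is set, the
#'   per-population mean-voltage matrix (steps x populations) is attached
#'   and available through [voltageTraces()].
#' @export
runSimulation <- function(network, drives = list(), config = SimulationConfig()) {
  viol <- validateNetwork(network, dt = config@dt)
  if (length(viol))
    stop("invalid network:\n  ", paste(viol, collapse = "\n  "))

  pops <- network@populations
  nm <- vapply(pops, function(p) p@name, character(1))
  sizes <- vapply(pops, function(p) p@size, integer(1))
  names(sizes) <- nm
  n_steps <- as.integer(round(config@duration / config@dt))

  # resolve each drive to its injection population before any stepping
  inj <- integer(length(drives))
  for (k in seq_along(drives)) {
    d <- drives[[k]]
    eff <- if (d@pathwayKind == "di_synaptic") d@relay else d@target
    if (!eff %in% nm)
      stop(sprintf("drive %d targets unknown population '%s'", k, eff))
    inj[k] <- match(eff, nm)
  }

  drive_mat <- matrix(0, n_steps, length(pops))
  for (k in seq_along(drives))
    drive_mat[, inj[k]] <- drive_mat[, inj[k]] +
      renderDrive(drives[[k]], config)

  set.seed(config@seed)
  conns <- lapply(network@connections, function(cn) {
    s <- match(cn@source, nm); t <- match(cn@target, nm)
    sign <- if (pops[[s]]@cellType == "excitatory") 1 else -1
    A <- matrix(0, sizes[t], sizes[s])
    if (cn@probability >= 1) {
      A[] <- sign * cn@weight / cn@tauSyn
    } else if (cn@probability > 0) {
      mask <- stats::runif(length(A)) < cn@probability
      A[mask] <- sign * cn@weight / cn@tauSyn
    }
    list(src = s - 1L, tgt = t - 1L,
         delay_steps = as.integer(round(cn@delay / config@dt)),
         decay = exp(-config@dt / cn@tauSyn), A = A)
  })

  res <- sim_core(sizes,
                  vapply(pops, function(p) p@tauM, 1),
                  vapply(pops, function(p) p@vRest, 1),
                  vapply(pops, function(p) p@vThresh, 1),
                  vapply(pops, function(p) p@vReset, 1),
                  vapply(pops, function(p) p@tRef, 1),
                  vapply(pops, function(p) p@backgroundRate, 1),
                  vapply(pops, function(p) p@backgroundWeight, 1),
                  conns, drive_mat, config@dt, n_steps,
                  config@recordVoltages)

  ev <- data.frame(population = nm[res$pop], neuron = res$neuron,
                   time = res$time)
  raster <- new("SpikeRaster", events = ev, duration = config@duration,
                popSizes = sizes, seed = config@seed)
  if (config@recordVoltages) {
    vt <- res$voltage
    colnames(vt) <- nm
    attr(raster, "voltage") <- vt
  }
  raster
}

#' @rdname accessors
#' @export
voltageTraces <- function(x) attr(x, "voltage")

#' Write / read a spike raster as delimited text
#'
#' One event per line (`population<TAB>neuron<TAB>time_ms`), preceded by
#' comment headers carrying the seed, the duration, the population sizes
#' and a content hash of those run parameters, so a re-read raster is fully
#' reconstructable.
#'
#' @param raster a [SpikeRaster-class].
#' @param path file path.
#' @return `writeRaster` returns `path` invisibly; `readRaster` the raster.
#' @export
writeRaster <- function(raster, path) {
  hdr <- c(
    sprintf("# seed: %d", raster@seed),
    sprintf("# duration_ms: %.10g", raster@duration),
    sprintf("# populations: %s",
            paste(names(raster@popSizes), raster@popSizes,
                  sep = "=", collapse = ",")),
    sprintf("# config_hash: %s",
            rlang::hash(list(raster@seed, raster@duration, raster@popSizes))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(raster@events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getf <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), hdr, value = TRUE))
  seed <- as.integer(getf("seed"))
  duration <- as.numeric(getf("duration_ms"))
  pp <- strsplit(strsplit(getf("populations"), ",")[[1]], "=")
  popSizes <- stats::setNames(as.integer(vapply(pp, `[`, "", 2)),
                              vapply(pp, `[`, "", 1))
  body <- lines[!grepl("^#", lines)]
  ev <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    data.frame(population = vapply(parts, `[`, "", 1),
               neuron = as.integer(vapply(parts, `[`, "", 2)),
               time = as.numeric(vapply(parts, `[`, "", 3)))
  } else data.frame(population = character(), neuron = integer(),
                    time = numeric())
  new("SpikeRaster", events = ev, duration = duration, popSizes = popSizes,
      seed = seed)
}
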