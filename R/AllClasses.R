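#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib engramosc, .registration = TRUE
NULL

## Central S4 containers. Every object that crosses a module boundary is a
## validated class; constructors below are the user-facing entry points.

#' A homogeneous population of leaky integrate-and-fire neurons
#'
#' Describes one population: its size, cell type (which fixes the Dale sign
#' of all its outgoing synapses), membrane constants and private Poisson
#' background noise.
#'
#' @slot name population identifier, unique within a network.
#' @slot size number of neurons (>= 1).
#' @slot cellType `"excitatory"` or `"inhibitory"`.
#' @slot tauM membrane time constant (ms).
#' @slot vRest resting potential (mV).
#' @slot vThresh spike threshold (mV).
#' @slot vReset post-spike reset potential (mV).
#' @slot tRef absolute refractory period (ms).
#' @slot backgroundRate per-neuron homogeneous Poisson noise rate (Hz).
#' @slot backgroundWeight membrane-potential jump per background event (mV).
#' @export
setClass("Population",
  representation(
    name = "character", size = "integer", cellType = "character",
    tauM = "numeric", vRest = "numeric", vThresh = "numeric",
    vReset = "numeric", tRef = "numeric",
    backgroundRate = "numeric", backgroundWeight = "numeric"),
  validity = function(object) {
    errs <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      errs <- c(errs, "name must be a single non-empty string")
    if (object@size < 1L) errs <- c(errs, "size must be >= 1")
    if (!object@cellType %in% c("excitatory", "inhibitory"))
      errs <- c(errs, "cellType must be 'excitatory' or 'inhibitory'")
    if (object@tauM <= 0) errs <- c(errs, "tauM must be > 0")
    if (object@vReset >= object@vThresh)
      errs <- c(errs, "vReset must be below vThresh")
    if (object@tRef < 0) errs <- c(errs, "tRef must be >= 0")
    if (object@backgroundRate < 0) errs <- c(errs, "backgroundRate must be >= 0")
    if (length(errs)) errs else TRUE
  })

#' A synaptic projection between two populations
#'
#' Weight is a non-negative magnitude (mV of total depolarisation delivered
#' per presynaptic spike); the effective postsynaptic sign follows Dale's
#' law from the source population's cell type. Individual synapses exist
#' with probability `probability`, realised from the simulation seed.
#'
#' @slot source,target population names.
#' @slot weight per-spike magnitude (mV, >= 0).
#' @slot probability connection probability in `[0, 1]`.
#' @slot delay conduction delay (ms); must be at least one simulation step.
#' @slot tauSyn exponential synaptic decay constant (ms).
#' @export
setClass("Connection",
  representation(
    source = "character", target = "character", weight = "numeric",
    probability = "numeric", delay = "numeric", tauSyn = "numeric"),
  validity = function(object) {
    errs <- character()
    if (object@weight < 0)
      errs <- c(errs, "weight must be >= 0 (sign comes from the source cell type)")
    if (object@probability < 0 || object@probability > 1)
      errs <- c(errs, "probability must lie in [0, 1]")
    if (object@delay <= 0) errs <- c(errs, "delay must be positive")
    if (object@tauSyn <= 0) errs <- c(errs, "tauSyn must be positive")
    if (length(errs)) errs else TRUE
  })

#' A full circuit description
#'
#' Populations, their synaptic connections, and a role map attaching
#' functional labels (`oscillator_E`, `oscillator_I`, `engram_k_E`,
#' `engram_k_I`, `engram_source_k`, `relay_*`) to population names.
#' Use [validateNetwork()] for the full structural check; the class
#' validity enforces only uniqueness and referential integrity.
#'
#' @slot populations list of [Population-class] objects.
#' @slot connections list of [Connection-class] objects.
#' @slot labels named character vector: role -> population name.
#' @export
setClass("NetworkSpec",
  representation(populations = "list", connections = "list",
                 labels = "character"),
  validity = function(object) {
    errs <- character()
    nm <- vapply(object@populations, function(p) p@name, character(1))
    if (anyDuplicated(nm))
      errs <- c(errs, "duplicate population names")
    for (cn in object@connections) {
      if (!cn@source %in% nm || !cn@target %in% nm)
        errs <- c(errs, sprintf("connection %s -> %s references a missing population",
                                cn@source, cn@target))
    }
    if (length(object@labels) && any(!object@labels %in% nm))
      errs <- c(errs, "label map references a missing population")
    if (length(errs)) errs else TRUE
  })

#' Simulation run parameters
#'
#' @slot dt forward-Euler integration step (ms).
#' @slot duration total simulated time (ms).
#' @slot seed integer seed; identical seed and specs give bit-identical runs.
#' @slot recordVoltages record per-population mean membrane potential traces.
#' @export
setClass("SimulationConfig",
  representation(dt = "numeric", duration = "numeric", seed = "integer",
                 recordVoltages = "logical"),
  validity = function(object) {
    errs <- character()
    if (object@dt <= 0) errs <- c(errs, "dt must be > 0")
    if (object@duration < object@dt) errs <- c(errs, "duration must be >= dt")
    if (length(errs)) errs else TRUE
  })

#' An external drive onto one population
#'
#' Constant or half-rectified-sinusoid current, applied uniformly to all
#' neurons of the target population within `[onset, offset)` and exactly
#' zero outside. The pathway says whether the current is injected directly
#' (mono-synaptic: the synapse is absorbed into the current) or into an
#' excitatory relay population that spikes onto the nominal target
#' (di-synaptic: adds conduction delay, low-pass filtering and the relay's
#' spiking nonlinearity).
#'
#' @slot target nominal target population name.
#' @slot pathwayKind `"mono_synaptic"` or `"di_synaptic"`.
#' @slot relay relay population name (di-synaptic only; `NA` otherwise).
#' @slot kind `"constant"` or `"sinusoid"`.
#' @slot amplitude drive magnitude (mV/ms equivalent current, >= 0).
#' @slot frequency sinusoid frequency (Hz; `NA` for constant drives).
#' @slot phase sinusoid phase (radians).
#' @slot onset,offset drive window (ms), `offset > onset >= 0`.
#' @export
setClass("DriveSpec",
  representation(
    target = "character", pathwayKind = "character", relay = "character",
    kind = "character", amplitude = "numeric", frequency = "numeric",
    phase = "numeric", onset = "numeric", offset = "numeric"),
  validity = function(object) {
    errs <- character()
    if (!object@kind %in% c("constant", "sinusoid"))
      errs <- c(errs, "kind must be 'constant' or 'sinusoid'")
    if (!object@pathwayKind %in% c("mono_synaptic", "di_synaptic"))
      errs <- c(errs, "pathwayKind must be 'mono_synaptic' or 'di_synaptic'")
    if (object@pathwayKind == "di_synaptic" && is.na(object@relay))
      errs <- c(errs, "di-synaptic drives need a relay population")
    if (object@amplitude < 0) errs <- c(errs, "amplitude must be >= 0")
    if (object@kind == "sinusoid" &&
        (is.na(object@frequency) || object@frequency <= 0))
      errs <- c(errs, "sinusoid drives need frequency > 0")
    if (object@onset < 0) errs <- c(errs, "onset must be >= 0")
    if (object@offset <= object@onset) errs <- c(errs, "offset must exceed onset")
    if (length(errs)) errs else TRUE
  })

#' Per-readout engram connection weights
#'
#' One engram readout part k receives the oscillator's excitatory spikes on
#' its E neurons with weight `wE` and on its I neurons with weight `wI`
#' (the W_e/W_i pair of the routing circuit). The (wE, wI) pairs across
#' parts must be pairwise distinct, otherwise parts are indistinguishable
#' by construction.
#'
#' @slot index readout part index (1-based).
#' @slot wE weight onto the part's excitatory neurons (mV).
#' @slot wI weight onto the part's inhibitory neurons (mV).
#' @export
setClass("EngramWeightSet",
  representation(index = "integer", wE = "numeric", wI = "numeric"),
  validity = function(object) {
    errs <- character()
    if (object@wE < 0 || object@wI < 0) errs <- c(errs, "weights must be >= 0")
    if (object@index < 1L) errs <- c(errs, "index must be >= 1")
    if (length(errs)) errs else TRUE
  })

#' Simulated spike events
#'
#' The simulator's primary output: one row per spike, with the population
#' name, the 0-based neuron index within that population, and the spike
#' time in ms. Rows are sorted by time (ties in population/index order).
#'
#' @slot events `data.frame` with columns `population`, `neuron`, `time`.
#' @slot duration simulated duration (ms).
#' @slot popSizes named integer vector of population sizes.
#' @slot seed seed of the generating run.
#' @export
setClass("SpikeRaster",
  representation(events = "data.frame", duration = "numeric",
                 popSizes = "integer", seed = "integer"),
  validity = function(object) {
    ev <- object@events
    errs <- character()
    if (!all(c("population", "neuron", "time") %in% names(ev)))
      return("events must have columns population, neuron, time")
    if (nrow(ev)) {
      if (min(ev$time) < 0 || max(ev$time) > object@duration)
        errs <- c(errs, "spike times must lie in [0, duration]")
      if (is.unsorted(ev$time))
        errs <- c(errs, "events must be sorted by time")
      if (!all(ev$population %in% names(object@popSizes)))
        errs <- c(errs, "events reference unknown populations")
      else {
        sz <- object@popSizes[ev$population]
        if (any(ev$neuron < 0L) || any(ev$neuron >= sz))
          errs <- c(errs, "neuron indices must lie in [0, population size)")
      }
    }
    if (length(errs)) errs else TRUE
  })

#' Binned population firing rate
#'
#' @slot population population name.
#' @slot binWidth bin width (ms).
#' @slot rate mean per-neuron firing rate per bin (Hz).
#' @export
setClass("RateTrace",
  representation(population = "character", binWidth = "numeric",
                 rate = "numeric"),
  validity = function(object) {
    if (object@binWidth <= 0) return("binWidth must be positive")
    if (length(object@rate) && min(object@rate) < 0) return("rates must be >= 0")
    TRUE
  })

#' Welch power spectrum of a rate trace
#'
#' @slot frequencies strictly increasing frequency grid (Hz), DC excluded.
#' @slot power power spectral density of the z-scored rate trace.
#' @slot peakFrequency frequency attaining maximal power in the band (Hz).
#' @slot peakPower power at the peak.
#' @slot hasPeak `FALSE` when the trace is flat/near-flat (no oscillation).
#' @slot resolution spectral resolution (Hz), one frequency-grid step.
#' @export
setClass("SpectrumResult",
  representation(frequencies = "numeric", power = "numeric",
                 peakFrequency = "numeric", peakPower = "numeric",
                 hasPeak = "logical", resolution = "numeric"),
  validity = function(object) {
    errs <- character()
    if (length(object@frequencies) != length(object@power))
      errs <- c(errs, "frequencies and power must have equal length")
    if (length(object@frequencies) > 1 &&
        any(diff(object@frequencies) <= 0))
      errs <- c(errs, "frequencies must be strictly increasing")
    if (object@hasPeak && length(object@power) &&
        abs(object@peakPower - max(object@power)) > 1e-9 * max(abs(object@power), 1))
      errs <- c(errs, "peakPower must attain the maximum over the band")
    if (length(errs)) errs else TRUE
  })

#' Latency from drive onset to sustained firing
#'
#' @slot population population name.
#' @slot onset drive onset (ms).
#' @slot responseTime start of the first sustained-rate run (ms) or `NA`.
#' @slot delay `responseTime - onset` (ms) or `NA` when no response.
#' @slot responded whether the activation criterion was ever met.
#' @export
setClass("DelayMeasurement",
  representation(population = "character", onset = "numeric",
                 responseTime = "numeric", delay = "numeric",
                 responded = "logical"),
  validity = function(object) {
    if (object@responded && (is.na(object@delay) || object@delay < 0))
      return("present responses must have delay >= 0")
    TRUE
  })

#' Drive-condition x engram-part activation table
#'
#' Entries are baseline-subtracted mean evoked rates, floored at zero and
#' row-normalised; the per-row winner is the argmax. Rows with no evoked
#' activity anywhere are flagged silent and left as zeros.
#'
#' @slot activation numeric matrix, rows = conditions, cols = parts.
#' @slot winners integer vector of per-row winning part (NA for silent rows).
#' @slot silent logical vector flagging all-zero rows.
#' @slot tied logical vector flagging rows whose top entries tie.
#' @export
setClass("SelectivityMatrix",
  representation(activation = "matrix", winners = "integer",
                 silent = "logical", tied = "logical"),
  validity = function(object) {
    a <- object@activation
    errs <- character()
    if (length(a) && min(a) < 0) errs <- c(errs, "entries must be >= 0")
    rs <- rowSums(a)
    active <- !object@silent
    if (any(active) && any(abs(rs[active] - 1) > 1e-8))
      errs <- c(errs, "active rows must sum to 1")
    if (length(object@winners) != nrow(a))
      errs <- c(errs, "one winner entry per row required")
    if (length(errs)) errs else TRUE
  })

#' Control-value to oscillation (frequency, power) transfer map
#'
#' @slot control strictly increasing control values (mono/di weight ratio
#'   or weight-set index).
#' @slot peakFrequency seed-averaged oscillation peak frequency (Hz).
#' @slot peakPower seed-averaged peak power.
#' @slot regime indices (into `control`) of the largest contiguous run over
#'   which `peakFrequency` is strictly monotone.
#' @export
setClass("TransferMap",
  representation(control = "numeric", peakFrequency = "numeric",
                 peakPower = "numeric", regime = "integer"),
  validity = function(object) {
    errs <- character()
    if (length(object@control) > 1 && any(diff(object@control) <= 0))
      errs <- c(errs, "control values must be strictly increasing")
    if (length(object@peakFrequency) != length(object@control))
      errs <- c(errs, "one peakFrequency per control value required")
    if (length(object@regime) &&
        (min(object@regime) < 1 || max(object@regime) > length(object@control)))
      errs <- c(errs, "regime bounds must lie within the sampled range")
    if (length(errs)) errs else TRUE
  })

#' Aggregated result of one experiment driver
#'
#' Per-seed results are kept alongside every aggregate so that each
#' aggregated number is recomputable from the stored per-seed entries.
#'
#' @slot experiment experiment name.
#' @slot configHash hash of the effective configuration.
#' @slot seeds integer seeds used.
#' @slot perSeed list of per-seed (or per-trial) result records.
#' @slot aggregate named list of aggregated results.
#' @slot passed named logical vector of acceptance-property flags.
#' @export
setClass("ExperimentReport",
  representation(experiment = "character", configHash = "character",
                 seeds = "integer", perSeed = "list", aggregate = "list",
                 passed = "logical"))
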