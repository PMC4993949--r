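## Constructor functions: the exported way to build the S4 containers.

#' Create a LIF population
#'
#' Defaults follow standard cortical LIF practice: 10 ms (excitatory) or
#' 8 ms (inhibitory) membrane time constant, -70 mV rest and reset, -54 mV
#' threshold, 2 ms / 1 ms refractoriness.
#'
#' @param name population identifier.
#' @param size neuron count.
#' @param cellType `"excitatory"` or `"inhibitory"`.
#' @param tauM membrane time constant (ms).
#' @param vRest,vThresh,vReset potentials (mV).
#' @param tRef absolute refractory period (ms).
#' @param backgroundRate per-neuron Poisson noise rate (Hz).
#' @param backgroundWeight potential jump per background event (mV).
#' @return A [Population-class] object.
#' @examples
#' Population("E", 400, "excitatory", backgroundRate = 2000, backgroundWeight = 0.1)
#' @export
Population <- function(name, size, cellType = c("excitatory", "inhibitory"),
                       tauM = if (cellType == "excitatory") 10 else 8,
                       vRest = -70, vThresh = -54, vReset = -70,
                       tRef = if (cellType == "excitatory") 2 else 1,
                       backgroundRate = 0, backgroundWeight = 0) {
  cellType <- match.arg(cellType)
  force(tauM); force(tRef)
  new("Population", name = as.character(name), size = as.integer(size),
      cellType = cellType, tauM = as.numeric(tauM), vRest = as.numeric(vRest),
      vThresh = as.numeric(vThresh), vReset = as.numeric(vReset),
      tRef = as.numeric(tRef), backgroundRate = as.numeric(backgroundRate),
      backgroundWeight = as.numeric(backgroundWeight))
}

#' Create a synaptic connection
#'
#' @param source,target population names.
#' @param weight per-spike depolarisation magnitude (mV, >= 0); the
#'   postsynaptic sign follows the source population's cell type.
#' @param probability synapse existence probability.
#' @param delay conduction delay (ms).
#' @param tauSyn synaptic decay time constant (ms).
#' @return A [Connection-class] object.
#' @export
Connection <- function(source, target, weight, probability = 1,
                       delay = 1, tauSyn = 3) {
  new("Connection", source = as.character(source), target = as.character(target),
      weight = as.numeric(weight), probability = as.numeric(probability),
      delay = as.numeric(delay), tauSyn = as.numeric(tauSyn))
}

#' Assemble a network specification
#'
#' @param populations list of [Population-class] objects.
#' @param connections list of [Connection-class] objects.
#' @param labels named character vector mapping functional roles to
#'   population names.
#' @return A [NetworkSpec-class] object.
#' @seealso [validateNetwork()] for the full structural check,
#'   [buildOscillator()], [buildEncoder()], [buildRouter()] for the shipped
#'   circuit motifs.
#' @export
NetworkSpec <- function(populations, connections = list(), labels = character()) {
  new("NetworkSpec", populations = populations, connections = connections,
      labels = labels)
}

#' Create a simulation configuration
#'
#' @param dt integration step (ms); default 0.1 ms forward Euler.
#' @param duration simulated time (ms).
#' @param seed integer seed; the same seed and specs reproduce the run
#'   bit-exactly (connectivity realisation and all Poisson noise included).
#' @param recordVoltages also record per-population mean voltage traces.
#' @return A [SimulationConfig-class] object.
#' @export
SimulationConfig <- function(dt = 0.1, duration = 1000, seed = 1L,
                             recordVoltages = FALSE) {
  new("SimulationConfig", dt = as.numeric(dt), duration = as.numeric(duration),
      seed = as.integer(seed), recordVoltages = isTRUE(recordVoltages))
}

#' Create an engram readout weight set
#'
#' @param index readout part index (1-based).
#' @param wE weight from oscillator E cells onto the part's E neurons (mV).
#' @param wI weight from oscillator E cells onto the part's I neurons (mV).
#' @return An [EngramWeightSet-class] object.
#' @export
EngramWeightSet <- function(index, wE, wI) {
  new("EngramWeightSet", index = as.integer(index), wE = as.numeric(wE),
      wI = as.numeric(wI))
}

## ---- accessors ------------------------------------------------------------

#' Accessors for the core containers
#'
#' @param x the object.
#' @return `populations()` and `connections()` return lists;
#'   `networkLabels()` the role map; `spikeEvents()` the event data.frame;
#'   `popSizes()` a named integer vector; `peakFrequency()`/`peakPower()`
#'   scalar spectrum summaries; `activationMatrix()` and `rowWinners()` the
#'   selectivity table and its per-row argmax.
#' @name accessors
NULL

#' @rdname accessors
#' @export
populations <- function(x) x@populations

#' @rdname accessors
#' @export
connections <- function(x) x@connections

#' @rdname accessors
#' @export
networkLabels <- function(x) x@labels

#' @rdname accessors
#' @export
spikeEvents <- function(x) x@events

#' @rdname accessors
#' @export
popSizes <- function(x) x@popSizes

#' @rdname accessors
#' @export
peakFrequency <- function(x) x@peakFrequency

#' @rdname accessors
#' @export
peakPower <- function(x) x@peakPower

#' @rdname accessors
#' @export
activationMatrix <- function(x) x@activation

#' @rdname accessors
#' @export
rowWinners <- function(x) x@winners

## ---- show methods ----------------------------------------------------------

setMethod("show", "Population", function(object) {
  cat(sprintf("Population '%s': %d %s neurons (tauM=%g ms, thr=%g mV, bg=%g Hz)\n",
              object@name, object@size, object@cellType, object@tauM,
              object@vThresh, object@backgroundRate))
})

setMethod("show", "NetworkSpec", function(object) {
  nm <- vapply(object@populations, function(p) p@name, character(1))
  sz <- vapply(object@populations, function(p) p@size, integer(1))
  cat(sprintf("NetworkSpec: %d populations (%d neurons), %d connections\n",
              length(nm), sum(sz), length(object@connections)))
  cat("  populations:", paste(sprintf("%s[%d]", nm, sz), collapse = ", "), "\n")
  if (length(object@labels))
    cat("  roles:", paste(names(object@labels), object@labels,
                          sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf("SpikeRaster: %d spikes over %g ms, %d populations (seed %d)\n",
              nrow(object@events), object@duration, length(object@popSizes),
              object@seed))
})

setMethod("show", "SpectrumResult", function(object) {
  if (object@hasPeak)
    cat(sprintf("SpectrumResult: peak %.2f Hz (power %.3g), resolution %.2f Hz\n",
                object@peakFrequency, object@peakPower, object@resolution))
  else
    cat("SpectrumResult: no oscillation peak (flat trace)\n")
})

setMethod("show", "DelayMeasurement", function(object) {
  if (object@responded)
    cat(sprintf("DelayMeasurement '%s': response %.1f ms after onset\n",
                object@population, object@delay))
  else
    cat(sprintf("DelayMeasurement '%s': no response\n", object@population))
})

setMethod("show", "SelectivityMatrix", function(object) {
  cat(sprintf("SelectivityMatrix: %d conditions x %d parts\n",
              nrow(object@activation), ncol(object@activation)))
  print(round(object@activation, 3))
  cat("  winners:", paste(ifelse(is.na(object@winners), "-", object@winners),
                          collapse = " "), "\n")
})

setMethod("show", "TransferMap", function(object) {
  cat(sprintf("TransferMap: %d control values, monotone regime [%d..%d]\n",
              length(object@control),
              if (length(object@regime)) min(object@regime) else NA_integer_,
              if (length(object@regime)) max(object@regime) else NA_integer_))
  print(data.frame(control = object@control,
                   peakFrequency = round(object@peakFrequency, 2),
                   peakPower = signif(object@peakPower, 3)))
})

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport '%s': %d seeds, config %s\n",
              object@experiment, length(object@seeds), object@configHash))
  if (length(object@passed))
    cat("  flags:", paste(names(object@passed), object@passed,
                          sep = "=", collapse = ", "), "\n")
})
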