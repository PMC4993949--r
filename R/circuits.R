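## Circuit builders for the two motifs:
##  - encoder (spatial -> temporal): sparse engram source populations drive
##    a recurrent E-I oscillator; each source reaches the inhibitory
##    population both mono-synaptically and di-synaptically (through an
##    excitatory relay), and the mono/di weight ratio at fixed total
##    I-directed weight sets the oscillation's frequency and power.
##  - router (temporal -> spatial): an oscillatory Input1 (di-synaptic,
##    via a relay) and a constant Input2 (mono-synaptic) impinge on the
##    oscillator's I population; the oscillator's E spikes fan out to
##    several small E-I engram readout parts with part-specific weights
##    (wE onto part E, wI onto part I), making each part respond in its
##    own drive-frequency band.

#' Default oscillator parameters
#'
#' Parameter bundle for [buildOscillator()]: population sizes, Poisson
#' background (rate Hz, weight mV), the four recurrent weight/probability
#' pairs, synaptic time constants and conduction delay. The shipped
#' defaults are the calibrated set under which sustained drive evokes a
#' clear population oscillation (see the package vignette).
#'
#' @param ... overrides of the named defaults.
#' @return named list of oscillator parameters.
#' @export
oscillatorParams <- function(...) {
  p <- list(
    nE = 400L, nI = 100L,
    bgRateE = 2000, bgWeightE = 1.0,
    bgRateI = 1000, bgWeightI = 0.4,
    wEE = 0.15, pEE = 0.10,
    wEI = 0.30, pEI = 0.20,
    wIE = 0.80, pIE = 0.30,
    wII = 0.50, pII = 0.30,
    tauSynE = 3, tauSynI = 6, delay = 1)
  modifyListStrict(p, list(...), "oscillator")
}

#' Default engram readout-part parameters
#'
#' Bundle for the small interconnected E-I readout parts of
#' [buildRouter()]. Part E neurons are slow integrators (`tauME`) that
#' detect the duration of the oscillator's per-cycle firing windows
#' (long at low drive frequency, short at high); part I neurons are
#' faster veto units whose feedforward inhibition cancels the part's
#' response once their own input threshold is reached. A weak private
#' background keeps the baseline rate measurable.
#'
#' @param ... overrides of the named defaults.
#' @return named list of part parameters.
#' @export
partParams <- function(...) {
  p <- list(
    nE = 80L, nI = 20L,
    tauME = 10, tauMI = 8,
    bgRateE = 200, bgWeightE = 0.3,
    bgRateI = 0, bgWeightI = 0,
    wEE = 0.05, pEE = 0.20,
    wEI = 0.30, pEI = 0.50,
    wIE = 2.50, pIE = 0.80,
    tauSynE = 4, tauSynI = 4, delay = 1,
    pIn = 0.70, tauSynInE = 3, tauSynInI = 3)
  modifyListStrict(p, list(...), "part")
}

#' Default encoder parameters
#'
#' Bundle for [buildEncoder()]: engram-source and relay sizes, the weight
#' from sources onto the oscillator's E population, the fixed total
#' I-directed weight that the mono/di ratio splits, and the relay chain.
#'
#' @param ... overrides of the named defaults.
#' @return named list of encoder parameters.
#' @export
encoderParams <- function(...) {
  p <- list(
    nSource = 20L, nRelay = 30L,
    wSourceE = 0.30, pSourceE = 0.50,
    wITotal = 0.5, pSourceI = 0.50,
    wSourceRelay = 0.55, pSourceRelay = 1.0,
    relayGain = 0.3, pRelayI = 0.50,
    wIRelay = 0.0, pIRelay = 0.60, tauSynIRelay = 30,
    wRelayE = 2.8, pRelayE = 0.30,
    tauMRelay = 25, bgRateRelay = 1000, bgWeightRelay = 0.5,
    delayMono = 1.5, delayHop = 1.5,
    tauSynSource = 3, tauSynRelay = 3)
  modifyListStrict(p, list(...), "encoder")
}

# modifyList with unknown-key rejection: silent typos are the dominant
# failure mode of simulation parameter bundles.
modifyListStrict <- function(base, overrides, what) {
  if (!length(overrides)) return(base)
  bad <- setdiff(names(overrides), names(base))
  if (length(bad))
    stop(sprintf("unknown %s parameter(s): %s", what,
                 paste(bad, collapse = ", ")))
  utils::modifyList(base, overrides)
}

oscPopulations <- function(o) {
  list(Population("osc_E", o$nE, "excitatory",
                  backgroundRate = o$bgRateE, backgroundWeight = o$bgWeightE),
       Population("osc_I", o$nI, "inhibitory",
                  backgroundRate = o$bgRateI, backgroundWeight = o$bgWeightI))
}

oscConnections <- function(o) {
  list(Connection("osc_E", "osc_E", o$wEE, o$pEE, o$delay, o$tauSynE),
       Connection("osc_E", "osc_I", o$wEI, o$pEI, o$delay, o$tauSynE),
       Connection("osc_I", "osc_E", o$wIE, o$pIE, o$delay, o$tauSynI),
       Connection("osc_I", "osc_I", o$wII, o$pII, o$delay, o$tauSynI))
}

#' Build a recurrent E-I oscillator
#'
#' One excitatory and one inhibitory population with all four recurrent
#' connection classes (E->E, E->I, I->E, I->I). The excitatory population
#' carries a strong Poisson background, so that rhythmic modulation of the
#' inhibitory population sculpts tonic E firing into a population
#' oscillation.
#'
#' @param params bundle from [oscillatorParams()].
#' @return A validated [NetworkSpec-class] with labels `oscillator_E`,
#'   `oscillator_I`.
#' @export
buildOscillator <- function(params = oscillatorParams()) {
  net <- NetworkSpec(
    populations = oscPopulations(params),
    connections = oscConnections(params),
    labels = c(oscillator_E = "osc_E", oscillator_I = "osc_I"))
  assertValid(net)
}

#' Build the engram-to-oscillator encoder
#'
#' For each engram source population k: a projection onto the oscillator's
#' E cells, a mono-synaptic projection onto its I cells, and a di-synaptic
#' route through a dedicated excitatory relay onto the same I cells. The
#' per-engram `ratio` r splits the fixed total I-directed weight `wITotal`
#' as mono `= r/(1+r)` and di `= 1/(1+r)`, so distinct ratios give
#' distinct oscillation frequencies at equal total drive. The di-synaptic
#' route is strictly slower than the mono-synaptic one (two hops plus
#' relay integration), and the relay receives slow feedback inhibition
#' from the oscillator's I population: when the di route dominates, the
#' relay-I loop paces a slow rhythm, whereas mono-dominant drive yields
#' fast recurrent E-I (PING-like) cycles — this is what stretches the
#' ratio-to-frequency map across several octaves.
#'
#' @param nEngrams number of engram sources (>= 1).
#' @param ratios mono/di weight ratio per engram; pairwise distinct.
#' @param oscParams bundle from [oscillatorParams()].
#' @param encParams bundle from [encoderParams()].
#' @return A validated [NetworkSpec-class] with labels `engram_source_k`,
#'   `relay_k` for each source.
#' @export
buildEncoder <- function(nEngrams = 3L,
                         ratios = c(0.2, 1.0, 4.0),
                         oscParams = oscillatorParams(),
                         encParams = encoderParams()) {
  stopifnot(nEngrams >= 1L, length(ratios) == nEngrams)
  if (any(ratios < 0)) stop("ratios must be >= 0")
  if (anyDuplicated(ratios))
    stop("duplicate mono/di ratios: engram sources would be indistinguishable")
  e <- encParams
  pops <- oscPopulations(oscParams)
  conns <- oscConnections(oscParams)
  labels <- c(oscillator_E = "osc_E", oscillator_I = "osc_I")
  for (k in seq_len(nEngrams)) {
    src <- sprintf("src_%d", k); rel <- sprintf("relay_%d", k)
    r <- ratios[k]
    wMono <- e$wITotal * r / (1 + r)
    wDi <- e$wITotal * 1 / (1 + r) * e$relayGain
    pops <- c(pops,
              Population(src, e$nSource, "excitatory"),
              Population(rel, e$nRelay, "excitatory", tauM = e$tauMRelay,
                         backgroundRate = e$bgRateRelay,
                         backgroundWeight = e$bgWeightRelay))
    wDiE <- e$wRelayE * 1 / (1 + r)
    conns <- c(conns, list(
      Connection(src, "osc_E", e$wSourceE, e$pSourceE, e$delayMono,
                 e$tauSynSource),
      Connection(rel, "osc_E", wDiE, e$pRelayE, e$delayHop,
                 e$tauSynSource),
      Connection(src, "osc_I", wMono, e$pSourceI, e$delayMono,
                 e$tauSynSource),
      Connection(src, rel, e$wSourceRelay, e$pSourceRelay, e$delayHop,
                 e$tauSynRelay),
      Connection(rel, "osc_I", wDi, e$pRelayI, e$delayHop, e$tauSynSource),
      Connection("osc_I", rel, e$wIRelay, e$pIRelay, e$delayHop,
                 e$tauSynIRelay)))
    labels[sprintf("engram_source_%d", k)] <- src
    labels[sprintf("relay_%d", k)] <- rel
  }
  assertValid(NetworkSpec(pops, conns, labels))
}

#' Build the oscillator-to-engram router
#'
#' The oscillator plus one excitatory input relay (the di-synaptic route
#' for the oscillatory Input1 onto the oscillator's I cells) plus one
#' small interconnected E-I readout part per weight set. The oscillator's
#' E population projects onto part k's E neurons with `wE(k)` and onto its
#' I neurons with `wI(k)`; the (wE, wI) pairs must be pairwise distinct.
#'
#' @param oscParams bundle from [oscillatorParams()].
#' @param weightSets list of [EngramWeightSet-class] (>= 1).
#' @param engramParams bundle from [partParams()].
#' @return A validated [NetworkSpec-class] with labels `engram_k_E`,
#'   `engram_k_I`, `relay_input`.
#' @export
buildRouter <- function(oscParams = oscillatorParams(),
                        weightSets = defaultWeightSets(),
                        engramParams = partParams()) {
  stopifnot(length(weightSets) >= 1)
  pairs <- vapply(weightSets, function(w) c(w@wE, w@wI), numeric(2))
  if (anyDuplicated(t(pairs)))
    stop("duplicate engram weight sets: readout parts would be indistinguishable")
  g <- engramParams
  pops <- c(oscPopulations(oscParams),
            Population("relay_input", 20L, "excitatory"))
  conns <- c(oscConnections(oscParams),
             list(Connection("relay_input", "osc_I", 1.0, 0.5, 1.5,
                             oscParams$tauSynE)))
  labels <- c(oscillator_E = "osc_E", oscillator_I = "osc_I",
              relay_input = "relay_input")
  for (w in weightSets) {
    k <- w@index
    pe <- sprintf("part%d_E", k); pin <- sprintf("part%d_I", k)
    pops <- c(pops,
              Population(pe, g$nE, "excitatory", tauM = g$tauME,
                         backgroundRate = g$bgRateE,
                         backgroundWeight = g$bgWeightE),
              Population(pin, g$nI, "inhibitory", tauM = g$tauMI,
                         backgroundRate = g$bgRateI,
                         backgroundWeight = g$bgWeightI))
    conns <- c(conns, list(
      Connection("osc_E", pe, w@wE, g$pIn, g$delay, g$tauSynInE),
      Connection("osc_E", pin, w@wI, g$pIn, g$delay, g$tauSynInI),
      Connection(pe, pe, g$wEE, g$pEE, g$delay, g$tauSynE),
      Connection(pe, pin, g$wEI, g$pEI, g$delay, g$tauSynE),
      Connection(pin, pe, g$wIE, g$pIE, g$delay, g$tauSynI)))
    labels[sprintf("engram_%d_E", k)] <- pe
    labels[sprintf("engram_%d_I", k)] <- pin
  }
  assertValid(NetworkSpec(pops, conns, labels))
}

#' Default router weight sets
#'
#' The three calibrated (wE, wI) pairs under which readout parts 1, 2 and
#' 3 respond selectively to the low, medium and high drive-frequency
#' bands. Values live in the shipped default configuration
#' (`inst/extdata/configs/router_weights.yaml`), not in code.
#'
#' @return list of three [EngramWeightSet-class] objects.
#' @export
defaultWeightSets <- function() {
  path <- system.file("extdata", "configs", "router_weights.yaml",
                      package = "engramosc")
  ws <- yaml::read_yaml(path)$weight_sets
  lapply(ws, function(w) EngramWeightSet(w$index, w$wE, w$wI))
}

assertValid <- function(network) {
  viol <- validateNetwork(network)
  if (length(viol))
    stop("builder produced an invalid network:\n  ",
         paste(viol, collapse = "\n  "))
  network
}

#' Validate a network specification
#'
#' Structural checks beyond class validity: reference integrity, Dale's
#' law (non-negative weight magnitudes; signs are fixed by cell type),
#' conduction delays of at least one integration step, and role-label
#' completeness (an oscillator role set must come with all four recurrent
#' connection classes).
#'
#' @param network a [NetworkSpec-class].
#' @param dt integration step the network will be run at (ms).
#' @return character vector of violations; empty means valid.
#' @export
validateNetwork <- function(network, dt = 0.1) {
  v <- character()
  nm <- vapply(network@populations, function(p) p@name, character(1))
  ct <- stats::setNames(
    vapply(network@populations, function(p) p@cellType, character(1)), nm)
  for (cn in network@connections) {
    if (!cn@source %in% nm)
      v <- c(v, sprintf("connection source '%s' does not exist", cn@source))
    if (!cn@target %in% nm)
      v <- c(v, sprintf("connection target '%s' does not exist", cn@target))
    if (cn@weight < 0)
      v <- c(v, sprintf("Dale's law violation: negative weight magnitude on %s -> %s",
                        cn@source, cn@target))
    if (cn@delay < dt - 1e-12)
      v <- c(v, sprintf("delay %.3g ms on %s -> %s is below one step (%g ms)",
                        cn@delay, cn@source, cn@target, dt))
  }
  bad <- network@labels[!network@labels %in% nm]
  for (b in seq_along(bad))
    v <- c(v, sprintf("label '%s' references missing population '%s'",
                      names(bad)[b], bad[b]))
  lb <- network@labels
  if (all(c("oscillator_E", "oscillator_I") %in% names(lb))) {
    oe <- lb[["oscillator_E"]]; oi <- lb[["oscillator_I"]]
    have <- vapply(network@connections,
                   function(cn) paste(cn@source, cn@target, sep = ">"),
                   character(1))
    need <- c(paste(oe, oe, sep = ">"), paste(oe, oi, sep = ">"),
              paste(oi, oe, sep = ">"), paste(oi, oi, sep = ">"))
    miss <- setdiff(need, have)
    for (m in miss)
      v <- c(v, sprintf("oscillator missing recurrent connection class %s",
                        sub(">", " -> ", m)))
    if (ct[[oe]] != "excitatory" || ct[[oi]] != "inhibitory")
      v <- c(v, "oscillator roles must map to one excitatory and one inhibitory population")
  } else if (any(c("oscillator_E", "oscillator_I") %in% names(lb))) {
    v <- c(v, "oscillator role set must contain both oscillator_E and oscillator_I")
  }
  v
}
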