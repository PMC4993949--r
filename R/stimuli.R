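## External inputs. Drives are deterministic: only the network's Poisson
## background is stochastic. The oscillatory waveform is a half-rectified
## sinusoid (a current-based model cannot inject negative drive through an
## excitatory pathway), which has a single spectral peak at its frequency.

#' Create an oscillatory (half-rectified sinusoid) drive
#'
#' The rendered waveform is
#' `amplitude * max(0, sin(2 pi f (t - onset)/1000 + phase))` inside
#' `[onset, offset)` and exactly zero outside. The canonical use is Input1
#' of the routing circuit: rhythmic drive delivered onto the oscillator's
#' inhibitory population through the di-synaptic relay.
#'
#' @param frequency sinusoid frequency (Hz, > 0).
#' @param amplitude peak drive (mV/ms equivalent current, >= 0).
#' @param onset,offset drive window (ms).
#' @param target nominal target population name.
#' @param pathway `"di_synaptic"` (default for Input1) or `"mono_synaptic"`.
#' @param relay relay population name (required for di-synaptic drives).
#' @param phase phase at onset (radians).
#' @return A [DriveSpec-class].
#' @export
makeOscillatoryDrive <- function(frequency, amplitude, onset, offset,
                                 target, pathway = "di_synaptic",
                                 relay = NA_character_, phase = 0) {
  new("DriveSpec", target = as.character(target), pathwayKind = pathway,
      relay = as.character(relay), kind = "sinusoid",
      amplitude = as.numeric(amplitude), frequency = as.numeric(frequency),
      phase = as.numeric(phase), onset = as.numeric(onset),
      offset = as.numeric(offset))
}

#' Create a constant drive
#'
#' Flat current inside `[onset, offset)`, zero outside. The canonical use
#' is Input2 of the routing circuit: tonic, just-subthreshold drive onto
#' the oscillator's inhibitory population through the mono-synaptic
#' pathway, which the peaks of the oscillatory Input1 then lift into the
#' oscillation regime.
#'
#' @inheritParams makeOscillatoryDrive
#' @return A [DriveSpec-class].
#' @export
makeConstantDrive <- function(amplitude, onset, offset, target,
                              pathway = "mono_synaptic",
                              relay = NA_character_) {
  new("DriveSpec", target = as.character(target), pathwayKind = pathway,
      relay = as.character(relay), kind = "constant",
      amplitude = as.numeric(amplitude), frequency = NA_real_,
      phase = 0, onset = as.numeric(onset), offset = as.numeric(offset))
}

#' Render a drive as a per-step current vector
#'
#' Samples the drive at the start of each integration step
#' (`t = 0, dt, 2 dt, ...`). A step contributes iff
#' `onset <= t < offset`; windows extending past the simulated duration
#' are truncated without error. Multiple drives on one population sum.
#'
#' @param drive a [DriveSpec-class].
#' @param config a [SimulationConfig-class] (supplies `dt` and `duration`).
#' @return numeric vector of length `duration/dt` (mV/ms).
#' @export
renderDrive <- function(drive, config) {
  n_steps <- as.integer(round(config@duration / config@dt))
  t <- (seq_len(n_steps) - 1L) * config@dt
  inside <- t >= drive@onset & t < drive@offset
  out <- numeric(n_steps)
  if (drive@kind == "constant") {
    out[inside] <- drive@amplitude
  } else {
    s <- sin(2 * pi * drive@frequency * (t[inside] - drive@onset) / 1000 +
             drive@phase)
    out[inside] <- drive@amplitude * pmax(0, s)
  }
  out
}
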