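## Configuration and report I/O. Configs are YAML with strict unknown-key
## rejection and default filling: the effective config an experiment runs
## under is always fully explicit, hashable and reproducible. Reports are
## JSON with an embedded content hash.

configSkeleton <- function(name) {
  common <- list(
    simulation = list(dt = 0.1, duration = 4000, record_voltages = FALSE),
    analysis = list(
      band = c(2, 80), rate_bin = 2,
      delay = list(bin = 10, k = 3, m = 3, floor_rate = 2)),
    network = list(
      oscillator = oscillatorParams(),
      encoder_oscillator = oscillatorParams(),
      part = partParams(),
      encoder = encoderParams(),
      weight_sets = list(),
      ratios = numeric()),
    drives = list(
      input1 = list(amplitude = 0, onset = 1000, offset = 4000),
      input2 = list(amplitude = 0, onset = 0, offset = 4000),
      source = list(amplitude = 0, onset = 1000, offset = 4000)))
  exp <- switch(name,
    temporal_to_spatial = list(
      name = "temporal_to_spatial", conditions = numeric(),
      n_seeds = 10L, base_seed = 42L),
    spatial_to_temporal = list(
      name = "spatial_to_temporal", n_seeds = 20L,
      n_calibration_seeds = 10L, base_seed = 42L),
    round_trip = list(
      name = "round_trip", conditions = numeric(), n_seeds = 20L,
      n_calibration_seeds = 5L, base_seed = 42L),
    sweep = list(
      name = "sweep", ratios = numeric(), n_seeds = 5L, base_seed = 42L),
    stop(sprintf("unknown experiment name '%s'", name)))
  c(list(experiment = exp), common)
}

# strict recursive merge: every override key must exist in the skeleton;
# unnamed lists (weight_sets, ratios, conditions) are replaced wholesale.
mergeConfig <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- paste0(path, nm)
    if (!nm %in% names(base))
      stop(sprintf("unknown config key '%s'", here))
    bv <- base[[nm]]; ov <- override[[nm]]
    if (is.list(bv) && length(names(bv)) && is.list(ov)) {
      base[[nm]] <- mergeConfig(bv, ov, paste0(here, "$"))
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

validateConfig <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  sim <- cfg$simulation
  chk(sim$dt > 0, "simulation$dt must be > 0")
  chk(sim$duration >= sim$dt, "simulation$duration must be >= dt")
  for (dn in names(cfg$drives)) {
    d <- cfg$drives[[dn]]
    chk(d$amplitude >= 0, sprintf("drives$%s$amplitude must be >= 0", dn))
    chk(d$offset > d$onset, sprintf("drives$%s: offset must exceed onset", dn))
    chk(d$onset >= 0, sprintf("drives$%s$onset must be >= 0", dn))
  }
  chk(cfg$analysis$band[2] > cfg$analysis$band[1],
      "analysis$band must be increasing")
  nm <- cfg$experiment$name
  if (nm %in% c("temporal_to_spatial", "round_trip")) {
    ws <- cfg$network$weight_sets
    chk(length(ws) >= 1, "network$weight_sets must be non-empty")
    if (nm == "temporal_to_spatial")
      chk(length(cfg$experiment$conditions) >= 2,
          "experiment$conditions needs >= 2 frequency conditions")
  }
  if (nm %in% c("spatial_to_temporal", "round_trip", "sweep")) {
    rat <- cfg$network$ratios
    chk(length(rat) >= if (nm == "sweep") 2 else 1,
        "network$ratios must be set")
    chk(!anyDuplicated(rat), "network$ratios must be pairwise distinct")
  }
  errs
}

#' Load, validate and default-fill an experiment configuration
#'
#' Reads a YAML experiment config, merges it over the built-in skeleton
#' for its experiment type (so every effective value is explicit), rejects
#' unknown keys with a path-to-field diagnostic, and validates
#' cross-references and invariants.
#'
#' @param path YAML file path.
#' @return the effective config: a fully populated named list.
#' @seealso [saveConfig()], [defaultConfig()]
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment$name))
    stop("config must declare experiment$name")
  cfg <- mergeConfig(configSkeleton(raw$experiment$name), raw)
  cfg <- normalizeConfig(cfg)
  errs <- validateConfig(cfg)
  if (length(errs))
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

# YAML reads integers/reals contextually; normalise the handful of fields
# whose types the experiments rely on.
normalizeConfig <- function(cfg) {
  for (f in c("n_seeds", "n_calibration_seeds", "base_seed"))
    if (!is.null(cfg$experiment[[f]]))
      cfg$experiment[[f]] <- as.integer(cfg$experiment[[f]])
  for (f in c("conditions", "ratios"))
    if (!is.null(cfg$experiment[[f]]))
      cfg$experiment[[f]] <- as.numeric(cfg$experiment[[f]])
  cfg$network$ratios <- as.numeric(cfg$network$ratios)
  cfg$analysis$band <- as.numeric(cfg$analysis$band)
  for (f in c("nE", "nI"))
    for (s in c("oscillator", "encoder_oscillator", "part"))
      cfg$network[[s]][[f]] <- as.integer(cfg$network[[s]][[f]])
  for (f in c("nSource", "nRelay"))
    cfg$network$encoder[[f]] <- as.integer(cfg$network$encoder[[f]])
  cfg
}

#' @rdname loadConfig
#' @param cfg an effective config list.
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Shipped default configuration for an experiment
#'
#' @param name one of `"t2s"`, `"s2t"`, `"roundtrip"`, `"sweep"`.
#' @return the effective config list (see [loadConfig()]).
#' @export
defaultConfig <- function(name = c("t2s", "s2t", "roundtrip", "sweep")) {
  name <- match.arg(name)
  loadConfig(system.file("extdata", "configs", paste0(name, ".yaml"),
                         package = "engramosc"))
}

#' Hash of an effective configuration
#'
#' @param cfg an effective config list.
#' @return short hash string identifying the configuration.
#' @export
configHash <- function(cfg) rlang::hash(cfg)

## ---- reports ---------------------------------------------------------------

reportToList <- function(report) {
  list(experiment = report@experiment,
       config_hash = report@configHash,
       seeds = report@seeds,
       per_seed = report@perSeed,
       aggregate = report@aggregate,
       passed = as.list(report@passed))
}

hasNonFinite <- function(x) {
  if (is.list(x)) return(any(vapply(x, hasNonFinite, logical(1))))
  is.numeric(x) && length(x) && any(is.nan(x) | is.infinite(x))
}

#' Write / read an experiment report as JSON
#'
#' Lossless JSON round-trip of an [ExperimentReport-class], with an
#' embedded content hash: `readReport` recomputes the hash over the body
#' and warns when it disagrees (tampered or hand-edited file). Non-finite
#' numbers serialise as explicit nulls with a warning.
#'
#' @param report an [ExperimentReport-class].
#' @param path JSON file path.
#' @return `writeReport` returns `path` invisibly; `readReport` the report.
#' @export
writeReport <- function(report, path) {
  body <- reportToList(report)
  if (hasNonFinite(body))
    warning("report contains non-finite values; serialising as null")
  body$integrity <- rlang::hash(
    jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, na = "null"))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  # integrity is recomputed over the unsimplified parse, which re-serialises
  # to the same JSON the writer hashed
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  integrity <- raw$integrity
  raw$integrity <- NULL
  expect <- rlang::hash(
    jsonlite::toJSON(raw, auto_unbox = TRUE, digits = NA, na = "null"))
  if (!identical(integrity, expect))
    warning(sprintf("report '%s': embedded hash does not match content", path))
  body <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = TRUE)
  new("ExperimentReport",
      experiment = body$experiment,
      configHash = body$config_hash,
      seeds = as.integer(body$seeds),
      perSeed = body$per_seed,
      aggregate = body$aggregate,
      passed = vapply(body$passed, isTRUE, logical(1)))
}
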