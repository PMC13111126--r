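# Configuration: construction, exhaustive validation, YAML round-trip.

configFieldNames <- function() {
  c("mode", "nlcc", "ratio", "phi", "eta", "dt", "period", "beats",
    "discard", "seed", "stimAmplitude", "stimDuration", "outputDir",
    "parameterFile")
}

# every violation is reported, not just the first
configViolations <- function(object) {
  msgs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) msgs <<- c(msgs, msg)
  chk(object@mode %in% c("stochastic", "deterministic"),
      "mode must be 'stochastic' or 'deterministic'")
  chk(length(object@nlcc) >= 1 && all(is.finite(object@nlcc)) &&
        all(object@nlcc >= 1) && all(object@nlcc == round(object@nlcc)),
      "nlcc must be one or more integers >= 1")
  chk(length(object@ratio) == 1 && is.finite(object@ratio) &&
        object@ratio >= 1, "ratio must be a single number >= 1")
  chk(length(object@phi) == 1 && is.finite(object@phi) && object@phi > 0,
      "phi must be a single positive number")
  chk(length(object@eta) == 1 && is.finite(object@eta) && object@eta > 0,
      "eta must be a single positive number")
  chk(length(object@dt) == 1 && is.finite(object@dt) && object@dt > 0,
      "dt must be a single positive number")
  chk(length(object@period) == 1 && is.finite(object@period) &&
        object@period > 0, "period must be a single positive number")
  chk(length(object@beats) == 1 && is.finite(object@beats) &&
        object@beats >= 1 && object@beats == round(object@beats),
      "beats must be a single integer >= 1")
  chk(length(object@discard) == 1 && is.finite(object@discard) &&
        object@discard >= 0 && object@discard == round(object@discard),
      "discard must be a single integer >= 0")
  if (length(object@beats) == 1 && length(object@discard) == 1 &&
      is.finite(object@beats) && is.finite(object@discard))
    chk(object@discard < object@beats, "discard must be smaller than beats")
  chk(length(object@seed) == 1 && is.finite(object@seed) &&
        object@seed == round(object@seed),
      "seed must be a single integer")
  chk(length(object@stimAmplitude) == 1 && is.finite(object@stimAmplitude),
      "stimAmplitude must be a single number")
  chk(length(object@stimDuration) == 1 && is.finite(object@stimDuration) &&
        object@stimDuration > 0, "stimDuration must be a single positive number")
  msgs
}

#' Build a simulation configuration
#'
#' All arguments default to the standard control protocol: deterministic
#' mode, 1 Hz pacing, dt = 0.001 ms, 1100 beats with the first 100
#' discarded, NRyR = 5 NLCC.
#'
#' @param mode "stochastic" or "deterministic".
#' @param nlcc L-type channel count(s); a vector defines a sweep grid.
#' @param ratio RyR:LCC ratio r (NRyR = r * NLCC).
#' @param phi phosphorylation multiplier.
#' @param eta LCC inactivation-rate multiplier.
#' @param dt time step (ms).
#' @param period pacing period (ms).
#' @param beats,discard total and discarded beat counts.
#' @param seed integer random seed.
#' @param stimAmplitude,stimDuration stimulus height (pA/pF) and width (ms).
#' @param outputDir,parameterFile optional output directory and parameter
#'   table path ("" = packaged defaults).
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(mode = "stochastic", nlcc = c(16, 32, 64), beats = 60,
#'                  discard = 10, seed = 42)
#' @export
simulationConfig <- function(mode = "deterministic", nlcc = 128, ratio = 5,
                             phi = 1, eta = 1, dt = 0.001, period = 1000,
                             beats = 1100, discard = 100, seed = 1,
                             stimAmplitude = 52, stimDuration = 1,
                             outputDir = "", parameterFile = "") {
  new("SimulationConfig", mode = mode, nlcc = as.numeric(nlcc),
      ratio = as.numeric(ratio), phi = as.numeric(phi),
      eta = as.numeric(eta), dt = as.numeric(dt),
      period = as.numeric(period), beats = as.numeric(beats),
      discard = as.numeric(discard), seed = as.numeric(seed),
      stimAmplitude = as.numeric(stimAmplitude),
      stimDuration = as.numeric(stimDuration),
      outputDir = outputDir, parameterFile = parameterFile)
}

#' Load and validate a configuration file
#'
#' Reads a YAML key-value file; unknown keys are rejected and all schema
#' violations are reported together.  An empty file yields the default
#' (deterministic control) configuration.
#'
#' @param path configuration file path.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration file must contain key: value pairs")
  errs <- character()
  unknown <- setdiff(names(raw), configFieldNames())
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  known <- raw[intersect(names(raw), configFieldNames())]
  cfg <- tryCatch(do.call(simulationConfig, known), error = function(e) e)
  if (inherits(cfg, "error")) {
    # rebuild without validity to collect every violation exhaustively
    proto <- simulationConfig()
    for (nm in names(known)) {
      v <- known[[nm]]
      slot(proto, nm) <- if (is.character(slot(proto, nm)))
        as.character(v) else as.numeric(v)
    }
    errs <- c(errs, configViolations(proto))
    if (!length(errs)) errs <- conditionMessage(cfg)
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' @rdname loadConfig
#' @param config a \linkS4class{SimulationConfig}.
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  x <- lapply(stats::setNames(configFieldNames(), configFieldNames()),
              function(nm) {
                v <- slot(config, nm)
                if (is.numeric(v)) v <- unname(v)
                v
              })
  yaml::write_yaml(x, path)
  invisible(path)
}

# stable content hash of a configuration (djb2 over its YAML rendering)
configHash <- function(config) {
  s <- yaml::as.yaml(lapply(configFieldNames(),
                            function(nm) slot(config, nm)))
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
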