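#' Model configuration
#'
#' Collects every tunable of the oscillation-modulated node model. Defaults
#' correspond to the calibration used for all shipped experiments: a 6.25 Hz
#' unit-amplitude cosine oscillator, base activation threshold 1, base
#' inhibition -0.2, 80 ms rectangular stimulus pulses (half an oscillator
#' cycle) and a 1 ms integration step.
#'
#' @param osc_frequency oscillator frequency in Hz.
#' @param osc_amplitude oscillation amplitude in activation units.
#' @param osc_phase_offset phase offset in radians; with the default 0 the
#'   cosine peaks at t = 0 and at every multiple of the period.
#' @param base_threshold activation threshold of unreduced nodes.
#' @param threshold_reduction amount subtracted from the threshold of
#'   high-frequency (sensitive) units; must lie in \[0, 0.5\].
#' @param base_inhibition negative rest-inhibition constant B. After a node
#'   activates it receives an excitatory burst -3B for the first 20 ms, a
#'   strong self-inhibition +3B up to 100 ms, and B thereafter.
#' @param excitation_window_ms,inhibition_window_ms the two post-activation
#'   windows in ms, `c(0, 20)` and `c(20, 100)` by default.
#' @param dt_ms integration step in ms (integer, >= 1).
#' @param input_mode `"stable"` for rectangular pulses or `"linear_ramp"`
#'   for input ramping linearly from 0 to its peak over the event.
#' @param topology `"parallel"` or `"hierarchical"` (see
#'   [build_connectivity()]).
#' @param sensitivity_enabled if `FALSE` all thresholds equal
#'   `base_threshold` regardless of `threshold_reduction` (control model).
#' @param stimulus_duration_ms duration of a stimulus event in ms.
#' @param train_rate_hz presentation rate of the entrainment train of empty
#'   words (stimulus property, kept at 6.25 Hz even when the internal
#'   oscillator frequency is varied).
#' @param n_entrain number of empty-word events in the entrainment train.
#' @param warmup_cycles oscillator cycles simulated before the first event
#'   so post-activation dynamics are cycle-stationary at probe time.
#' @param decision_window_cycles length, in oscillator cycles, of the window
#'   after probe onset within which threshold crossings count as responses.
#' @return An object of class `model_config` (a validated list).
#' @export
model_config <- function(osc_frequency = 6.25,
                         osc_amplitude = 1,
                         osc_phase_offset = 0,
                         base_threshold = 1,
                         threshold_reduction = 0,
                         base_inhibition = -0.2,
                         excitation_window_ms = c(0, 20),
                         inhibition_window_ms = c(20, 100),
                         dt_ms = 1,
                         input_mode = c("stable", "linear_ramp"),
                         topology = c("parallel", "hierarchical"),
                         sensitivity_enabled = TRUE,
                         stimulus_duration_ms = 80,
                         train_rate_hz = 6.25,
                         n_entrain = 5,
                         warmup_cycles = 3,
                         decision_window_cycles = 2) {
  input_mode <- match.arg(input_mode)
  topology <- match.arg(topology)
  if (!is.numeric(osc_frequency) || osc_frequency <= 0)
    stop("osc_frequency must be > 0")
  if (threshold_reduction < 0 || threshold_reduction > 0.5)
    stop("threshold_reduction must lie in [0, 0.5]")
  if (base_inhibition >= 0)
    stop("base_inhibition must be negative")
  if (dt_ms < 1 || dt_ms != round(dt_ms))
    stop("dt_ms must be an integer >= 1")
  if (excitation_window_ms[1] != 0 ||
      excitation_window_ms[2] != inhibition_window_ms[1] ||
      inhibition_window_ms[2] <= inhibition_window_ms[1])
    stop("post-activation windows must be contiguous: [0, a), [a, b]")
  if (n_entrain < 3)
    stop("n_entrain must be >= 3 so the pre-probe state is periodic")
  structure(
    list(osc_frequency = osc_frequency, osc_amplitude = osc_amplitude,
         osc_phase_offset = osc_phase_offset,
         base_threshold = base_threshold,
         threshold_reduction = threshold_reduction,
         base_inhibition = base_inhibition,
         excitation_window_ms = excitation_window_ms,
         inhibition_window_ms = inhibition_window_ms,
         dt_ms = dt_ms, input_mode = input_mode, topology = topology,
         sensitivity_enabled = sensitivity_enabled,
         stimulus_duration_ms = stimulus_duration_ms,
         train_rate_hz = train_rate_hz, n_entrain = n_entrain,
         warmup_cycles = warmup_cycles,
         decision_window_cycles = decision_window_cycles),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Load a model configuration from a YAML or JSON file
#'
#' The file holds a flat mapping mirroring the [model_config()] argument
#' names; fields not present keep their defaults. Entries in `overrides`
#' take precedence over the file.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @param overrides named list of field overrides.
#' @return A `model_config`.
#' @export
load_model_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(model_config)))
    if (length(unknown))
      stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  vals[names(overrides)] <- overrides
  do.call(model_config, vals)
}

#' Oscillation value at a time point
#'
#' The population-excitability oscillation
#' `A * cos(2 * pi * f * t / 1000 + phi0)`, periodic with period
#' `1000 / osc_frequency` ms and range \[-A, A\].
#'
#' @param t time in ms (vectorized).
#' @param config a [model_config()].
#' @return Numeric vector of activation units.
#' @export
oscillation_value <- function(t, config) {
  config$osc_amplitude *
    cos(2 * pi * config$osc_frequency * t / 1000 + config$osc_phase_offset)
}

#' Post-threshold activation dynamics
#'
#' Piecewise contribution of a node's own activation history: an excitatory
#' burst `-3 * B` while `0 <= Ta < 20` ms since threshold crossing, a strong
#' self-inhibition `+3 * B` for `20 <= Ta <= 100` ms, and the rest
#' inhibition `B` beyond 100 ms and for nodes that never activated
#' (`Ta = Inf`). `B` (`base_inhibition`) is negative, so the burst is
#' positive. The window boundaries are configurable through
#' `excitation_window_ms` / `inhibition_window_ms`.
#'
#' @param ta time since last threshold crossing in ms; `Inf` for a node that
#'   never activated. Vectorized.
#' @param base_inhibition negative base inhibition constant.
#' @param excitation_window_ms,inhibition_window_ms window boundaries.
#' @return Numeric vector of activation units.
#' @export
post_threshold_activation <- function(ta, base_inhibition,
                                      excitation_window_ms = c(0, 20),
                                      inhibition_window_ms = c(20, 100)) {
  stopifnot(base_inhibition < 0)
  out <- rep(base_inhibition, length(ta))
  out[ta >= excitation_window_ms[1] & ta < excitation_window_ms[2]] <-
    -3 * base_inhibition
  out[ta >= inhibition_window_ms[1] & ta <= inhibition_window_ms[2]] <-
    3 * base_inhibition
  out
}

#' Per-node activation thresholds from trait frequency
#'
#' High-frequency units (consonant /d/, vowel /α/, words /dαt/ and /xat/)
#' get `base_threshold - threshold_reduction`; low-frequency units and the
#' empty nodes keep `base_threshold`. With `sensitivity_enabled = FALSE`
#' every threshold equals `base_threshold` (the no-sensitivity control).
#'
#' @param lexicon a `trait_lexicon`.
#' @param config a [model_config()].
#' @return List with named numeric vectors `phoneme` and `word`.
#' @export
apply_sensitivity <- function(lexicon, config) {
  stopifnot(inherits(lexicon, "trait_lexicon"))
  phon <- stats::setNames(rep(config$base_threshold, 5),
                          lexicon$phonemes$phoneme)
  word <- stats::setNames(rep(config$base_threshold, 5),
                          lexicon$words$word)
  if (isTRUE(config$sensitivity_enabled)) {
    high_p <- c(names(which(lexicon$trait_class$consonant == "high")),
                names(which(lexicon$trait_class$vowel == "high")))
    high_w <- names(which(lexicon$trait_class$word == "high"))
    phon[high_p] <- phon[high_p] - config$threshold_reduction
    word[high_w] <- word[high_w] - config$threshold_reduction
  }
  list(phoneme = phon, word = word)
}
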