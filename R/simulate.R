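#' Construct a stimulus event
#'
#' An event loads the input-word nodes with fixed amplitudes for a fixed
#' duration. A morph event has two nonzero amplitudes summing to one; an
#' entrainment event loads only the empty word node.
#'
#' @param onset_ms onset time in ms.
#' @param amplitudes named numeric vector over input-word node ids; missing
#'   nodes are 0.
#' @param duration_ms event duration in ms.
#' @return A list of class `stimulus_event`.
#' @export
stimulus_event <- function(onset_ms, amplitudes, duration_ms = 80) {
  if (any(amplitudes < 0)) stop("amplitudes must be nonnegative")
  structure(list(onset_ms = onset_ms, duration_ms = duration_ms,
                 amplitudes = amplitudes),
            class = "stimulus_event")
}

# Input-node activation matrix (n_input x n_steps) from an event sequence.
build_input_matrix <- function(sequence, input_ids, n_steps, config) {
  inp <- matrix(0, length(input_ids), n_steps,
                dimnames = list(input_ids, NULL))
  dt <- config$dt_ms
  for (ev in sequence) {
    i0 <- floor(ev$onset_ms / dt) + 1
    i1 <- min(floor((ev$onset_ms + ev$duration_ms) / dt), n_steps)
    if (i0 > n_steps) next
    idx <- i0:min(i1, n_steps)
    shape <- if (config$input_mode == "linear_ramp")
      seq_along(idx) / length(idx) else rep(1, length(idx))
    for (nm in names(ev$amplitudes))
      inp[nm, idx] <- inp[nm, idx] + ev$amplitudes[[nm]] * shape
  }
  inp
}

#' Run the two-level node model over a stimulus sequence
#'
#' Integrates the activation dynamics: at every step each node's activation
#' is the connectivity-weighted lower-level activation, plus its
#' post-threshold term (see [post_threshold_activation()]), plus the
#' oscillation. A node's activation clock resets whenever it is at or above
#' threshold. The run is fully deterministic.
#'
#' @param sequence list of [stimulus_event()]s, time-ordered.
#' @param config a [model_config()].
#' @param connectivity a [build_connectivity()] result; defaults to the
#'   topology named in `config` over the study lexicon.
#' @param thresholds per-node thresholds as from [apply_sensitivity()].
#' @param t_max_ms total simulated time; defaults to the last event offset
#'   plus the decision window.
#' @param keep_trace if `TRUE`, store full per-node activation time courses.
#' @return An object of class `simulation_trace`: list with `times` (ms),
#'   `crossings` (data.frame: level, node, time_ms, activation),
#'   optional `activation` matrices per level, and the inputs used.
#' @export
simulate_stimcon <- function(sequence, config,
                             connectivity = NULL, thresholds = NULL,
                             t_max_ms = NULL, keep_trace = FALSE) {
  if (length(sequence) == 0) stop("empty stimulus sequence")
  onsets <- vapply(sequence, function(e) e$onset_ms, 0)
  if (is.unsorted(onsets)) stop("events must be time-ordered")
  lex <- build_lexicon()
  if (is.null(connectivity))
    connectivity <- build_connectivity(lex, config$topology)
  if (is.null(thresholds)) thresholds <- apply_sensitivity(lex, config)

  period <- 1000 / config$osc_frequency
  if (is.null(t_max_ms)) {
    last <- sequence[[length(sequence)]]
    t_max_ms <- last$onset_ms + last$duration_ms +
      config$decision_window_cycles * period
  }
  n_steps <- floor(t_max_ms / config$dt_ms) + 1
  input_ids <- rownames(connectivity$input_to_phoneme)
  inp <- build_input_matrix(sequence, input_ids, n_steps, config)

  hier <- identical(connectivity$topology, "hierarchical")
  c_pw <- if (hier) connectivity$phoneme_to_word else
    matrix(0, length(thresholds$phoneme), length(thresholds$word))

  res <- cpp_simulate(inp, connectivity$input_to_phoneme,
                      connectivity$input_to_word, c_pw, hier,
                      unname(thresholds$phoneme), unname(thresholds$word),
                      config$osc_amplitude, config$osc_frequency,
                      config$osc_phase_offset, config$base_inhibition,
                      config$excitation_window_ms[2],
                      config$inhibition_window_ms[2],
                      config$dt_ms, keep_trace)

  phon_ids <- colnames(connectivity$input_to_phoneme)
  word_ids <- colnames(connectivity$input_to_word)
  node_id <- ifelse(res$level == 1, phon_ids[res$node], word_ids[res$node])
  crossings <- data.frame(
    level = c("phoneme", "word")[res$level],
    node = node_id, time_ms = res$time_ms, activation = res$activation,
    stringsAsFactors = FALSE
  )
  out <- list(times = seq(0, by = config$dt_ms, length.out = n_steps),
              crossings = crossings, config = config,
              thresholds = thresholds, sequence = sequence)
  if (keep_trace) {
    rownames(res$trace_phoneme) <- phon_ids
    rownames(res$trace_word) <- word_ids
    out$activation <- list(phoneme = res$trace_phoneme,
                           word = res$trace_word)
  }
  structure(out, class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("simulation_trace: %d ms, %d threshold crossings\n",
              max(x$times), nrow(x$crossings)))
  invisible(x)
}

#' Long-format activation table of a simulation trace
#'
#' Requires the trace to have been run with `keep_trace = TRUE`.
#'
#' @param x a `simulation_trace`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns time_ms, level, node, activation.
#' @export
as.data.frame.simulation_trace <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  if (is.null(x$activation))
    stop("trace was run with keep_trace = FALSE")
  blocks <- lapply(names(x$activation), function(lv) {
    m <- x$activation[[lv]]
    data.frame(time_ms = rep(x$times, each = nrow(m)),
               level = lv, node = rownames(m),
               activation = as.vector(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

#' Write a simulation trace to disk
#'
#' Writes the long activation table as tab-separated text and the
#' threshold-crossing events as JSON (with the configuration snapshot).
#'
#' @param trace a `simulation_trace` run with `keep_trace = TRUE`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(trace),
                     file.path(dir, "activation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(crossings = trace$crossings, config = unclass(trace$config)),
    file.path(dir, "crossings.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Categorization decision from a simulation trace
#'
#' The chosen node is the candidate that first crosses threshold at or
#' after the probe onset (and within the decision window). If the two
#' candidates cross on the same step, the one with the stronger activation
#' at the crossing wins. If no candidate crosses, or the simultaneous
#' activations are exactly equal, the model guesses: in deterministic mode
#' the choice value is 0.5; in stochastic mode a random candidate is drawn
#' (seed the session RNG for reproducibility).
#'
#' @param trace a `simulation_trace`.
#' @param level `"phoneme"` or `"word"`.
#' @param onset_ms probe onset time in ms.
#' @param candidates character vector of two node ids at that level; the
#'   *second* is coded as choice value 1.
#' @param mode `"deterministic"` or `"stochastic"` guess resolution.
#' @param window_ms decision window after onset; defaults to the config's
#'   `decision_window_cycles` oscillator cycles.
#' @param act_tol activations of simultaneous crossings closer than this
#'   are treated as exactly equal (a numerical tie); keeps knife-edge
#'   comparisons from being decided by floating-point residue.
#' @return A list of class `model_decision` with `level`, `choice` (node id
#'   or `"GUESS"` in deterministic mode), `choice_value` (0, 0.5 or 1) and
#'   `decision_time_ms` (NA for a guess).
#' @export
decide <- function(trace, level, onset_ms, candidates,
                   mode = c("deterministic", "stochastic"),
                   window_ms = NULL, act_tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(length(candidates) == 2)
  if (!level %in% c("phoneme", "word"))
    stop("level must be 'phoneme' or 'word'")
  if (is.null(window_ms))
    window_ms <- trace$config$decision_window_cycles *
      1000 / trace$config$osc_frequency
  cr <- trace$crossings
  cr <- cr[cr$level == level & cr$node %in% candidates &
             cr$time_ms >= onset_ms & cr$time_ms <= onset_ms + window_ms, ,
           drop = FALSE]
  first <- vapply(candidates, function(nd) {
    tt <- cr$time_ms[cr$node == nd]
    if (length(tt)) min(tt) else Inf
  }, 0)
  guess <- FALSE
  if (all(is.infinite(first))) {
    guess <- TRUE
  } else if (first[1] == first[2]) {
    act <- vapply(candidates, function(nd)
      cr$activation[cr$node == nd & cr$time_ms == first[[nd]]][1], 0)
    if (abs(act[1] - act[2]) <= act_tol) guess <- TRUE
    else choice <- candidates[which.max(act)]
  } else {
    choice <- candidates[which.min(first)]
  }
  if (guess) {
    if (mode == "deterministic") {
      choice <- "GUESS"; value <- 0.5
    } else {
      choice <- sample(candidates, 1)
      value <- as.numeric(choice == candidates[2])
    }
    dtime <- NA_real_
  } else {
    value <- as.numeric(choice == candidates[2])
    dtime <- unname(first[choice])
  }
  structure(list(level = level, choice = choice, choice_value = value,
                 decision_time_ms = dtime),
            class = "model_decision")
}
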