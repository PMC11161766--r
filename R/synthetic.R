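#' Specification of a synthetic behavioral experiment
#'
#' Describes the data-generating process the behavioral analyses assume:
#' each trial is a Bernoulli draw whose probability is sinusoidally
#' modulated across SOA,
#' `P(response = 1) = base_prob + amplitude * sin(2 pi f soa + phase)`.
#'
#' @param n_participants number of participants.
#' @param n_trials_per_soa trials per participant and SOA.
#' @param soas SOA grid in seconds; defaults to [default_soa_grid()].
#' @param base_prob baseline choice probability.
#' @param modulation_amplitude modulation amplitude (probability units);
#'   `base_prob ± amplitude` must stay in \[0, 1\].
#' @param modulation_frequency modulation frequency in Hz.
#' @param modulation_phase common phase (radians) of the modulation.
#' @param phase_jitter_sd SD of a per-participant Gaussian phase jitter
#'   around `modulation_phase` (0 = identical phase in all participants).
#' @return List of class `behavioral_sim_spec`.
#' @export
behavioral_sim_spec <- function(n_participants = 18, n_trials_per_soa = 40,
                                soas = default_soa_grid(), base_prob = 0.5,
                                modulation_amplitude = 0,
                                modulation_frequency = 6.25,
                                modulation_phase = 0,
                                phase_jitter_sd = 0) {
  if (base_prob + modulation_amplitude > 1 ||
      base_prob - modulation_amplitude < 0)
    stop("base_prob +/- modulation_amplitude must stay within [0, 1]")
  structure(list(n_participants = n_participants,
                 n_trials_per_soa = n_trials_per_soa, soas = soas,
                 base_prob = base_prob,
                 modulation_amplitude = modulation_amplitude,
                 modulation_frequency = modulation_frequency,
                 modulation_phase = modulation_phase,
                 phase_jitter_sd = phase_jitter_sd),
            class = "behavioral_sim_spec")
}

#' Generate a synthetic behavioral response table
#'
#' Draws trial-level binary responses under a [behavioral_sim_spec()].
#' Trials within each participant x SOA cell are split into experiment
#' halves (column `half`) in presentation order.
#'
#' @param spec a `behavioral_sim_spec`.
#' @param seed RNG seed.
#' @return data.frame with columns `participant`, `soa_s`, `morph`,
#'   `response`, `half` (a valid response table, see
#'   [read_response_table()]).
#' @export
generate_behavioral_dataset <- function(spec, seed = 1) {
  set.seed(seed)
  ph <- spec$modulation_phase +
    stats::rnorm(spec$n_participants, 0, spec$phase_jitter_sd)
  n_cell <- spec$n_trials_per_soa
  rows <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    pr <- spec$base_prob + spec$modulation_amplitude *
      sin(2 * pi * spec$modulation_frequency * spec$soas + ph[i])
    resp <- stats::rbinom(n_cell * length(spec$soas), 1, rep(pr, each = n_cell))
    rows[[i]] <- data.frame(
      participant = sprintf("P%02d", i),
      soa_s = rep(spec$soas, each = n_cell),
      morph = "ambiguous",
      response = resp,
      half = rep(rep(1:2, each = ceiling(n_cell / 2), length.out = n_cell),
                 length(spec$soas)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Specification of a synthetic neural (ROI time-series) experiment
#'
#' Multi-participant trial sets of oscillatory time series for labeled
#' streams (e.g. `"STG"` and `"MTG"`), in which the binary response for a
#' given labeling depends on the true oscillatory phase at one
#' time-frequency point of one stream:
#' `P(response = 1) = plogis(beta * cos(phase_at_effect - phi0))` with a
#' participant-specific preferred phase `phi0` (uniform across
#' participants). Labelings without an effect draw responses at 0.5.
#'
#' Each trial of a stream is a sum of stationary background oscillations
#' (random phase per trial), 1/f noise, and — for streams carrying an
#' effect — a band-limited oscillatory burst at the effect frequency,
#' Gaussian-windowed around the effect latency (SD `burst_sd_s`). The
#' burst makes the phase information local in time as well as frequency:
#' a stationary component would let prestimulus phase at any latency
#' predict the response.
#'
#' @param n_participants,n_trials design size.
#' @param sfreq sampling rate in Hz.
#' @param epoch epoch window in seconds, `c(start, end)`; must leave room
#'   for the analysis wavelets on both sides of the prestimulus window
#'   (a 5-cycle wavelet at 1 Hz spans about ±2 s).
#' @param streams stream (ROI) names.
#' @param oscillations data.frame with columns `freq` (Hz) and `amp`
#'   giving the background oscillations present in every stream.
#' @param noise_sd SD of the 1/f (exponent 1) noise.
#' @param effects named list (by labeling, e.g. `consonant`, `word`) of
#'   lists with `stream`, `freq` (Hz), `time` (s), `beta`; use `NULL`
#'   entries for null labelings.
#' @param burst_sd_s temporal SD (s) of the Gaussian window of effect
#'   bursts.
#' @param burst_amp amplitude of effect bursts at their center.
#' @return List of class `neural_sim_spec`.
#' @export
neural_sim_spec <- function(n_participants = 20, n_trials = 200,
                            sfreq = 100, epoch = c(-3.2, 2.0),
                            streams = c("STG", "MTG"),
                            oscillations = data.frame(freq = 10, amp = 0.5),
                            noise_sd = 1,
                            effects = list(
                              consonant = list(stream = "STG", freq = 7.6,
                                               time = -0.2, beta = 1),
                              word = list(stream = "MTG", freq = 6.4,
                                          time = -0.1, beta = 1)),
                            burst_sd_s = 0.15, burst_amp = 1) {
  for (ef in effects) {
    if (is.null(ef)) next
    if (ef$time < epoch[1] || ef$time > epoch[2])
      stop("effect time outside the epoch")
    if (ef$freq <= 0 || ef$freq > sfreq / 2)
      stop("effect frequency outside the analyzable band")
  }
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 sfreq = sfreq, epoch = epoch, streams = streams,
                 oscillations = oscillations, noise_sd = noise_sd,
                 effects = effects, burst_sd_s = burst_sd_s,
                 burst_amp = burst_amp),
            class = "neural_sim_spec")
}

# 1/f-shaped Gaussian noise (exponent 1), one trial per row: white noise
# filtered with amplitude 1/sqrt(f) in the frequency domain (DC removed).
pink_noise <- function(n_trials, n_samples, sd = 1) {
  bin <- pmin(0:(n_samples - 1), n_samples - 0:(n_samples - 1))
  filt <- ifelse(bin == 0, 0, 1 / sqrt(bin))
  white <- matrix(stats::rnorm(n_trials * n_samples), n_samples, n_trials)
  shaped <- Re(stats::mvfft(stats::mvfft(white) * filt, inverse = TRUE)) /
    n_samples
  shaped <- t(shaped)
  shaped * sd / mean(apply(shaped, 1, stats::sd))
}

#' Generate a synthetic neural dataset
#'
#' Draws per-participant, per-stream trial time series and the binary
#' responses per labeling, following a [neural_sim_spec()]. The true
#' per-trial phase of the effect oscillation at the effect latency (known
#' exactly from the generated component) drives the response; the
#' time-series analysis chain then has to recover it through the Morlet
#' decomposition.
#'
#' @param spec a `neural_sim_spec`.
#' @param seed RNG seed.
#' @return Object of class `neural_dataset`: list with `times` (s),
#'   `sfreq`, `spec`, and `participants`, a list of
#'   `list(streams = <named list of trials x samples matrices>,
#'   responses = <named list of 0/1 vectors per labeling>,
#'   preferred_phase = <named numeric>,
#'   burst_phase = <named list of true per-trial effect phases>)`. The
#'   last two are generation ground truth, kept for validation.
#' @export
generate_neural_dataset <- function(spec, seed = 1) {
  set.seed(seed)
  times <- seq(spec$epoch[1], spec$epoch[2], by = 1 / spec$sfreq)
  ns <- length(times)
  labelings <- names(spec$effects)

  participants <- vector("list", spec$n_participants)
  for (pp in seq_len(spec$n_participants)) {
    phi0 <- stats::setNames(stats::runif(length(labelings), -pi, pi),
                            labelings)
    streams <- list()
    burst_phase <- list()  # per labeling: per-trial burst phase theta
    for (st in spec$streams) {
      sig <- pink_noise(spec$n_trials, ns, spec$noise_sd)
      comps <- spec$oscillations
      for (k in seq_len(nrow(comps))) {
        theta <- stats::runif(spec$n_trials, -pi, pi)
        sig <- sig + comps$amp[k] *
          cos(outer(theta, 2 * pi * comps$freq[k] * times, "+"))
      }
      # band-limited effect bursts carried by this stream
      for (lb in labelings) {
        ef <- spec$effects[[lb]]
        if (is.null(ef) || ef$stream != st) next
        theta <- stats::runif(spec$n_trials, -pi, pi)
        win <- exp(-(times - ef$time)^2 / (2 * spec$burst_sd_s^2))
        carrier <- outer(theta, 2 * pi * ef$freq * (times - ef$time), "+")
        sig <- sig + spec$burst_amp *
          cos(carrier) * rep(win, each = spec$n_trials)
        burst_phase[[lb]] <- theta
      }
      streams[[st]] <- sig
    }
    responses <- list()
    for (lb in labelings) {
      ef <- spec$effects[[lb]]
      if (is.null(ef)) {
        responses[[lb]] <- stats::rbinom(spec$n_trials, 1, 0.5)
      } else {
        # the burst phase at the effect point is theta itself
        pr <- stats::plogis(ef$beta * cos(burst_phase[[lb]] - phi0[lb]))
        responses[[lb]] <- stats::rbinom(spec$n_trials, 1, pr)
      }
    }
    participants[[pp]] <- list(streams = streams, responses = responses,
                               preferred_phase = phi0,
                               burst_phase = burst_phase)
  }
  structure(list(times = times, sfreq = spec$sfreq, spec = spec,
                 participants = participants),
            class = "neural_dataset")
}

#' Cluster analysis of one labeling x stream combination
#'
#' The full recovery chain for a synthetic neural dataset: per participant,
#' Morlet phase extraction of the stream's trials on the analysis grid,
#' null-centered logistic phase-effect magnitude map
#' ([participant_effect_map()]), then the group-level
#' [group_cluster_test()].
#'
#' @param data a `neural_dataset`.
#' @param labeling which response labeling to analyze.
#' @param stream which stream's phases to use.
#' @param grid analysis grid, `list(freqs, times)`; default
#'   [default_tf_grid()].
#' @param n_cycles Morlet width in cycles.
#' @param n_perm_center within-participant centering permutations.
#' @param n_perm group-level sign-flip permutations.
#' @param seed RNG seed.
#' @return A `cluster_test`, with the analysis `grid` attached as
#'   attribute.
#' @export
analyze_neural_dataset <- function(data, labeling, stream,
                                   grid = default_tf_grid(), n_cycles = 5,
                                   n_perm_center = 20, n_perm = 500,
                                   seed = 1) {
  stopifnot(inherits(data, "neural_dataset"))
  set.seed(seed)
  np <- length(data$participants)
  maps <- array(NA_real_, c(np, length(grid$freqs), length(grid$times)))
  for (pp in seq_len(np)) {
    part <- data$participants[[pp]]
    tf <- extract_tf_phase(part$streams[[stream]], data$times, grid$freqs,
                           grid$times, n_cycles = n_cycles,
                           responses = part$responses[[labeling]],
                           participant = pp)
    maps[pp, , ] <- participant_effect_map(tf, n_perm_center)
  }
  out <- group_cluster_test(maps, n_perm = n_perm,
                            seed = sample.int(2^31 - 1, 1))
  attr(out, "grid") <- grid
  out
}
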