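#' Morph spectrum between two endpoint words
#'
#' The two endpoints must differ in exactly one trait (consonant or vowel).
#' Morph level `p` presents endpoint B with amplitude `p` and endpoint A
#' with amplitude `1 - p` on the input-word nodes.
#'
#' @param endpoint_a,endpoint_b word ids (see [build_lexicon()]).
#' @param proportions strictly increasing morph proportions in \[0, 1\];
#'   default 10 equally spaced levels.
#' @return Object of class `morph_spectrum` with endpoints, proportions,
#'   the morphed `trait`, and decision candidates per level (ordered so the
#'   second candidate corresponds to endpoint B, i.e. choice value 1).
#' @export
morph_spectrum <- function(endpoint_a, endpoint_b,
                           proportions = seq(0, 1, length.out = 10)) {
  lex <- build_lexicon()
  stopifnot(endpoint_a %in% lex$words$word, endpoint_b %in% lex$words$word,
            endpoint_a != "none", endpoint_b != "none")
  if (any(diff(proportions) <= 0) || any(proportions < 0 | proportions > 1))
    stop("proportions must be strictly increasing within [0, 1]")
  ph_a <- lex$word_to_phonemes[[endpoint_a]]
  ph_b <- lex$word_to_phonemes[[endpoint_b]]
  diff_a <- setdiff(ph_a, ph_b)
  if (length(diff_a) != 1)
    stop("endpoints must differ in exactly one trait")
  diff_b <- setdiff(ph_b, ph_a)
  trait <- lex$phonemes$trait[lex$phonemes$phoneme == diff_a]
  structure(
    list(endpoint_a = endpoint_a, endpoint_b = endpoint_b,
         proportions = proportions, trait = trait,
         candidates = list(phoneme = c(diff_a, diff_b),
                           word = c(endpoint_a, endpoint_b))),
    class = "morph_spectrum"
  )
}

#' The four morph spectra of the study design
#'
#' Two consonant spectra (/xαt/-/dαt/ and /xat/-/dat/) and two vowel
#' spectra (/dat/-/dαt/ and /xat/-/xαt/). Endpoint B is always the word
#' with the high-frequency value of the morphed trait, so choice value 1
#' means "heard the frequent variant of the morphed trait".
#'
#' @param proportions passed to [morph_spectrum()].
#' @return Named list of four `morph_spectrum` objects.
#' @export
study_spectra <- function(proportions = seq(0, 1, length.out = 10)) {
  list(
    xAt_dAt = morph_spectrum("xAt", "dAt", proportions),
    xat_dat = morph_spectrum("xat", "dat", proportions),
    dat_dAt = morph_spectrum("dat", "dAt", proportions),
    xat_xAt = morph_spectrum("xat", "xAt", proportions)
  )
}

#' Input amplitudes for one morph level
#'
#' @param spectrum a [morph_spectrum()].
#' @param p morph proportion in \[0, 1\] (amplitude of endpoint B).
#' @return Named amplitude vector over the two endpoint input nodes.
#' @export
make_morph_input <- function(spectrum, p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  stats::setNames(c(1 - p, p),
                  c(spectrum$endpoint_a, spectrum$endpoint_b))
}

#' Default SOA grid of the entrainment experiment
#'
#' Twelve equidistant stimulus onset asynchronies between 0.1 and 0.42 s,
#' spanning exactly two cycles of 6.25 Hz.
#'
#' @return Numeric vector of SOAs in seconds.
#' @export
default_soa_grid <- function() seq(0.1, 0.42, length.out = 12)

# One probe presentation at a given oscillator phase (radians relative to
# the cosine peak); returns deterministic choice values per level.
present_probe_at_phase <- function(config, connectivity, thresholds,
                                   spectrum, p, phase,
                                   mode = "deterministic") {
  period <- 1000 / config$osc_frequency
  onset <- config$warmup_cycles * period + (phase %% (2 * pi)) / (2 * pi) * period
  onset <- round(onset / config$dt_ms) * config$dt_ms
  ev <- stimulus_event(onset, make_morph_input(spectrum, p),
                       config$stimulus_duration_ms)
  tr <- simulate_stimcon(list(ev), config, connectivity, thresholds)
  list(
    phoneme = decide(tr, "phoneme", onset, spectrum$candidates$phoneme, mode),
    word = decide(tr, "word", onset, spectrum$candidates$word, mode),
    onset_ms = onset
  )
}

#' Psychometric sweep across morph levels and presentation phases
#'
#' Presents every morph level of the spectrum at `phase_grid_size` phases
#' evenly spanning one oscillator cycle and averages the deterministic
#' choice values across phases, per analysis level and combined (the
#' per-presentation mean of the phoneme- and word-level values).
#'
#' @param config a [model_config()].
#' @param spectrum a [morph_spectrum()].
#' @param phase_grid_size number of evenly spaced phases (>= 8).
#' @return Object of class `psychometric_curve`: data.frame with
#'   `proportion`, `value_phoneme`, `value_word`, `value_combined`, plus
#'   the spectrum as an attribute.
#' @export
run_psychometric_sweep <- function(config, spectrum, phase_grid_size = 16) {
  if (phase_grid_size < 8) stop("phase_grid_size must be >= 8")
  lex <- build_lexicon()
  conn <- build_connectivity(lex, config$topology)
  thr <- apply_sensitivity(lex, config)
  phases <- 2 * pi * (seq_len(phase_grid_size) - 1) / phase_grid_size
  rows <- lapply(spectrum$proportions, function(p) {
    vals <- vapply(phases, function(ph) {
      d <- present_probe_at_phase(config, conn, thr, spectrum, p, ph)
      c(d$phoneme$choice_value, d$word$choice_value)
    }, c(0, 0))
    data.frame(proportion = p,
               value_phoneme = mean(vals[1, ]),
               value_word = mean(vals[2, ]),
               value_combined = mean(colMeans(vals)))
  })
  out <- do.call(rbind, rows)
  attr(out, "spectrum") <- spectrum
  class(out) <- c("psychometric_curve", "data.frame")
  out
}

#' Logistic psychometric fit
#'
#' Least-squares fit of `y = 1 / (1 + exp(-slope * (p - midpoint)))` to the
#' combined psychometric curve. The midpoint (proportion at 50% choice) is
#' the "most ambiguous morph" used by the entrainment and random-phase
#' protocols. A fit-quality flag is raised for flat or strongly
#' non-monotone data and when the optimizer fails.
#'
#' @param curve a `psychometric_curve` (or data.frame with `proportion` and
#'   `value_combined`), needing at least 5 points.
#' @param value column to fit, default `"value_combined"`.
#' @return Object of class `psychometric_fit`: list with `slope`,
#'   `midpoint`, `residual` (RMS), `flag` (logical) and the fitted values.
#' @export
fit_psychometric <- function(curve, value = "value_combined") {
  p <- curve$proportion
  y <- curve[[value]]
  if (length(p) < 5) stop("need at least 5 points")
  flag <- FALSE
  if (stats::var(y) < 1e-8) {
    # flat curve: slope unidentifiable
    return(structure(list(slope = 0, midpoint = 0.5, residual = 0,
                          flag = TRUE, fitted = rep(mean(y), length(y))),
                     class = "psychometric_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-k * (p - m))),
                      start = list(k = 10, m = 0.5),
                      lower = c(k = 1e-3, m = 0), upper = c(k = 1e4, m = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the grid point closest to 0.5
    mid <- p[which.min(abs(y - 0.5))]
    return(structure(list(slope = NA_real_, midpoint = mid,
                          residual = NA_real_, flag = TRUE, fitted = y),
                     class = "psychometric_fit"))
  }
  cf <- stats::coef(fit)
  fitted <- 1 / (1 + exp(-cf[["k"]] * (p - cf[["m"]])))
  resid <- sqrt(mean((y - fitted)^2))
  if (resid > 0.15 || cf[["k"]] < 0.5) flag <- TRUE
  structure(list(slope = cf[["k"]], midpoint = cf[["m"]],
                 residual = resid, flag = flag, fitted = fitted),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric_fit: midpoint %.3f, slope %.2f, RMS %.3f%s\n",
              x$midpoint, x$slope, x$residual,
              if (x$flag) " [fit-quality flag]" else ""))
  invisible(x)
}

#' Entrainment experiment: probe at varying SOA after a rhythmic train
#'
#' Presents `n_entrain` empty-word events at `train_rate_hz`, then the
#' probe morph at each SOA (seconds, onset-to-onset from the last train
#' event). Decisions are deterministic (guess = 0.5) and reported per
#' level plus combined.
#'
#' @param config a [model_config()].
#' @param spectrum a [morph_spectrum()].
#' @param ambiguous_p probe morph proportion, normally the fitted
#'   psychometric midpoint.
#' @param soas SOA grid in seconds; defaults to [default_soa_grid()].
#' @return data.frame of class `entrainment_result` with `soa_s`,
#'   `value_phoneme`, `value_word`, `value_combined`.
#' @export
run_entrainment_experiment <- function(config, spectrum, ambiguous_p,
                                       soas = default_soa_grid()) {
  if (!length(soas)) stop("soas must be nonempty")
  if (any(soas * 1000 < config$dt_ms))
    stop("SOA shorter than one integration step")
  lex <- build_lexicon()
  conn <- build_connectivity(lex, config$topology)
  thr <- apply_sensitivity(lex, config)
  period <- 1000 / config$osc_frequency
  t0 <- config$warmup_cycles * period     # first train event on a peak
  train_onsets <- t0 + (seq_len(config$n_entrain) - 1) * 1000 / config$train_rate_hz
  train <- lapply(train_onsets, function(on)
    stimulus_event(on, c(none = 1), config$stimulus_duration_ms))
  last <- train_onsets[length(train_onsets)]
  amps <- make_morph_input(spectrum, ambiguous_p)
  rows <- lapply(soas, function(soa) {
    onset <- round((last + soa * 1000) / config$dt_ms) * config$dt_ms
    ev <- stimulus_event(onset, amps, config$stimulus_duration_ms)
    tr <- simulate_stimcon(c(train, list(ev)), config, conn, thr)
    dp <- decide(tr, "phoneme", onset, spectrum$candidates$phoneme)
    dw <- decide(tr, "word", onset, spectrum$candidates$word)
    data.frame(soa_s = soa,
               value_phoneme = dp$choice_value,
               value_word = dw$choice_value,
               value_combined = (dp$choice_value + dw$choice_value) / 2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("entrainment_result", "data.frame")
  out
}

#' Random-phase trial simulation
#'
#' Presents the ambiguous morph at a uniformly random oscillator phase on
#' every trial (no entrainment train) and records the presentation phase
#' together with the per-level categorization choice. Guesses are resolved
#' stochastically (random endpoint). Phoneme-level choices are reported as
#' the endpoint word containing the chosen phoneme.
#'
#' @param config a [model_config()].
#' @param spectrum a [morph_spectrum()].
#' @param ambiguous_p probe morph proportion.
#' @param n_trials number of trials.
#' @param seed RNG seed for the phase draws and guess resolution.
#' @return data.frame of class `phase_trial_records` with `trial`,
#'   `phase` (radians in \[-pi, pi)), `phoneme_choice`, `word_choice`
#'   (word ids).
#' @export
run_random_phase_experiment <- function(config, spectrum, ambiguous_p,
                                        n_trials = 1000, seed = 1) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  lex <- build_lexicon()
  conn <- build_connectivity(lex, config$topology)
  thr <- apply_sensitivity(lex, config)
  word_of_phoneme <- stats::setNames(spectrum$candidates$word,
                                     spectrum$candidates$phoneme)
  u <- stats::runif(n_trials)
  rows <- lapply(seq_len(n_trials), function(i) {
    phase <- 2 * pi * u[i]
    d <- present_probe_at_phase(config, conn, thr, spectrum, ambiguous_p,
                                phase, mode = "stochastic")
    rec_phase <- wrap_pi(2 * pi * config$osc_frequency * d$onset_ms / 1000 +
                           config$osc_phase_offset)
    data.frame(trial = i, phase = rec_phase,
               phoneme_choice = unname(word_of_phoneme[d$phoneme$choice]),
               word_choice = d$word$choice,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_trial_records", "data.frame")
  out
}

#' Circular mean phase differences against a reference word
#'
#' For each categorization choice the circular mean presentation phase is
#' computed and subtracted (wrapped to \[-pi, pi)) from the circular mean
#' phase of the reference-word choices. Pooling records from both
#' consonant spectra gives the three non-reference words.
#'
#' @param records `phase_trial_records` (possibly `rbind`-ed across
#'   spectra).
#' @param reference_word reference word id, /dαt/ (`"dAt"`) by default.
#' @param level `"phoneme"` or `"word"` choices.
#' @return Named numeric vector of wrapped phase differences (radians) per
#'   choice word, with attribute `n` (trial counts). Words with no trials
#'   are `NA`.
#' @export
compute_model_phase_differences <- function(records, reference_word = "dAt",
                                            level = c("phoneme", "word")) {
  level <- match.arg(level)
  col <- paste0(level, "_choice")
  choices <- records[[col]]
  ref_ph <- records$phase[choices == reference_word]
  if (!length(ref_ph)) stop("no trials with the reference choice")
  ref_mean <- circular_mean(ref_ph)
  words <- setdiff(unique(choices), reference_word)
  out <- vapply(words, function(wd) {
    ph <- records$phase[choices == wd]
    if (!length(ph)) return(NA_real_)
    wrap_pi(circular_mean(ph) - ref_mean)
  }, 0)
  attr(out, "n") <- table(choices)
  out
}
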