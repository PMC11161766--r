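# Shared fixtures for the test suite. Everything is generated in code.

# Lexicon/connectivity are deterministic; build once.
lex <- build_lexicon()
conn_par <- build_connectivity(lex, "parallel")

# A fake simulation trace with hand-written crossings, for decision-rule
# tests that should not depend on the integrator.
fake_trace <- function(crossings, osc_frequency = 6.25) {
  structure(list(
    times = 0:1000,
    crossings = crossings,
    config = model_config(osc_frequency = osc_frequency)),
    class = "simulation_trace")
}

# Approximate von Mises sample via wrapped normal (good for kappa >~ 5).
rvm_approx <- function(n, mu, kappa) {
  wrap_pi(stats::rnorm(n, mu, 1 / sqrt(kappa)))
}

# Run one probe at a given oscillator phase and return both level decisions.
probe_at <- function(config, spectrum, p, phase, mode = "deterministic") {
  thr <- apply_sensitivity(lex, config)
  period <- 1000 / config$osc_frequency
  onset <- round(config$warmup_cycles * period +
                   (phase %% (2 * pi)) / (2 * pi) * period)
  ev <- stimulus_event(onset, make_morph_input(spectrum, p),
                       config$stimulus_duration_ms)
  tr <- simulate_stimcon(list(ev), config, conn_par, thr)
  list(trace = tr, onset = onset,
       phoneme = decide(tr, "phoneme", onset, spectrum$candidates$phoneme, mode),
       word = decide(tr, "word", onset, spectrum$candidates$word, mode))
}
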