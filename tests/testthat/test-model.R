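test_that("oscillation follows the cosine convention and is periodic", {
  cfg <- model_config()
  expect_equal(oscillation_value(0, cfg), 1)
  expect_equal(oscillation_value(80, cfg), -1)   # half of the 160 ms period
  t <- seq(0, 500, by = 7)
  expect_equal(oscillation_value(t, cfg), oscillation_value(t + 160, cfg))
  cfg2 <- model_config(osc_amplitude = 0.4, osc_phase_offset = 1.1)
  expect_true(all(abs(oscillation_value(0:2000, cfg2)) <= 0.4 + 1e-12))
})

test_that("post-threshold dynamics: burst, inhibition, rest", {
  expect_equal(post_threshold_activation(10, -0.2), 0.6)
  expect_equal(post_threshold_activation(50, -0.2), -0.6)
  expect_equal(post_threshold_activation(150, -0.2), -0.2)
  # boundaries: burst is [0, 20), inhibition [20, 100]
  expect_equal(post_threshold_activation(c(0, 19.9, 20, 100, 100.1), -0.2),
               c(0.6, 0.6, -0.6, -0.6, -0.2))
  expect_equal(post_threshold_activation(Inf, -0.2), -0.2)  # never active
  expect_error(post_threshold_activation(10, 0.2))
})

test_that("sensitivity lowers thresholds of frequent units only", {
  thr <- apply_sensitivity(lex, model_config(threshold_reduction = 0.3))
  expect_equal(unname(thr$phoneme[c("d", "x", "A", "a", "none")]),
               c(0.7, 1, 0.7, 1, 1))
  expect_equal(unname(thr$word[c("dAt", "xAt", "xat", "dat", "none")]),
               c(0.7, 1, 0.7, 1, 1))
  thr0 <- apply_sensitivity(lex, model_config(threshold_reduction = 0))
  expect_true(all(unlist(thr0) == 1))
  off <- apply_sensitivity(lex, model_config(threshold_reduction = 0.3,
                                             sensitivity_enabled = FALSE))
  expect_true(all(unlist(off) == 1))
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(threshold_reduction = 0.6), "0.5")
  expect_error(model_config(base_inhibition = 0.1), "negative")
  expect_error(model_config(dt_ms = 0.5), "integer")
  expect_error(model_config(osc_frequency = -1))
  expect_error(model_config(n_entrain = 2), "periodic")
})

test_that("config round-trips through YAML and JSON files with overrides", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(osc_frequency = 5, threshold_reduction = 0.25), f)
  cfg <- load_model_config(f)
  expect_equal(cfg$osc_frequency, 5)
  expect_equal(cfg$threshold_reduction, 0.25)
  cfg2 <- load_model_config(f, overrides = list(threshold_reduction = 0.4))
  expect_equal(cfg2$threshold_reduction, 0.4)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(osc_frequency = 5), fj, auto_unbox = TRUE)
  expect_equal(load_model_config(fj)$osc_frequency, 5)
  yaml::write_yaml(list(not_a_field = 1), f)
  expect_error(load_model_config(f), "unknown")
})

test_that("without stimulation no node reaches threshold under the default config", {
  cfg <- model_config()  # reduction 0: osc peak + rest inhibition = 0.8 < 1
  ev <- stimulus_event(0, c(none = 0), 1)
  tr <- simulate_stimcon(list(ev), cfg, t_max_ms = 2000)
  expect_equal(nrow(tr$crossings), 0)
})

test_that("the simulation is deterministic and records consistent crossings", {
  cfg <- model_config(threshold_reduction = 0.3)
  ev <- stimulus_event(500, c(dAt = 0.6, xAt = 0.4), 80)
  t1 <- simulate_stimcon(list(ev), cfg, keep_trace = TRUE)
  t2 <- simulate_stimcon(list(ev), cfg, keep_trace = TRUE)
  expect_identical(t1$activation, t2$activation)
  expect_identical(t1$crossings, t2$crossings)
  thr <- apply_sensitivity(lex, cfg)
  for (i in seq_len(nrow(t1$crossings))) {
    cr <- t1$crossings[i, ]
    expect_gte(cr$activation, thr[[cr$level]][[cr$node]])
    idx <- which(t1$times == cr$time_ms)
    expect_equal(unname(t1$activation[[cr$level]][cr$node, idx]),
                 cr$activation)
  }
  expect_error(simulate_stimcon(list(), cfg), "empty")
  expect_error(simulate_stimcon(list(stimulus_event(100, c(dAt = 1)),
                                     stimulus_event(50, c(xAt = 1))), cfg),
               "time-ordered")
})

test_that("starting from rest, lowering a threshold never delays the node's first crossing", {
  # before any crossing the two trajectories coincide, so the reduced
  # threshold must be reached no later; measured from simulation start
  for (r in c(0.1, 0.25, 0.4)) {
    for (phase in c(0, pi / 3, pi, 5 * pi / 3)) {
      onset <- round(480 + phase / (2 * pi) * 160)
      ev <- stimulus_event(onset, c(dAt = 0.6), 80)
      first_cross <- function(red) {
        thr <- apply_sensitivity(lex, model_config(threshold_reduction = red))
        tr <- simulate_stimcon(list(ev), model_config(), conn_par, thr,
                               t_max_ms = 1400)
        tt <- tr$crossings$time_ms[tr$crossings$level == "word" &
                                     tr$crossings$node == "dAt"]
        if (length(tt)) min(tt) else Inf
      }
      expect_lte(first_cross(r), first_cross(0))
    }
  }
})

test_that("with both candidates at rest the frequent node crosses at an earlier-or-equal phase", {
  # oscillation amplitude below the spontaneous-firing point isolates the
  # pure threshold race (no refractory dynamics); brute force over phases
  for (r in c(0.15, 0.3, 0.5)) {
    cfg <- model_config(threshold_reduction = r, osc_amplitude = 0.65)
    thr <- apply_sensitivity(lex, cfg)
    for (phase in seq(0, 2 * pi, length.out = 9)[-9]) {
      onset <- round(480 + phase / (2 * pi) * 160)
      ev <- stimulus_event(onset, c(dAt = 0.5, xAt = 0.5), 80)
      tr <- simulate_stimcon(list(ev), cfg, conn_par, thr)
      first <- vapply(c("dAt", "xAt"), function(nd) {
        tt <- tr$crossings$time_ms[tr$crossings$level == "word" &
                                     tr$crossings$node == nd &
                                     tr$crossings$time_ms >= onset]
        if (length(tt)) min(tt) else Inf
      }, 0)
      expect_lte(first["dAt"], first["xAt"])  # Inf <= Inf when neither fires
    }
  }
})

test_that("self-inhibition prevents re-crossing of unstimulated nodes within the inhibition window", {
  for (r in c(0.25, 0.45)) {
    cfg <- model_config(threshold_reduction = r)
    ev <- stimulus_event(0, c(none = 0), 1)   # oscillation-only dynamics
    tr <- simulate_stimcon(list(ev), cfg, t_max_ms = 2000)
    cr <- tr$crossings
    for (lv in unique(cr$level)) for (nd in unique(cr$node[cr$level == lv])) {
      gaps <- diff(sort(cr$time_ms[cr$level == lv & cr$node == nd]))
      expect_true(all(gaps > cfg$inhibition_window_ms[2]))
    }
  }
})

test_that("under the default calibration the winner depends on the probe phase", {
  # refractoriness after spontaneous firing lets the rare word win on some
  # phases: the core phase-coding mechanism
  cfg <- model_config(threshold_reduction = 0.3)
  sp <- study_spectra()$xAt_dAt
  winners <- vapply(seq(0, 2 * pi, length.out = 17)[-17], function(ph)
    probe_at(cfg, sp, 0.5, ph)$word$choice, "")
  expect_true("dAt" %in% winners)
  expect_true("xAt" %in% winners)
})

test_that("the hierarchical topology still activates word nodes through phonemes", {
  cfg <- model_config(threshold_reduction = 0.3, topology = "hierarchical")
  ch <- build_connectivity(lex, "hierarchical")
  thr <- apply_sensitivity(lex, cfg)
  ev <- stimulus_event(480, c(dAt = 1), 80)
  tr <- simulate_stimcon(list(ev), cfg, ch, thr)
  cr <- tr$crossings
  expect_true(any(cr$level == "word" & cr$node == "dAt" & cr$time_ms >= 480))
})

test_that("decisions follow first-crossing, strongest-at-tie and guess rules", {
  cand <- c("x", "d")
  tr <- fake_trace(data.frame(level = "phoneme", node = c("d", "x"),
                              time_ms = c(50, 70), activation = c(1.1, 1.2)))
  d <- decide(tr, "phoneme", 0, cand)
  expect_equal(d$choice, "d")
  expect_equal(d$choice_value, 1)      # d is the second candidate
  expect_equal(d$decision_time_ms, 50)

  tr2 <- fake_trace(data.frame(level = "phoneme", node = c("d", "x"),
                               time_ms = c(50, 50), activation = c(1.1, 1.2)))
  expect_equal(decide(tr2, "phoneme", 0, cand)$choice, "x")

  tr3 <- fake_trace(data.frame(level = character(), node = character(),
                               time_ms = numeric(), activation = numeric()))
  d3 <- decide(tr3, "phoneme", 0, cand)
  expect_equal(d3$choice, "GUESS")
  expect_equal(d3$choice_value, 0.5)
  set.seed(99)
  vals <- replicate(40, decide(tr3, "phoneme", 0, cand, "stochastic")$choice_value)
  expect_true(all(vals %in% c(0, 1)))
  expect_true(length(unique(vals)) == 2)
  set.seed(7); a <- decide(tr3, "phoneme", 0, cand, "stochastic")$choice
  set.seed(7); b <- decide(tr3, "phoneme", 0, cand, "stochastic")$choice
  expect_identical(a, b)

  # exact activation tie resolves as a guess
  tr4 <- fake_trace(data.frame(level = "phoneme", node = c("d", "x"),
                               time_ms = c(50, 50), activation = c(1.2, 1.2)))
  expect_equal(decide(tr4, "phoneme", 0, cand)$choice_value, 0.5)
  # crossings before onset are ignored
  expect_equal(decide(tr, "phoneme", 60, cand)$choice, "x")
  expect_error(decide(tr, "syllable", 0, cand), "level")
})

test_that("trace export produces a long table consistent with the run", {
  cfg <- model_config(threshold_reduction = 0.3)
  ev <- stimulus_event(480, c(dAt = 0.7, xAt = 0.3), 80)
  tr <- simulate_stimcon(list(ev), cfg, keep_trace = TRUE)
  df <- as.data.frame(tr)
  expect_named(df, c("time_ms", "level", "node", "activation"))
  expect_equal(nrow(df), length(tr$times) * 10)
  sub <- df[df$level == "word" & df$node == "dAt", ]
  expect_equal(sub$activation, unname(tr$activation$word["dAt", ]))
  expect_error(as.data.frame(simulate_stimcon(list(ev), cfg)), "keep_trace")
})
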