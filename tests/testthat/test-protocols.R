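test_that("morph inputs weight the endpoints complementarily", {
  sp <- morph_spectrum("xat", "dat")
  expect_equal(make_morph_input(sp, 0.9), c(xat = 0.1, dat = 0.9))
  expect_equal(unname(make_morph_input(sp, 0.5)), c(0.5, 0.5))
  expect_equal(make_morph_input(sp, 0), c(xat = 1, dat = 0))
  expect_error(make_morph_input(sp, 1.2), "0, 1")
})

test_that("spectra require endpoints differing in exactly one trait", {
  expect_error(morph_spectrum("xAt", "dat"), "exactly one trait")
  expect_error(morph_spectrum("dAt", "dAt"), "exactly one trait")
  expect_error(morph_spectrum("xat", "dat", proportions = c(0.2, 0.2, 0.4)),
               "strictly increasing")
  sp <- morph_spectrum("dat", "dAt")
  expect_equal(sp$trait, "vowel")
  expect_equal(sp$candidates$phoneme, c("a", "A"))
  all4 <- study_spectra()
  expect_setequal(vapply(all4, function(s) s$trait, ""),
                  c("consonant", "consonant", "vowel", "vowel"))
})

test_that("psychometric sweep is monotone and anchored at the endpoints", {
  cfg <- model_config(threshold_reduction = 0.3)
  sp <- morph_spectrum("xAt", "dAt", proportions = seq(0, 1, length.out = 6))
  cur <- run_psychometric_sweep(cfg, sp, phase_grid_size = 8)
  expect_true(all(cur$value_combined >= 0 & cur$value_combined <= 1))
  # nonincreasing in the proportion of the low-sensitivity endpoint
  # (= nondecreasing in p, the proportion of the frequent endpoint dAt)
  expect_true(all(diff(cur$value_combined) >= -1e-9))
  expect_lt(cur$value_combined[1], 0.5)
  expect_gt(cur$value_combined[6], 0.5)
  expect_error(run_psychometric_sweep(cfg, sp, phase_grid_size = 4), ">= 8")
})

test_that("a symmetric model without sensitivity gives 0.5 at the ambiguous morph", {
  cfg <- model_config(threshold_reduction = 0.3, sensitivity_enabled = FALSE)
  sp <- morph_spectrum("xAt", "dAt", proportions = c(0.25, 0.5, 0.75))
  cur <- run_psychometric_sweep(cfg, sp, phase_grid_size = 8)
  expect_equal(cur$value_combined[2], 0.5)
})

test_that("psychometric fitting recovers parameters and flags degenerate data", {
  p <- seq(0, 1, length.out = 10)
  y <- 1 / (1 + exp(-8 * (p - 0.45)))
  fit <- fit_psychometric(data.frame(proportion = p, value_combined = y))
  expect_lt(abs(fit$midpoint - 0.45), 0.01)
  expect_lt(abs(fit$slope - 8), 0.1)
  expect_false(fit$flag)

  flat <- fit_psychometric(data.frame(proportion = p,
                                      value_combined = rep(0.5, 10)))
  expect_true(flat$flag)

  step <- fit_psychometric(data.frame(proportion = p,
                                      value_combined = as.numeric(p > 0.5)))
  expect_lt(abs(step$midpoint - 0.5), diff(p)[1] + 1e-6)
  expect_error(fit_psychometric(data.frame(proportion = p[1:4],
                                           value_combined = y[1:4])),
               "5 points")
})

test_that("the default SOA grid spans two 6.25 Hz cycles in 12 steps", {
  soas <- default_soa_grid()
  expect_length(soas, 12)
  expect_equal(soas[1], 0.1)
  expect_equal(soas[12], 0.42)
  expect_equal(diff(range(soas)), 2 / 6.25)
  expect_equal(length(unique(round(diff(soas), 10))), 1)
})

test_that("entrainment responses are periodic in SOA at the oscillator period", {
  cfg <- model_config(threshold_reduction = 0.3)
  sp <- study_spectra()$xAt_dAt
  soas <- c(0.10, 0.18, 0.26, 0.34)
  ent <- run_entrainment_experiment(cfg, sp, 0.5, c(soas, soas + 0.16))
  expect_equal(ent$value_combined[1:4], ent$value_combined[5:8])
  expect_error(run_entrainment_experiment(cfg, sp, 0.5, numeric()), "nonempty")
  expect_error(run_entrainment_experiment(cfg, sp, 0.5, 1e-4), "step")
})

test_that("random-phase records are reproducible, uniform in phase, and labeled by words", {
  cfg <- model_config(threshold_reduction = 0.45)
  sp <- study_spectra()$xAt_dAt
  r1 <- run_random_phase_experiment(cfg, sp, 0.5, n_trials = 200, seed = 5)
  r2 <- run_random_phase_experiment(cfg, sp, 0.5, n_trials = 200, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$phase >= -pi & r1$phase < pi))
  expect_gt(rayleigh_test(r1$phase)$p, 0.01)
  expect_true(all(r1$phoneme_choice %in% c("xAt", "dAt")))
  expect_true(all(r1$word_choice %in% c("xAt", "dAt")))
})

test_that("without sensitivity the choice carries no phase information", {
  cfg <- model_config(threshold_reduction = 0, sensitivity_enabled = FALSE)
  sp <- study_spectra()$xAt_dAt
  r <- run_random_phase_experiment(cfg, sp, 0.5, n_trials = 400, seed = 3)
  y <- as.numeric(r$word_choice == "dAt")
  expect_gt(mean(y), 0.35)
  expect_lt(mean(y), 0.65)
  fit <- logistic_phase_regression(r$phase, y)
  expect_lt(fit$effect_magnitude, 0.35)
})

test_that("phase differences are zero against the reference itself and match construction", {
  recs <- data.frame(
    trial = 1:40,
    phase = wrap_pi(c(rnorm(20, 0.5, 0.05), rnorm(20, 0.5 - pi, 0.05))),
    phoneme_choice = rep(c("dAt", "xAt"), each = 20),
    word_choice = rep(c("dAt", "xAt"), each = 20),
    stringsAsFactors = FALSE)
  d <- compute_model_phase_differences(recs, "dAt", "phoneme")
  expect_equal(abs(unname(d["xAt"])), pi, tolerance = 0.1)
  same <- compute_model_phase_differences(
    rbind(recs, within(recs, trial <- trial + 40)), "dAt", "word")
  expect_equal(abs(unname(same["xAt"])), pi, tolerance = 0.1)
  only_ref <- recs[recs$phoneme_choice == "dAt", ]
  expect_error(compute_model_phase_differences(
    within(only_ref, phoneme_choice <- "xat"), "dAt", "phoneme"),
    "reference")
})
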