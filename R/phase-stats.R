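#' @useDynLib phasecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Wrap angles to \[-pi, pi)
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Circular mean direction
#' @param phases angles in radians.
#' @return mean direction in \[-pi, pi).
#' @export
circular_mean <- function(phases) {
  if (!length(phases)) stop("empty input")
  atan2(mean(sin(phases)), mean(cos(phases)))
}

#' Resultant length of a sample of angles
#' @param phases angles in radians.
#' @return mean resultant length in \[0, 1\].
#' @export
resultant_length <- function(phases) {
  sqrt(mean(sin(phases))^2 + mean(cos(phases))^2)
}

#' Difference of circular means
#'
#' `circular_mean(a) - circular_mean(b)`, wrapped to \[-pi, pi). The
#' boundary case of exactly opposite means returns `-pi` (the wrap
#' convention of [wrap_pi()]).
#'
#' @param phases_a,phases_b nonempty angle vectors (radians).
#' @return wrapped difference in radians.
#' @export
circular_mean_difference <- function(phases_a, phases_b) {
  if (!length(phases_a) || !length(phases_b)) stop("empty input")
  wrap_pi(circular_mean(phases_a) - circular_mean(phases_b))
}

#' Directed test for circular nonuniformity (v-test)
#'
#' Tests nonuniformity of a sample of angles with a prespecified mean
#' direction `mu`: `V = n * R * cos(theta_bar - mu)` where `R` is the mean
#' resultant length and `theta_bar` the sample mean direction. The p-value
#' uses the one-sided normal approximation of `u = V * sqrt(2 / n)`.
#'
#' @param phases angles in radians (n >= 5 recommended).
#' @param mu hypothesized direction in radians.
#' @return Object of class `v_test` with `n`, `mean_direction`,
#'   `resultant_length`, `mu`, `V`, `u`, `p`.
#' @export
v_test <- function(phases, mu) {
  n <- length(phases)
  rbar <- resultant_length(phases)
  theta <- circular_mean(phases)
  v <- n * rbar * cos(theta - mu)
  u <- v * sqrt(2 / n)
  structure(list(n = n, mean_direction = theta, resultant_length = rbar,
                 mu = mu, V = v, u = u,
                 p = stats::pnorm(u, lower.tail = FALSE)),
            class = "v_test")
}

#' @export
print.v_test <- function(x, ...) {
  cat(sprintf("v-test: V = %.3f (n = %d, mu = %.3f rad), p = %.4g\n",
              x$V, x$n, x$mu, x$p))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Undirected companion of [v_test()]; used to check that generated phases
#' are uniform. P-value by the standard approximation
#' `exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))`.
#'
#' @param phases angles in radians.
#' @return list with `R` (resultant length), `z = n * R^2`, `p`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  rbar <- resultant_length(phases)
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (rbar * n)^2)) - (1 + 2 * n))
  list(R = rbar, z = z, p = min(1, p))
}

#' Combine p-values by their product
#'
#' The conjunction rule for a set of independent directed tests: the
#' product of the p-values is reported as the probability of all events
#' jointly. (Deliberately not Fisher's method.)
#'
#' @param ps numeric vector of p-values in (0, 1\].
#' @return the product.
#' @export
combine_pvalues_product <- function(ps) {
  if (!length(ps)) stop("empty p-value list")
  if (any(ps <= 0 | ps > 1)) stop("p-values must lie in (0, 1]")
  prod(ps)
}

#' Per-participant demeaned response time courses
#'
#' Aggregates a behavioral response table to proportions per participant
#' and condition (SOA), removes each participant's mean across conditions,
#' and averages across participants.
#'
#' @param table a response table (see [read_response_table()]): columns
#'   `participant`, `soa_s`, `response` (0/1); extra columns ignored.
#' @return List of class `demeaned_responses`: `soas`, `participant_curves`
#'   (participants x SOA matrix, demeaned), `group_curve`.
#' @export
demean_responses <- function(table) {
  stopifnot(all(c("participant", "soa_s", "response") %in% names(table)))
  soas <- sort(unique(table$soa_s))
  parts <- unique(table$participant)
  agg <- tapply(table$response,
                list(factor(table$participant, parts),
                     factor(table$soa_s, soas)), mean)
  if (anyNA(agg))
    stop("every participant must cover all SOA conditions")
  dem <- agg - rowMeans(agg)
  structure(list(soas = soas, participant_curves = dem,
                 group_curve = colMeans(dem)),
            class = "demeaned_responses")
}

# Projection matrix onto {1, sin, cos} at frequency f over SOAs (s). The
# intercept matters: on a finite SOA grid the sinusoid pair is not exactly
# orthogonal to the constant.
sinusoid_projection <- function(soas, f) {
  x <- cbind(1, sin(2 * pi * f * soas), cos(2 * pi * f * soas))
  x %*% solve(crossprod(x), t(x))
}

#' Least-squares sinusoid fit at a fixed frequency
#'
#' Regresses a demeaned group time course on `sin(2 pi f s)` and
#' `cos(2 pi f s)` (plus an intercept, which absorbs the demeaning shift
#' on a finite SOA grid) over the SOAs `s`. Amplitude is
#' `sqrt(a^2 + b^2)`, phase `atan2(a, b)`, and
#' `r^2 = 1 - SSresid / SStotal` the explained variance about the mean.
#'
#' @param y demeaned group curve (one value per SOA).
#' @param soas SOAs in seconds (>= 3).
#' @param f fixed frequency in Hz.
#' @return Object of class `sinusoid_fit` with `frequency`, `sin_coef`,
#'   `cos_coef`, `amplitude`, `phase`, `r_squared`, `fitted`. A
#'   zero-variance input yields `r_squared = NA` and `flag = TRUE`.
#' @export
fit_fixed_frequency_sinusoid <- function(y, soas, f) {
  if (length(soas) < 3) stop("need at least 3 SOAs")
  stopifnot(length(y) == length(soas))
  x <- cbind(1, sin(2 * pi * f * soas), cos(2 * pi * f * soas))
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-20)
    return(structure(list(frequency = f, sin_coef = 0, cos_coef = 0,
                          amplitude = 0, phase = NA_real_,
                          r_squared = NA_real_, flag = TRUE,
                          fitted = rep(0, length(y))),
                     class = "sinusoid_fit"))
  cf <- solve(crossprod(x), crossprod(x, y))
  fitted <- drop(x %*% cf)
  r2 <- 1 - sum((y - fitted)^2) / sst
  structure(list(frequency = f, sin_coef = cf[2], cos_coef = cf[3],
                 amplitude = sqrt(cf[2]^2 + cf[3]^2),
                 phase = atan2(cf[2], cf[3]),
                 r_squared = r2, flag = FALSE, fitted = fitted),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "sinusoid_fit @ %.3g Hz: amplitude %.3f, phase %.3f rad, r^2 %.3f\n",
    x$frequency, x$amplitude, x$phase, x$r_squared))
  invisible(x)
}

#' Permutation test of a fixed-frequency sinusoid fit
#'
#' Observed statistic: the `r^2` of the sinusoid fit to the demeaned group
#' curve. Null distribution: SOA labels are shuffled independently within
#' each participant and the group fit repeated. The p-value uses the
#' add-one rule `(1 + #{null >= obs}) / (1 + n_perm)`.
#'
#' @param table behavioral response table.
#' @param f fixed frequency in Hz.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return Object of class `permutation_test` with `observed`, `null`
#'   (numeric vector), `p`, `n_perm`, `seed`, and the group `fit`.
#' @export
permutation_sinusoid_test <- function(table, f = 6.25, n_perm = 10000,
                                      seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  dem <- demean_responses(table)
  fit <- fit_fixed_frequency_sinusoid(dem$group_curve, dem$soas, f)
  m_proj <- sinusoid_projection(dem$soas, f)
  set.seed(seed)
  null <- cpp_perm_r2(dem$participant_curves, m_proj, as.integer(n_perm))
  obs <- fit$r_squared
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(list(observed = obs, null = null, p = p, n_perm = n_perm,
                 seed = seed, fit = fit),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test: observed %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Split-half comparison of the sinusoid fit
#'
#' Fits the fixed-frequency sinusoid separately to the first and second
#' half of the experiment (column `half` of the table) and tests the
#' statistic `r^2(first) - r^2(second)` against a null obtained by
#' shuffling the half labels within participant.
#'
#' @param table behavioral response table with a `half` column (1 or 2).
#' @param f fixed frequency in Hz.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `statistic`, `r2_first`, `r2_second`, `null`, `p`
#'   (one-sided, add-one rule).
#' @export
split_half_comparison <- function(table, f = 6.25, n_perm = 1000, seed = 1) {
  if (!"half" %in% names(table))
    stop("table must carry a 'half' column with within-experiment order")
  half_r2 <- function(tb) {
    r2 <- vapply(c(1, 2), function(h) {
      dem <- demean_responses(tb[tb$half == h, , drop = FALSE])
      fit_fixed_frequency_sinusoid(dem$group_curve, dem$soas, f)$r_squared
    }, 0)
    r2
  }
  obs <- half_r2(table)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    tb <- table
    for (p in unique(tb$participant)) {
      i <- which(tb$participant == p)
      tb$half[i] <- sample(tb$half[i])
    }
    r2 <- half_r2(tb)
    r2[1] - r2[2]
  }, 0)
  stat <- obs[1] - obs[2]
  list(statistic = stat, r2_first = obs[1], r2_second = obs[2],
       null = null, p = (1 + sum(null >= stat)) / (1 + n_perm))
}
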