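#' Default time-frequency analysis grid
#'
#' Frequencies 1-15 Hz in 1 Hz steps and prestimulus times -0.5 to 0 s in
#' 20 ms steps (15 x 26 grid).
#'
#' @return list with `freqs` (Hz) and `times` (s).
#' @export
default_tf_grid <- function() {
  list(freqs = 1:15, times = seq(-0.5, 0, by = 0.02))
}

#' Single-trial time-frequency phase via Morlet wavelets
#'
#' Convolves each trial with complex Morlet wavelets
#' (`n_cycles` cycles, Gaussian SD `n_cycles / (2 pi f)` in time) and
#' returns the phase of the complex spectrum at the requested grid points.
#' Grid points whose wavelet support (±2.5 SD) extends beyond the epoch are
#' flagged missing (`NA`).
#'
#' @param trials trials x samples numeric matrix.
#' @param times sample times in seconds (uniform grid).
#' @param freqs analysis frequencies in Hz.
#' @param out_times time points (s) at which phase is extracted.
#' @param n_cycles Morlet width in cycles.
#' @param responses optional per-trial binary labels stored alongside.
#' @param participant optional participant id.
#' @return Object of class `tf_phase_grid`: list with `phase`
#'   (trials x freq x time array, radians in \[-pi, pi)), `freqs`, `times`
#'   (= `out_times`), `responses`, `participant`.
#' @export
extract_tf_phase <- function(trials, times, freqs, out_times,
                             n_cycles = 5, responses = NULL,
                             participant = NA) {
  stopifnot(is.matrix(trials), ncol(trials) == length(times))
  sfreq <- 1 / mean(diff(times))
  if (sfreq < 2 * max(freqs))
    stop("sampling rate must be at least twice the maximum frequency")
  n_trials <- nrow(trials)
  ns <- length(times)
  out_idx <- vapply(out_times, function(tt) which.min(abs(times - tt)), 0L)

  # FFT length covering signal + the longest wavelet
  max_half <- ceiling(2.5 * n_cycles / (2 * pi * min(freqs)) * sfreq)
  nfft <- stats::nextn(ns + 2 * max_half + 1, 2)

  ph <- array(NA_real_, c(n_trials, length(freqs), length(out_times)))
  tr_fft <- stats::mvfft(t(cbind(trials, matrix(0, n_trials, nfft - ns))))

  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sd_t <- n_cycles / (2 * pi * f)
    half <- ceiling(2.5 * sd_t * sfreq)
    tw <- (-half:half) / sfreq
    w <- exp(-tw^2 / (2 * sd_t^2)) * exp(2i * pi * f * tw)
    w <- w / sum(abs(w))
    wpad <- complex(length.out = nfft)
    wpad[1:length(w)] <- w
    wf <- stats::fft(wpad)
    conv <- stats::mvfft(tr_fft * wf, inverse = TRUE) / nfft
    # full wavelet support must lie inside the epoch
    valid <- out_idx - half >= 1 & out_idx + half <= ns
    sel <- out_idx[valid] + half
    if (any(valid))
      ph[, fi, valid] <- t(Arg(conv[sel, , drop = FALSE]))
  }
  structure(list(phase = ph, freqs = freqs, times = out_times,
                 responses = responses, participant = participant),
            class = "tf_phase_grid")
}

#' Logistic regression of a binary response on oscillatory phase
#'
#' Maximum-likelihood logit fit of `response ~ sin(phase) + cos(phase)`.
#' The phase-effect magnitude is `sqrt(beta_sin^2 + beta_cos^2)` and the
#' preferred phase (at which P(response = 1) is maximal) is
#' `atan2(beta_sin, beta_cos)`.
#'
#' @param phases per-trial phases in radians (>= 20 trials).
#' @param responses binary 0/1 vector; both classes must be present.
#' @param cap absolute cap applied to coefficients when (quasi-)separation
#'   is detected; the fit is then flagged.
#' @return Object of class `logistic_phase_fit` with `beta0`, `beta_sin`,
#'   `beta_cos`, `effect_magnitude`, `preferred_phase`, `flag`.
#' @export
logistic_phase_regression <- function(phases, responses, cap = 15) {
  if (length(phases) < 20) stop("need at least 20 trials")
  if (length(unique(responses)) < 2)
    stop("both response classes must be present")
  df <- data.frame(y = responses, s = sin(phases), c = cos(phases))
  fit <- suppressWarnings(stats::glm(y ~ s + c, data = df,
                                     family = stats::binomial()))
  cf <- stats::coef(fit)
  flag <- !fit$converged || any(abs(cf) > cap)
  cf <- pmin(pmax(cf, -cap), cap)
  structure(list(beta0 = unname(cf[1]), beta_sin = unname(cf[2]),
                 beta_cos = unname(cf[3]),
                 effect_magnitude = unname(sqrt(cf[2]^2 + cf[3]^2)),
                 preferred_phase = unname(atan2(cf[2], cf[3])),
                 flag = flag),
            class = "logistic_phase_fit")
}

#' Null-centered phase-effect magnitude map for one participant
#'
#' At every time-frequency grid point the logistic phase-effect magnitude
#' (see [logistic_phase_regression()]) is computed, and its positive bias
#' under the null is removed by subtracting the mean magnitude over
#' `n_perm_center` within-participant permutations of the response labels.
#' The centered maps are the per-participant quantities entering
#' [group_cluster_test()].
#'
#' @param grid a `tf_phase_grid` with responses.
#' @param n_perm_center permutations used for centering.
#' @return freq x time matrix of centered magnitudes (NA where the grid has
#'   missing phases).
#' @export
participant_effect_map <- function(grid, n_perm_center = 20) {
  stopifnot(inherits(grid, "tf_phase_grid"), !is.null(grid$responses))
  dm <- dim(grid$phase)
  flat <- matrix(grid$phase, dm[1], dm[2] * dm[3])
  ok <- !apply(is.na(flat), 2, any)
  res <- cpp_logit_maps(flat[, ok, drop = FALSE],
                        as.integer(grid$responses),
                        as.integer(n_perm_center))
  out <- rep(NA_real_, dm[2] * dm[3])
  out[ok] <- res$observed - res$null_mean
  matrix(out, dm[2], dm[3],
         dimnames = list(paste0(grid$freqs, "Hz"), grid$times))
}

# BFS cluster labels on an nf x nt matrix (4-neighborhood), via compiled core
find_clusters <- function(stat, threshold) {
  lab <- cpp_label_clusters(as.numeric(stat), nrow(stat), ncol(stat),
                            threshold)
  matrix(lab, nrow(stat), ncol(stat))
}

#' Cluster-based permutation test across participants
#'
#' One-sample t-statistics across participants are computed at every grid
#' point of the (null-centered) effect maps; contiguous suprathreshold
#' points (4-neighborhood, pointwise one-sided p < `cluster_alpha` under
#' the t distribution) form clusters whose statistic is the sum of member
#' t-values. The null distribution of the maximum cluster statistic is
#' built by randomly flipping the sign of whole participant maps (the
#' within-participant label exchange of a one-sample design); cluster
#' p-values use the add-one rule.
#'
#' @param maps participants x freq x time array of effect maps (no NAs).
#' @param cluster_alpha pointwise cluster-forming alpha.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed RNG seed.
#' @return Object of class `cluster_test` with `stat_map` (freq x time
#'   t-values), `clusters` (list of `mask` index matrix, `stat`, `p`),
#'   `threshold` (t cutoff), `max_null`, `n_perm`, `seed`.
#' @export
group_cluster_test <- function(maps, cluster_alpha = 0.05, n_perm = 500,
                               seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  dm <- dim(maps)
  n <- dm[1]
  if (n < 5) stop("need at least 5 participants")
  nf <- dm[2]; nt <- dm[3]
  x <- matrix(maps, n, nf * nt)
  if (anyNA(x)) stop("effect maps contain missing grid points")
  thr <- stats::qt(1 - cluster_alpha, df = n - 1)

  mu <- colMeans(x)
  sde <- apply(x, 2, stats::sd) / sqrt(n)
  tmap <- matrix(mu / pmax(sde, 1e-15), nf, nt)

  lab <- find_clusters(tmap, thr)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sums <- vapply(ids, function(k) sum(tmap[lab == k]), 0)
  ord <- order(sums, decreasing = TRUE)
  ids <- ids[ord]; sums <- sums[ord]

  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  means <- (signs %*% x) / n
  max_null <- cpp_max_cluster_sums(means, colSums(x^2), n, thr, nf, nt)

  clusters <- lapply(seq_along(ids), function(i) {
    list(mask = which(lab == ids[i], arr.ind = TRUE),
         stat = sums[i],
         p = (1 + sum(max_null >= sums[i])) / (1 + n_perm))
  })
  structure(list(stat_map = tmap, clusters = clusters, threshold = thr,
                 max_null = max_null, n_perm = n_perm, seed = seed,
                 n_participants = n),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("cluster test: %d cluster(s), t-threshold %.2f, %d perms\n",
              length(x$clusters), x$threshold, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  stat = %.2f (%d points), p = %.4g\n",
                cl$stat, nrow(cl$mask), cl$p))
  invisible(x)
}

#' Significant-cluster membership of a grid point
#'
#' Convenience predicate: is any cluster with `p < alpha` within
#' `freq_tol` / `time_tol` of the target (freq, time) point?
#'
#' @param test a `cluster_test`.
#' @param freqs,times the grid axes the maps were computed on.
#' @param freq,time target point (Hz, s).
#' @param alpha significance level.
#' @param freq_tol,time_tol tolerance around the target.
#' @return logical.
#' @export
cluster_covers <- function(test, freqs, times, freq, time, alpha = 0.05,
                           freq_tol = 1, time_tol = 0.06) {
  for (cl in test$clusters) {
    if (cl$p >= alpha) next
    fd <- abs(freqs[cl$mask[, 1]] - freq)
    td <- abs(times[cl$mask[, 2]] - time)
    if (any(fd <= freq_tol & td <= time_tol)) return(TRUE)
  }
  FALSE
}
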