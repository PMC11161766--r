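#' Read a behavioral response table
#'
#' Tab-separated text with header. Required columns: `participant`,
#' `soa_s` (SOA in seconds) or `phase_rad` (presentation phase in
#' radians), `morph`, `response` (strictly 0/1). Optional: `half`.
#' SOAs that look like milliseconds (values > 10) are rejected.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_response_table(tb)
  tb
}

validate_response_table <- function(tb) {
  need <- c("participant", "morph", "response")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("response table is missing column(s): ", paste(miss, collapse = ", "))
  has_soa <- "soa_s" %in% names(tb)
  has_phase <- "phase_rad" %in% names(tb)
  if (!has_soa && !has_phase)
    stop("response table needs a 'soa_s' or 'phase_rad' condition column")
  if (has_soa && has_phase)
    stop("mixed condition units: provide either 'soa_s' or 'phase_rad'")
  if (!all(tb$response %in% c(0, 1)))
    stop("responses must be binary 0/1")
  if (has_soa && any(tb$soa_s > 10))
    stop("soa_s values > 10 look like milliseconds; units must be seconds")
  invisible(tb)
}

#' Write a behavioral response table
#'
#' @param table a valid response table.
#' @param path output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  validate_response_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run manifest for a workflow result
#'
#' Records the configuration, seed and package version with a result so a
#' run can be reproduced exactly.
#'
#' @param config the configuration object (list).
#' @param seed the seed(s) used.
#' @param extra optional named list of additional fields.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, extra = list()) {
  structure(c(list(
    config = config, seed = seed,
    package_version = as.character(utils::packageVersion("phasecode")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra),
    class = "run_manifest")
}

#' Full model study: psychometric, entrainment and random-phase protocols
#'
#' Runs the complete simulated experiment chain for a configuration:
#' (1) psychometric sweep over all four morph spectra, (2) logistic fits
#' and extraction of each spectrum's most ambiguous morph (the fitted
#' midpoint), (3) entrainment SOA sweep per spectrum at that morph, and
#' (4) random-phase trial simulation on the two consonant spectra with the
#' circular phase-difference readout against /dαt/.
#'
#' @param config a [model_config()]; the headline configuration uses
#'   `threshold_reduction = 0.3` for the psychometric/entrainment stages
#'   and 0.45 for the random-phase stage (pass `random_phase_config` to
#'   override).
#' @param random_phase_config optional separate config for the
#'   random-phase stage; defaults to `config`.
#' @param n_random_trials random-phase trials per consonant spectrum.
#' @param soas entrainment SOA grid (s).
#' @param phase_grid_size psychometric phase grid.
#' @param seed RNG seed (random-phase guesses).
#' @param out_dir if non-`NULL`, results are written there as TSV tables
#'   plus a JSON manifest.
#' @return List of class `model_study` with `psychometric` (curves),
#'   `fits`, `ambiguous` (named midpoints), `entrainment` (per-spectrum
#'   data.frames), `random_phase` (pooled records),
#'   `phase_differences` (list with `phoneme`, `word`), and `manifest`.
#' @export
run_full_model_study <- function(config = model_config(threshold_reduction = 0.3),
                                 random_phase_config = NULL,
                                 n_random_trials = 1000,
                                 soas = default_soa_grid(),
                                 phase_grid_size = 16,
                                 seed = 1,
                                 out_dir = NULL) {
  if (is.null(random_phase_config)) random_phase_config <- config
  spectra <- study_spectra()
  psychometric <- lapply(spectra, function(sp)
    run_psychometric_sweep(config, sp, phase_grid_size))
  fits <- lapply(psychometric, fit_psychometric)
  ambiguous <- vapply(fits, function(f) f$midpoint, 0)

  entrainment <- mapply(function(sp, p)
    run_entrainment_experiment(config, sp, p, soas),
    spectra, ambiguous[names(spectra)], SIMPLIFY = FALSE)

  # the neural (random-phase) protocol uses the consonant spectra only
  cons <- c("xAt_dAt", "xat_dat")
  rp_fits <- lapply(cons, function(nm) {
    curve <- run_psychometric_sweep(random_phase_config, spectra[[nm]],
                                    phase_grid_size)
    fit_psychometric(curve)
  })
  names(rp_fits) <- cons
  records <- mapply(function(nm, i)
    run_random_phase_experiment(random_phase_config, spectra[[nm]],
                                rp_fits[[nm]]$midpoint,
                                n_trials = n_random_trials,
                                seed = seed + i),
    cons, seq_along(cons), SIMPLIFY = FALSE)
  pooled <- do.call(rbind, records)
  phase_differences <- list(
    phoneme = compute_model_phase_differences(pooled, "dAt", "phoneme"),
    word = compute_model_phase_differences(pooled, "dAt", "word"))

  out <- structure(
    list(psychometric = psychometric, fits = fits, ambiguous = ambiguous,
         entrainment = entrainment, random_phase = pooled,
         phase_differences = phase_differences,
         manifest = run_manifest(unclass(config), seed)),
    class = "model_study")
  if (!is.null(out_dir)) write_model_study(out, out_dir)
  out
}

write_model_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psy <- do.call(rbind, lapply(names(study$psychometric), function(nm)
    cbind(spectrum = nm, study$psychometric[[nm]])))
  utils::write.table(psy, file.path(out_dir, "psychometric.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ent <- do.call(rbind, lapply(names(study$entrainment), function(nm)
    cbind(spectrum = nm, study$entrainment[[nm]])))
  utils::write.table(ent, file.path(out_dir, "entrainment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$random_phase,
                     file.path(out_dir, "random_phase_trials.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(ambiguous = as.list(study$ambiguous),
         phase_differences = lapply(study$phase_differences, as.list),
         manifest = unclass(study$manifest)),
    file.path(out_dir, "model_study.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Synthetic validation suite
#'
#' Calibration checks of the statistical chain on synthetic data: type-I
#' error and power of the sinusoid permutation test, preferred-phase
#' recovery of the logistic phase regression, and family-wise error of the
#' cluster test on null Gaussian maps. Problem sizes are parameters so the
#' suite scales from smoke test to full calibration.
#'
#' @param n_type1 null behavioral datasets for the type-I rate.
#' @param n_power datasets per modulation amplitude.
#' @param amplitudes modulation amplitudes for the power curve.
#' @param n_perm permutations per sinusoid test.
#' @param n_recovery seeds for preferred-phase recovery.
#' @param n_fwer null map simulations for cluster FWER.
#' @param fwer_dims `c(participants, freqs, times)` of the null maps.
#' @param n_perm_cluster sign-flip permutations per cluster test.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return List of class `validation_report`: `type1_rate`, `power`
#'   (named by amplitude), `phase_recovery_median_error` (rad),
#'   `cluster_fwer`, and the sizes used.
#' @export
run_synthetic_validation <- function(n_type1 = 200, n_power = 100,
                                     amplitudes = c(0, 0.05, 0.1, 0.15),
                                     n_perm = 199, n_recovery = 20,
                                     n_fwer = 100,
                                     fwer_dims = c(20, 15, 26),
                                     n_perm_cluster = 200,
                                     alpha = 0.05, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_type1 + n_power * length(amplitudes) +
                        n_recovery + n_fwer + 1)
  si <- 0L

  reject <- logical(n_type1)
  for (i in seq_len(n_type1)) {
    si <- si + 1L
    tb <- generate_behavioral_dataset(behavioral_sim_spec(), seeds[si])
    reject[i] <- permutation_sinusoid_test(tb, 6.25, n_perm,
                                           seed = seeds[si])$p < alpha
  }
  type1 <- mean(reject)

  power <- vapply(amplitudes, function(a) {
    hits <- logical(n_power)
    for (i in seq_len(n_power)) {
      si <<- si + 1L
      tb <- generate_behavioral_dataset(
        behavioral_sim_spec(modulation_amplitude = a), seeds[si])
      hits[i] <- permutation_sinusoid_test(tb, 6.25, n_perm,
                                           seed = seeds[si])$p < alpha
    }
    mean(hits)
  }, 0)
  names(power) <- paste0("amp_", amplitudes)

  err <- vapply(seq_len(n_recovery), function(i) {
    si <<- si + 1L
    set.seed(seeds[si])
    phi0 <- stats::runif(1, -pi, pi)
    ph <- stats::runif(500, -pi, pi)
    y <- stats::rbinom(500, 1, stats::plogis(cos(ph - phi0)))
    fit <- logistic_phase_regression(ph, y)
    abs(wrap_pi(fit$preferred_phase - phi0))
  }, 0)

  fwer_hits <- logical(n_fwer)
  for (i in seq_len(n_fwer)) {
    si <- si + 1L
    set.seed(seeds[si])
    maps <- array(stats::rnorm(prod(fwer_dims)), fwer_dims)
    ct <- group_cluster_test(maps, n_perm = n_perm_cluster,
                             seed = seeds[si])
    ps <- vapply(ct$clusters, function(cl) cl$p, 0)
    fwer_hits[i] <- length(ps) > 0 && min(ps) < alpha
  }

  structure(list(
    type1_rate = type1, power = as.list(power),
    phase_recovery_median_error = stats::median(err),
    cluster_fwer = mean(fwer_hits),
    sizes = list(n_type1 = n_type1, n_power = n_power, n_perm = n_perm,
                 n_recovery = n_recovery, n_fwer = n_fwer,
                 fwer_dims = fwer_dims, alpha = alpha, seed = seed)),
    class = "validation_report")
}

#' Write a validation report as JSON
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
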