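#' Pipeline configuration
#'
#' Collects every tunable of the training/prediction pipeline with its
#' default, validating against the component preconditions.
#'
#' @param prior First-level [prior_spec()].
#' @param thresholds [classification_thresholds()].
#' @param iters,chains,thin_to Per-patient MCMC settings.
#' @param beta Kernel expansion factor for the second-level prior.
#' @param M Second-level prior particle count.
#' @param noise_upper Upper bound of the noise-parameter priors.
#' @param horizon Final-volume prediction time (days); defaults to three
#'   days after the schedule's final dose (day 56 for a day-53 final dose).
#' @param schedule Standard schedule used for classification.
#' @param convention Dose impulse convention, see [apply_dose()].
#' @param seed Integer seed for the whole pipeline.
#' @return A classed list of settings.
#' @export
rt_config <- function(prior = prior_spec(),
                      thresholds = classification_thresholds(),
                      iters = 25000, chains = 4, thin_to = 2500,
                      beta = 2, M = 100000, noise_upper = 0.5,
                      horizon = NULL, schedule = standard_schedule(),
                      convention = "transfer", seed = 1) {
  if (is.null(horizon)) horizon <- max(schedule$dose_times) + 3
  stopifnot(inherits(prior, "rt_prior"), inherits(thresholds,
                                                  "rt_thresholds"),
            iters >= 2, chains >= 1, thin_to >= 1, beta >= 0, M >= 1,
            noise_upper > 0, horizon >= 0)
  structure(list(prior = prior, thresholds = thresholds, iters = iters,
                 chains = chains, thin_to = thin_to, beta = beta, M = M,
                 noise_upper = noise_upper, horizon = horizon,
                 schedule = schedule, convention = convention, seed = seed),
            class = "rt_config")
}

#' Train the population-level model on a cohort
#'
#' Runs the full training workflow: cohort-level noise pre-estimation,
#' per-patient posterior sampling under the first-level prior with the
#' noise parameters fixed, pooling into the population-level posterior, and
#' truncated-kernel expansion into the second-level prior.
#'
#' @param cohort A named list of [observation_set()] objects (>= 2).
#' @param config An [rt_config()].
#' @param noise Optional pre-estimated [noise_params()]; when supplied the
#'   noise pre-estimation stage is skipped.
#' @param out_dir Optional directory: persists posterior samples, particle
#'   sets, the configuration and all seeds.
#' @param verbose Print stage-boundary progress.
#' @return An object of class `"rt_training"` with elements `noise`,
#'   `posteriors` (per patient), `pooled`, `second_level`, `config`.
#' @export
run_training <- function(cohort, config = rt_config(), noise = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(length(cohort) >= 2)
  cohort <- lapply(cohort, function(x)
    if (inherits(x, "rt_synth_patient")) x$obs else x)
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 1, length(cohort) + 2)
  if (is.null(noise)) {
    if (verbose) message("Pre-estimating noise parameters ...")
    noise <- estimate_noise_params(
      cohort, config$prior, config$noise_upper, iters = config$iters,
      chains = config$chains, thin_to = config$thin_to,
      seed = seeds[length(cohort) + 1], convention = config$convention)
  }
  posteriors <- vector("list", length(cohort))
  names(posteriors) <- names(cohort)
  for (i in seq_along(cohort)) {
    if (verbose) message("Sampling posterior for patient ",
                         names(cohort)[i], " ...")
    posteriors[[i]] <- sample_posterior_mcmc(
      cohort[[i]], config$prior, noise, iters = config$iters,
      chains = config$chains, thin_to = config$thin_to, seed = seeds[i],
      convention = config$convention)
  }
  pooled <- pool_posteriors(posteriors)
  if (verbose) message("Building second-level prior (M = ", config$M,
                       ") ...")
  second <- build_second_level_prior(
    pooled, silverman_covariance(pooled, config$beta), M = config$M,
    bounds = config$prior, seed = seeds[length(cohort) + 2])
  out <- structure(list(noise = noise, posteriors = posteriors,
                        pooled = pooled, second_level = second,
                        config = config, seeds = seeds),
                   class = "rt_training")
  if (!is.null(out_dir)) persist_training(out, out_dir)
  out
}

#' @export
print.rt_training <- function(x, ...) {
  cat(sprintf("Trained population model: %d patients, %d pooled draws,\n",
              length(x$posteriors), nrow(x$pooled$theta)))
  cat(sprintf("  second-level prior with %d particles; noise sd(V) = %.4g + %.4g V\n",
              nrow(x$second_level$theta), x$noise$alpha1, x$noise$alpha2))
  invisible(x)
}

persist_training <- function(training, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  post <- do.call(rbind, lapply(names(training$posteriors), function(id) {
    d <- as.data.frame(training$posteriors[[id]]$draws)
    d$patient_id <- id
    d
  }))
  utils::write.csv(post, file.path(out_dir, "posterior_samples.csv"),
                   row.names = FALSE)
  p2 <- as.data.frame(training$second_level$theta)
  p2$weight <- training$second_level$weights
  p2$provenance <- training$second_level$provenance
  utils::write.csv(p2, file.path(out_dir, "particles.csv"),
                   row.names = FALSE)
  cfg <- training$config
  jsonlite::write_json(
    list(noise = list(alpha1 = training$noise$alpha1,
                      alpha2 = training$noise$alpha2),
         seeds = training$seeds, seed = cfg$seed,
         prior = list(lower = cfg$prior$lower, upper = cfg$prior$upper),
         thresholds = unclass(cfg$thresholds),
         mcmc = list(iters = cfg$iters, chains = cfg$chains,
                     thin_to = cfg$thin_to),
         beta = cfg$beta, M = cfg$M, horizon = cfg$horizon,
         convention = cfg$convention),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Real-time weekly prediction for a new patient
#'
#' Replays the patient's record: at each measurement time, filters the
#' second-level prior on all data up to and including that time and emits
#' the final-volume prediction and response-class probabilities.
#'
#' @param obs The new patient's [observation_set()].
#' @param second_level The trained second-level prior particles (or an
#'   `rt_training` object).
#' @param noise The pre-estimated [noise_params()] (taken from the training
#'   object if one is supplied).
#' @param config An [rt_config()].
#' @param times Prediction times; defaults to the patient's measurement
#'   times.
#' @return A list with `final_volume` (data frame, one row per prediction
#'   time: mean and intervals of V(horizon) plus filter ESS) and
#'   `class_probs` (data frame of per-class probabilities by prediction
#'   time), of class `"rt_realtime"`.
#' @export
run_realtime_prediction <- function(obs, second_level, noise = NULL,
                                    config = rt_config(), times = NULL) {
  if (inherits(second_level, "rt_training")) {
    if (is.null(noise)) noise <- second_level$noise
    second_level <- second_level$second_level
  }
  stopifnot(inherits(second_level, "rt_particles"),
            inherits(noise, "rt_noise"))
  if (is.null(times)) times <- obs$times
  fv <- NULL
  cp <- NULL
  for (tt in times) {
    o <- observations_upto(obs, tt)
    flt <- particle_filter_update(second_level, o, noise,
                                  convention = config$convention)
    pred <- predict_final_volume(flt, obs$dose_times, config$horizon,
                                 convention = config$convention)
    probs <- predict_class_probs(flt, config$schedule, config$thresholds,
                                 convention = config$convention)
    fv <- rbind(fv, cbind(prediction_time = tt, pred,
                          ess = attr(flt, "ess"),
                          n_obs_used = length(o$times)))
    cp <- rbind(cp, data.frame(prediction_time = tt, t(probs)))
  }
  structure(list(final_volume = fv, class_probs = cp,
                 patient_id = obs$patient_id, horizon = config$horizon),
            class = "rt_realtime")
}

#' @export
print.rt_realtime <- function(x, ...) {
  cat(sprintf("Real-time predictions for patient %s (horizon day %g):\n",
              x$patient_id, x$horizon))
  print(round(x$final_volume[, c("prediction_time", "mean", "q025",
                                 "q975", "ess")], 3))
  invisible(x)
}

#' Leave-one-out cross-validation over a cohort
#'
#' For each patient: retrains the pooled posterior and second-level prior on
#' the remaining patients (the pre-estimated noise parameters are shared)
#' and runs the real-time prediction replay on the held-out record.
#'
#' @param cohort A named list of [observation_set()] objects (>= 3).
#' @param config An [rt_config()].
#' @param noise Optional pre-estimated [noise_params()] shared across
#'   folds; estimated from the full cohort when omitted.
#' @param verbose Print per-fold progress.
#' @return A named list of `rt_realtime` reports, one per held-out patient,
#'   with a `summary` attribute (final-volume prediction error per patient).
#' @export
run_loocv <- function(cohort, config = rt_config(), noise = NULL,
                      verbose = FALSE) {
  stopifnot(length(cohort) >= 3)
  cohort <- lapply(cohort, function(x)
    if (inherits(x, "rt_synth_patient")) x$obs else x)
  if (is.null(noise)) {
    set.seed(config$seed)
    noise <- estimate_noise_params(
      cohort, config$prior, config$noise_upper, iters = config$iters,
      chains = config$chains, thin_to = config$thin_to,
      seed = sample.int(2^31 - 1, 1), convention = config$convention)
  }
  reports <- list()
  for (id in names(cohort)) {
    if (verbose) message("LOOCV fold: holding out ", id)
    train_set <- cohort[names(cohort) != id]
    stopifnot(!id %in% names(train_set))
    trained <- run_training(train_set, config, noise = noise)
    reports[[id]] <- run_realtime_prediction(cohort[[id]], trained,
                                             config = config)
  }
  err <- vapply(names(reports), function(id) {
    fv <- reports[[id]]$final_volume
    last <- fv[nrow(fv), ]
    obs <- cohort[[id]]
    truth <- obs$v_obs[length(obs$v_obs)]
    last$mean - truth
  }, numeric(1))
  attr(reports, "summary") <- data.frame(patient_id = names(reports),
                                         final_volume_error = err)
  reports
}
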