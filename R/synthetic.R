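#' Generate a synthetic patient
#'
#' Draws a parameter vector from the given source (a box prior or a weighted
#' particle set), optionally rejecting draws until the noise-free response
#' matches a target class, simulates the noise-free measurement series under
#' the schedule, and adds measurement noise. Class-conditional generation
#' uses rejection on the parameter draw only, so the observation-noise model
#' is never altered.
#'
#' @param source An [prior_spec()] or [weighted_particles()] object.
#' @param target_class Optional response class (one of [response_classes]).
#' @param schedule A schedule list as from [standard_schedule()].
#' @param noise A [noise_params()] object (fixture default
#'   `(alpha1, alpha2) = (0.05, 0.10)`).
#' @param seed Optional integer seed; regeneration from the same seed is
#'   bit-identical.
#' @param patient_id Identifier.
#' @param thresholds Classification thresholds.
#' @param max_draws Rejection cap for class-conditional generation.
#' @param ... Passed to [simulate_gtv()].
#' @return An object of class `"rt_synth_patient"`: `theta` (true log-scale
#'   parameters), `params`, `schedule`, `noise_free` (data frame of
#'   noise-free measurements), `obs` (the noisy [observation_set()]),
#'   `class` (true response class), `noise`, `seed`.
#' @export
generate_patient <- function(source, target_class = NULL,
                             schedule = standard_schedule(),
                             noise = noise_params(0.05, 0.10), seed = NULL,
                             patient_id = "synth",
                             thresholds = classification_thresholds(),
                             max_draws = 1e6, ...) {
  if (!is.null(target_class))
    target_class <- match.arg(target_class, response_classes)
  if (!is.null(seed)) set.seed(seed)
  draw_theta <- function() {
    if (inherits(source, "rt_prior")) as.numeric(sample_prior(1, source))
    else source$theta[sample.int(nrow(source$theta), 1,
                                 prob = source$weights), ]
  }
  n_draw <- 0
  repeat {
    n_draw <- n_draw + 1
    if (n_draw > max_draws)
      stop("rejection cap exceeded: ",
           if (is.null(target_class)) "no draw could be classified"
           else paste0("class '", target_class,
                       "' appears unreachable from the source"),
           call. = FALSE)
    theta <- draw_theta()
    cls <- tryCatch(as.character(classify_params(theta, schedule,
                                                 thresholds, ...)),
                    error = function(e) NA_character_)
    if (is.na(cls)) next
    if (is.null(target_class) || cls == target_class) break
  }
  nf <- simulate_gtv(theta, schedule$dose_times, schedule$meas_times,
                     log_scale = TRUE, compartments = TRUE, ...)
  v_obs <- add_noise(nf$V, noise)
  obs <- observation_set(schedule$meas_times, v_obs, schedule$dose_times,
                         patient_id = patient_id)
  structure(list(theta = stats::setNames(as.numeric(theta), .theta_names),
                 params = params_from_log(theta), schedule = schedule,
                 noise_free = nf, obs = obs,
                 class = factor(cls, levels = response_classes),
                 noise = noise, seed = seed, n_draw = n_draw),
            class = "rt_synth_patient")
}

#' @export
print.rt_synth_patient <- function(x, ...) {
  cat(sprintf("Synthetic patient %s: true class %s, %d measurement(s)\n",
              x$obs$patient_id, as.character(x$class), length(x$obs$times)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @inheritParams generate_patient
#' @param n_patients Cohort size.
#' @param class_mix Optional named vector of target-class proportions (e.g.
#'   `c(fast_responder = 0.8, poor_responder = 0.2)`); patients are assigned
#'   target classes deterministically in proportion.
#' @param dir Optional directory: writes `patients.csv`, `schedules.csv` and
#'   a `manifest.json` recording seeds, noise parameters and true
#'   parameters/classes.
#' @return A list of `rt_synth_patient` objects (invisibly carries the
#'   manifest as an attribute).
#' @export
generate_cohort <- function(n_patients, source,
                            class_mix = NULL,
                            schedule = standard_schedule(),
                            noise = noise_params(0.05, 0.10), seed = NULL,
                            dir = NULL, ...) {
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 1, n_patients)
  targets <- rep(list(NULL), n_patients)
  if (!is.null(class_mix)) {
    counts <- round(class_mix / sum(class_mix) * n_patients)
    while (sum(counts) < n_patients) counts[1] <- counts[1] + 1
    while (sum(counts) > n_patients)
      counts[which.max(counts)] <- max(counts) - 1
    targets <- as.list(rep(names(counts), counts))[seq_len(n_patients)]
  }
  ids <- sprintf("synth%03d", seq_len(n_patients))
  cohort <- lapply(seq_len(n_patients), function(i)
    generate_patient(source, targets[[i]], schedule, noise, seeds[i],
                     ids[i], ...))
  names(cohort) <- ids
  if (!is.null(dir)) write_cohort(cohort, dir, seed = seed)
  cohort
}

#' Prior-predictive response-class probabilities
#'
#' Samples parameter vectors from a prior (or particle set), classifies each
#' by noise-free simulation under the standard schedule, and returns the
#' class proportions with binomial Monte Carlo standard errors. Under the
#' uninformative first-level box prior this gives the pre-data probability
#' that a patient shows an eventual response.
#'
#' @param prior An [prior_spec()] or [weighted_particles()] object.
#' @param n_samples Number of draws (>= 1000).
#' @param seed Optional integer seed.
#' @inheritParams classify_params
#' @return A classed list: `proportions` (named, over [response_classes]
#'   plus `eventual_response`), `se` (binomial Monte Carlo standard
#'   errors), `n` (draws actually classified).
#' @export
prior_predictive_class_probs <- function(prior, n_samples = 10000,
                                         seed = NULL,
                                         schedule = standard_schedule(),
                                         thresholds =
                                           classification_thresholds(),
                                         ...) {
  stopifnot(n_samples >= 1000)
  if (!is.null(seed)) set.seed(seed)
  theta <- if (inherits(prior, "rt_prior")) sample_prior(n_samples, prior)
           else prior$theta[sample.int(nrow(prior$theta), n_samples,
                                       replace = TRUE,
                                       prob = prior$weights), ,
                            drop = FALSE]
  labels <- classify_params(theta, schedule, thresholds, ...)
  ok <- !is.na(labels)
  n <- sum(ok)
  prop <- vapply(response_classes,
                 function(cl) mean(labels[ok] == cl), numeric(1))
  prop <- c(prop, eventual_response = unname(1 - prop["poor_responder"]))
  se <- sqrt(prop * (1 - prop) / n)
  structure(list(proportions = prop, se = se, n = n, seed = seed),
            class = "rt_class_probs")
}

#' @export
print.rt_class_probs <- function(x, ...) {
  cat(sprintf("Response-class probabilities (n = %d draws):\n", x$n))
  print(round(rbind(proportion = x$proportions, mc_se = x$se), 4))
  invisible(x)
}
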