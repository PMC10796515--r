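#' Fit the tumour-response model to a patient
#'
#' The central model-fitting interface. Two estimation routes are provided:
#' \describe{
#'   \item{`method = "mcmc"`}{Robust adaptive Metropolis sampling of the
#'     patient's posterior under the first-level box prior (the route used
#'     for training-set patients); see [sample_posterior_mcmc()].}
#'   \item{`method = "filter"`}{Bootstrap particle filtering of a
#'     pre-computed particle prior -- typically the second-level prior built
#'     from a training cohort -- reweighted by the patient's likelihood (the
#'     real-time route for new patients); see [particle_filter_update()].}
#' }
#' Both return a weighted particle representation of the posterior wrapped
#' in an object with the usual modelling methods (`print`, `summary`,
#' `coef`, `predict`, `simulate`, `residuals`, `plot`).
#'
#' @param obs An [observation_set()].
#' @param noise A [noise_params()] object (pre-estimated and fixed).
#' @param method `"mcmc"` or `"filter"`.
#' @param prior A [prior_spec()] (MCMC route).
#' @param particles An [weighted_particles()] prior (filter route).
#' @param seed Optional integer seed.
#' @param ... Further arguments to the chosen backend.
#' @return An object of class `"rt_fit"`.
#' @examples
#' sched <- standard_schedule()
#' pat <- generate_patient(prior_spec(), schedule = sched, seed = 7)
#' prior_particles <- weighted_particles(sample_prior(2000, seed = 1),
#'                                       provenance = "prior")
#' fit <- rt_fit(pat$obs, noise_params(0.05, 0.1), method = "filter",
#'               particles = prior_particles)
#' coef(fit)
#' predict(fit, type = "final_volume")
#' @export
rt_fit <- function(obs, noise, method = c("filter", "mcmc"),
                   prior = prior_spec(), particles = NULL, seed = NULL,
                   ...) {
  method <- match.arg(method)
  stopifnot(inherits(obs, "rt_obs"), inherits(noise, "rt_noise"))
  if (method == "mcmc") {
    post <- sample_posterior_mcmc(obs, prior, noise, seed = seed, ...)
    p <- weighted_particles(post$draws[, .theta_names, drop = FALSE],
                            provenance = "filtered",
                            patient_id = rep(obs$patient_id,
                                             nrow(post$draws)))
    diagnostics <- list(acceptance = post$acceptance, rhat = post$rhat)
  } else {
    if (is.null(particles))
      stop("method = 'filter' requires a 'particles' prior", call. = FALSE)
    p <- particle_filter_update(particles, obs, noise, ...)
    diagnostics <- list(ess = attr(p, "ess"))
  }
  structure(list(particles = p, obs = obs, noise = noise, method = method,
                 prior = prior, diagnostics = diagnostics, seed = seed),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("Tumour-response fit for patient %s (%s route)\n",
              x$obs$patient_id, x$method))
  cat(sprintf("  %d measurement(s), %d dose(s); %d particles, ESS %.1f\n",
              length(x$obs$times), length(x$obs$dose_times),
              nrow(x$particles$theta),
              effective_sample_size(x$particles$weights)))
  invisible(x)
}

# Posterior-sample fitted values at the observation times (rows = particles)
fitted_value_matrix <- function(object, max_particles = 500) {
  p <- object$particles
  n <- nrow(p$theta)
  idx <- if (n > max_particles)
    sample.int(n, max_particles, replace = TRUE, prob = p$weights)
  else seq_len(n)
  sim <- simulate_gtv(p$theta[idx, , drop = FALSE], object$obs$dose_times,
                      object$obs$times)
  w <- if (n > max_particles) rep(1 / length(idx), length(idx))
       else p$weights
  list(V = sim$V, weights = w, ok = sim$ok)
}

#' @export
summary.rt_fit <- function(object, ...) {
  p <- object$particles
  w <- p$weights
  qs <- c(0.025, 0.5, 0.975)
  tab <- t(apply(p$theta, 2, function(x)
    c(mean = weighted_mean(x, w), weighted_quantile(x, w, qs))))
  colnames(tab) <- c("mean", "q025", "median", "q975")
  r2 <- if (length(object$obs$times) >= 2) {
    fv <- fitted_value_matrix(object)
    keep <- fv$ok & apply(is.finite(fv$V), 1, all)
    suppressWarnings(
      bayesian_r2(fv$V[keep, , drop = FALSE], object$obs$v_obs))
  } else NA_real_
  out <- list(patient_id = object$obs$patient_id, method = object$method,
              theta = tab,
              ess = effective_sample_size(w),
              n_particles = nrow(p$theta),
              bayes_r2 = r2, diagnostics = object$diagnostics)
  class(out) <- "summary.rt_fit"
  out
}

#' @export
print.summary.rt_fit <- function(x, ...) {
  cat(sprintf("Posterior summary for patient %s (%s route)\n",
              x$patient_id, x$method))
  print(round(x$theta, 3))
  cat(sprintf("Particles: %d (ESS %.1f); median Bayesian R^2: %s\n",
              x$n_particles, x$ess,
              if (is.na(x$bayes_r2)) "NA" else sprintf("%.3f", x$bayes_r2)))
  invisible(x)
}

#' @export
coef.rt_fit <- function(object, natural = FALSE, ...) {
  m <- apply(object$particles$theta, 2, weighted_mean,
             w = object$particles$weights)
  if (natural) stats::setNames(exp(m), .param_names) else m
}

#' Predictions from a fitted patient model
#'
#' @param object An `rt_fit` object.
#' @param type `"trajectory"` (default), `"final_volume"`, or
#'   `"class_probs"`.
#' @param times Prediction times (trajectory type); defaults to a daily grid
#'   from 0 to the horizon.
#' @param horizon Final-volume prediction time in days; defaults to three
#'   days after the patient's final dose (day 56 for treatment ending on
#'   day 53).
#' @param noise Optional [noise_params()] for observation-level bands.
#' @param ... Passed on to the underlying prediction function.
#' @return See [predict_trajectory()], [predict_final_volume()],
#'   [predict_class_probs()].
#' @export
predict.rt_fit <- function(object, type = c("trajectory", "final_volume",
                                            "class_probs"),
                           times = NULL, horizon = NULL, noise = NULL,
                           ...) {
  type <- match.arg(type)
  if (is.null(horizon))
    horizon <- if (length(object$obs$dose_times))
      max(object$obs$dose_times) + 3 else max(object$obs$times, 0) + 3
  switch(type,
    trajectory = predict_trajectory(
      object$particles, object$obs$dose_times,
      if (is.null(times)) seq(0, horizon, by = 1) else times,
      noise = noise, ...),
    final_volume = predict_final_volume(object$particles,
                                        object$obs$dose_times, horizon,
                                        noise = noise, ...),
    class_probs = predict_class_probs(object$particles, ...))
}

#' @export
simulate.rt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$particles
  idx <- sample.int(nrow(p$theta), nsim, replace = TRUE, prob = p$weights)
  sim <- simulate_gtv(p$theta[idx, , drop = FALSE], object$obs$dose_times,
                      object$obs$times)
  out <- as.data.frame(t(apply(sim$V, 1, function(v)
    add_noise(v, object$noise))))
  names(out) <- paste0("t", object$obs$times)
  out
}

#' @export
residuals.rt_fit <- function(object, ...) {
  fv <- fitted_value_matrix(object)
  keep <- fv$ok & apply(is.finite(fv$V), 1, all)
  fit_mean <- as.numeric(crossprod(fv$weights[keep] / sum(fv$weights[keep]),
                                   fv$V[keep, , drop = FALSE]))
  object$obs$v_obs - fit_mean
}

#' @export
plot.rt_fit <- function(x, horizon = NULL, ...) {
  if (is.null(horizon))
    horizon <- if (length(x$obs$dose_times)) max(x$obs$dose_times) + 3
               else max(x$obs$times, 0) + 3
  tr <- predict.rt_fit(x, type = "trajectory", horizon = horizon)
  yl <- range(tr$q025, tr$q975, x$obs$v_obs)
  plot(tr$t, tr$mean, type = "n", ylim = yl, xlab = "time (days)",
       ylab = "GTV (fold change)", ...)
  graphics::polygon(c(tr$t, rev(tr$t)), c(tr$q025, rev(tr$q975)),
                    col = grDevices::adjustcolor("purple", 0.2),
                    border = NA)
  graphics::polygon(c(tr$t, rev(tr$t)), c(tr$q25, rev(tr$q75)),
                    col = grDevices::adjustcolor("purple", 0.4),
                    border = NA)
  graphics::lines(tr$t, tr$mean, lwd = 2, col = "purple4")
  graphics::points(x$obs$times, x$obs$v_obs, pch = 19)
  graphics::rug(x$obs$dose_times)
  invisible(tr)
}
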