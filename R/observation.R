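#' Observation-noise parameters
#'
#' CT measurements are modelled as Gaussian about the model volume with a
#' standard deviation linear in volume, `sd = alpha1 + alpha2 * V`: `alpha1`
#' is an absolute contribution (fold-change units) and `alpha2` a relative
#' one. The noise parameters are shared across patients and pre-estimated
#' once at the cohort level.
#'
#' @param alpha1,alpha2 Nonnegative; at least one must be positive.
#' @return An object of class `"rt_noise"`.
#' @export
noise_params <- function(alpha1, alpha2) {
  if (!is.finite(alpha1) || !is.finite(alpha2) || alpha1 < 0 || alpha2 < 0)
    stop("'alpha1' and 'alpha2' must be finite and >= 0", call. = FALSE)
  if (alpha1 == 0 && alpha2 == 0)
    stop("at least one of 'alpha1', 'alpha2' must be > 0", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2), class = "rt_noise")
}

#' @export
print.rt_noise <- function(x, ...) {
  cat(sprintf("Observation noise: sd(V) = %.4g + %.4g V\n",
              x$alpha1, x$alpha2))
  invisible(x)
}

#' @rdname noise_params
#' @param v Volume(s), >= 0.
#' @param noise An `rt_noise` object.
#' @return `noise_sd()`: the measurement standard deviation at each volume.
#' @export
noise_sd <- function(v, noise) {
  if (any(v < 0)) stop("volumes must be >= 0", call. = FALSE)
  noise$alpha1 + noise$alpha2 * v
}

#' A patient's observation record
#'
#' Bundles a patient's noisy GTV fold-change measurements (optionally with
#' necrotic-volume measurements) and their radiotherapy schedule: the unit
#' of inference.
#'
#' @param times Sorted measurement times in days (first at day 0).
#' @param v_obs GTV measurements as fold change of the first scan.
#' @param dose_times The patient's radiotherapy dose times (days).
#' @param n_obs Optional necrotic-volume fold-change measurements (`NA`
#'   where unavailable).
#' @param patient_id Identifier.
#' @param initial_cm3 Raw initial GTV in cm^3 (metadata; the model works in
#'   fold-change units).
#' @return An object of class `"rt_obs"`.
#' @export
observation_set <- function(times, v_obs, dose_times = numeric(0),
                            n_obs = NULL, patient_id = "patient",
                            initial_cm3 = NA_real_) {
  times <- as.numeric(times)
  v_obs <- as.numeric(v_obs)
  if (length(times) != length(v_obs))
    stop("'times' and 'v_obs' lengths differ", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted", call. = FALSE)
  if (length(v_obs) && !all(is.finite(v_obs)))
    stop("'v_obs' must be finite", call. = FALSE)
  if (!is.null(n_obs) && length(n_obs) != length(times))
    stop("'n_obs' length must match 'times'", call. = FALSE)
  structure(list(patient_id = patient_id, times = times, v_obs = v_obs,
                 n_obs = n_obs, dose_times = as.numeric(dose_times),
                 initial_cm3 = initial_cm3),
            class = "rt_obs")
}

#' @export
print.rt_obs <- function(x, ...) {
  cat(sprintf("Patient %s: %d measurement(s), %d dose(s)",
              x$patient_id, length(x$times), length(x$dose_times)),
      if (!is.null(x$n_obs)) "(GTV + necrosis)\n" else "\n")
  invisible(x)
}

#' Restrict an observation record to measurements up to a cutoff
#'
#' @param obs An `rt_obs` object.
#' @param upto_day Keep measurements with `time <= upto_day`; the full dose
#'   schedule is retained (it is part of the treatment plan, known ahead).
#' @return An `rt_obs` object.
#' @export
observations_upto <- function(obs, upto_day) {
  keep <- obs$times <= upto_day
  observation_set(obs$times[keep], obs$v_obs[keep], obs$dose_times,
                  if (!is.null(obs$n_obs)) obs$n_obs[keep],
                  obs$patient_id, obs$initial_cm3)
}

#' Gaussian log-likelihood of an observation record
#'
#' Sum over measurements of the Normal log density with mean equal to the
#' model volume at the measurement time and standard deviation
#' `alpha1 + alpha2 * V_model`. With necrosis measurements present, the
#' analogous independent Normal terms for `N` (with the same shared noise
#' parameters) are added. A failed simulation yields `-Inf` so the particle
#' receives zero weight.
#'
#' @param obs An [observation_set()].
#' @param params An [model_params()] object, log-theta vector, or matrix of
#'   log-theta rows (one log-likelihood per row).
#' @param noise A [noise_params()] object.
#' @param convention Dose convention, see [apply_dose()].
#' @param rtol,atol Integration tolerances.
#' @return Log-likelihood value(s).
#' @export
log_likelihood <- function(obs, params, noise,
                           convention = c("transfer", "exponential"),
                           rtol = 1e-8, atol = 1e-10) {
  convention <- match.arg(convention)
  theta <- if (is.matrix(params)) params
           else matrix(if (inherits(params, "rt_params"))
                         theta_log(params) else as.numeric(params),
                       nrow = 1)
  n_obs <- if (is.null(obs$n_obs)) numeric(0)
           else ifelse(is.na(obs$n_obs), NA_real_, obs$n_obs)
  ll <- .loglik_many_cpp(exp(theta), obs$dose_times, obs$times, obs$v_obs,
                         as.numeric(n_obs), noise$alpha1, noise$alpha2,
                         rtol, atol, convention == "exponential")
  if (!is.matrix(params)) ll[1] else ll
}

#' Add measurement noise to noise-free volumes
#'
#' Perturbs each volume by `Normal(0, (alpha1 + alpha2 * v)^2)`. Draws are
#' plain Normal (no truncation at zero), matching the statistical model as
#' written; negative synthetic volumes are possible and retained.
#'
#' @param measurements Noise-free volumes.
#' @param noise A [noise_params()] object.
#' @param seed Optional integer seed.
#' @return Noisy volumes.
#' @export
add_noise <- function(measurements, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  measurements + stats::rnorm(length(measurements),
                              sd = noise_sd(pmax(measurements, 0), noise))
}

#' Pre-estimate the noise parameters at the cohort level
#'
#' The noise parameters are shared across patients. They are pre-estimated
#' by running a joint 8-parameter MCMC (the six dynamical parameters plus
#' `alpha1`, `alpha2`) for each patient, pooling an equal number of
#' `(alpha1, alpha2)` posterior samples per patient, and taking the joint
#' marginal posterior mode via a 2-D Gaussian kernel density estimate
#' (Silverman bandwidths, 200 x 200 grid).
#'
#' @param cohort A list of [observation_set()] objects.
#' @param prior First-level [prior_spec()] for the dynamical parameters.
#' @param noise_upper Upper bound of the independent `U(0, noise_upper)`
#'   priors on `alpha1` and `alpha2`. Volumes are O(1) in fold-change units,
#'   so the default 0.5 spans all plausible noise levels.
#' @param iters,chains,thin_to Per-patient MCMC settings, see
#'   [sample_posterior_mcmc()].
#' @param seed Optional integer seed.
#' @param ... Passed to the sampler (e.g. `check_convergence`).
#' @return A [noise_params()] object; attributes `pooled` (the pooled
#'   `(alpha1, alpha2)` samples) and `seed` are attached.
#' @export
estimate_noise_params <- function(cohort, prior = prior_spec(),
                                  noise_upper = 0.5, iters = 25000,
                                  chains = 4, thin_to = 2500, seed = NULL,
                                  ...) {
  stopifnot(length(cohort) >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 1, length(cohort))
  pooled <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    fit <- sample_posterior_mcmc(cohort[[i]], prior, noise = NULL,
                                 iters = iters, chains = chains,
                                 thin_to = thin_to, seed = seeds[i],
                                 noise_upper = noise_upper, ...)
    pooled[[i]] <- fit$draws[, c("alpha1", "alpha2"), drop = FALSE]
  }
  ab <- do.call(rbind, pooled)
  mode <- kde2d_mode(ab[, 1], ab[, 2], lims = c(0, noise_upper))
  out <- noise_params(mode[1], mode[2])
  attr(out, "pooled") <- ab
  attr(out, "seed") <- seed
  out
}

# Joint marginal mode of (x, y) via a 2-D Gaussian KDE on a 200 x 200 grid,
# with Silverman (normal reference) bandwidths per dimension.
kde2d_mode <- function(x, y, n = 200, lims = NULL) {
  h <- 4 * c(stats::bw.nrd0(x), stats::bw.nrd0(y))  # kde2d kernel sd = h/4
  rng <- if (is.null(lims)) c(range(x), range(y))
         else c(max(lims[1], min(x) - h[1]), min(lims[2], max(x) + h[1]),
                max(lims[1], min(y) - h[2]), min(lims[2], max(y) + h[2]))
  kd <- MASS::kde2d(x, y, h = h, n = n, lims = rng)
  ij <- which(kd$z == max(kd$z), arr.ind = TRUE)[1, ]
  c(kd$x[ij[1]], kd$y[ij[2]])
}
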