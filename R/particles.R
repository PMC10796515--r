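#' Weighted particle sets
#'
#' The common representation for pooled posteriors, second-level priors and
#' filtered posteriors: a matrix of log-scale theta rows with normalised
#' weights.
#'
#' @param theta Matrix of log-scale parameter rows (6 columns).
#' @param weights Nonnegative weights, recycled/normalised to sum to 1;
#'   defaults to uniform.
#' @param provenance One of `"pooled_posterior"`, `"second_level_prior"`,
#'   `"filtered"`, `"prior"`.
#' @param patient_id Optional per-particle patient labels.
#' @return An object of class `"rt_particles"`.
#' @export
weighted_particles <- function(theta, weights = NULL,
                               provenance = c("pooled_posterior",
                                              "second_level_prior",
                                              "filtered", "prior"),
                               patient_id = NULL) {
  provenance <- match.arg(provenance)
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != 6) stop("'theta' must have 6 columns", call. = FALSE)
  if (nrow(theta) < 1) stop("particle count must be >= 1", call. = FALSE)
  colnames(theta) <- .theta_names
  if (is.null(weights)) weights <- rep(1 / nrow(theta), nrow(theta))
  if (length(weights) != nrow(theta))
    stop("'weights' length must match the particle count", call. = FALSE)
  if (any(weights < 0) || !all(is.finite(weights)))
    stop("weights must be finite and nonnegative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero", call. = FALSE)
  structure(list(theta = theta, weights = weights / s,
                 provenance = provenance, patient_id = patient_id),
            class = "rt_particles")
}

#' @export
print.rt_particles <- function(x, ...) {
  cat(sprintf("Weighted particle set (%s): %d particles, ESS %.1f\n",
              x$provenance, nrow(x$theta),
              effective_sample_size(x$weights)))
  invisible(x)
}

#' Effective sample size of normalised weights
#'
#' `1 / sum(w^2)`: equals the particle count for uniform weights and 1 when a
#' single particle carries all weight. Used as a degeneracy diagnostic for
#' the bootstrap particle filter.
#'
#' @param weights Normalised weights (or an `rt_particles` object).
#' @return A scalar in `[1, length(weights)]`.
#' @export
effective_sample_size <- function(weights) {
  if (inherits(weights, "rt_particles")) weights <- weights$weights
  1 / sum(weights^2)
}

#' Weighted quantiles via the left-continuous inverse CDF
#'
#' @param x Numeric values.
#' @param weights Nonnegative weights (normalised internally).
#' @param probs Probabilities.
#' @return `F^-(p) = inf{x : F(x) >= p}` for each probability.
#' @export
weighted_quantile <- function(x, weights, probs) {
  o <- order(x)
  x <- x[o]
  w <- weights[o] / sum(weights)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

#' Pool per-patient posteriors into the population-level posterior
#'
#' The full (population-level) posterior is a uniform mixture of the
#' individual patient posteriors; with equal per-patient sample counts it is
#' represented by simple concatenation with uniform weights.
#'
#' @param per_patient A list of [posterior_samples][sample_posterior_mcmc]
#'   objects (or plain draw matrices).
#' @return An `rt_particles` object with provenance `"pooled_posterior"` and
#'   per-particle patient labels.
#' @export
pool_posteriors <- function(per_patient) {
  stopifnot(length(per_patient) >= 1)
  draws <- lapply(per_patient, function(p)
    if (inherits(p, "rt_posterior")) p$draws else p)
  counts <- vapply(draws, nrow, integer(1))
  if (length(unique(counts)) != 1)
    stop("per-patient sample counts differ; thin to equal counts first",
         call. = FALSE)
  ids <- names(per_patient)
  if (is.null(ids)) ids <- as.character(seq_along(per_patient))
  weighted_particles(do.call(rbind, draws),
                     provenance = "pooled_posterior",
                     patient_id = rep(ids, each = counts[1]))
}

#' Silverman-rule kernel covariance with expansion factor
#'
#' The perturbation covariance used to expand the pooled posterior into the
#' second-level prior:
#' \deqn{\Sigma_\varepsilon = \beta \left(\frac{4}{m(d+2)}\right)^{1/(d+4)}
#'   \mathrm{diag}(\Sigma_\theta),}
#' with `d = 6` parameters, `m` samples and expansion factor `beta`
#' (default 2). `beta = 1` is Silverman's rule; larger values widen the
#' kernels to admit new patients not represented in the training set.
#'
#' @param particles An `rt_particles` object or a matrix of theta rows.
#' @param beta Expansion factor, >= 0.
#' @return A classed list with `Sigma_eps` (diagonal matrix), `beta`, `m`,
#'   `dim` and the scalar Silverman `factor`.
#' @export
silverman_covariance <- function(particles, beta = 2) {
  theta <- if (inherits(particles, "rt_particles")) particles$theta
           else particles
  m <- nrow(theta)
  if (m < 2) stop("need at least 2 samples", call. = FALSE)
  d <- ncol(theta)
  v <- apply(theta, 2, stats::var)
  if (any(v <= 0))
    stop("degenerate (zero-variance) parameter dimension", call. = FALSE)
  factor <- beta * (4 / (m * (d + 2)))^(1 / (d + 4))
  structure(list(Sigma_eps = diag(factor * v, d), beta = beta, m = m,
                 dim = d, factor = factor),
            class = "rt_kernel")
}

#' Build the second-level prior by truncated-kernel expansion
#'
#' Resamples base particles from the pooled posterior (respecting weights)
#' and perturbs each with a `N(0, Sigma_eps)` kernel, redrawing the
#' perturbation until it lands inside the first-level prior box. This is a
#' kernel density estimate with truncated multivariate normal kernels; the
#' output particles carry uniform weights.
#'
#' @param pooled An `rt_particles` pooled posterior.
#' @param expansion A [silverman_covariance()] object (built from `pooled`
#'   with `beta = 2` when omitted).
#' @param M Number of output particles (default 100000).
#' @param bounds The first-level [prior_spec()] box.
#' @param seed Optional integer seed.
#' @param max_tries Total redraw cap per lingering base particle.
#' @return An `rt_particles` object with provenance `"second_level_prior"`.
#' @export
build_second_level_prior <- function(pooled, expansion = NULL, M = 100000,
                                     bounds = prior_spec(), seed = NULL,
                                     max_tries = 1e6) {
  stopifnot(inherits(pooled, "rt_particles"))
  if (is.null(expansion)) expansion <- silverman_covariance(pooled, beta = 2)
  if (!is.null(seed)) set.seed(seed)
  sds <- sqrt(diag(expansion$Sigma_eps))
  idx <- sample.int(nrow(pooled$theta), M, replace = TRUE,
                    prob = pooled$weights)
  base <- pooled$theta[idx, , drop = FALSE]
  if (all(sds == 0)) {
    # beta = 0 degenerates to a plain bootstrap resample
    return(weighted_particles(base, provenance = "second_level_prior"))
  }
  out <- base + matrix(stats::rnorm(M * 6), ncol = 6) %*% diag(sds)
  todo <- which(!in_prior(out, bounds))
  tries <- 1
  while (length(todo) > 0) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("truncated-kernel acceptance too low for ", length(todo),
           " base particle(s)", call. = FALSE)
    prop <- base[todo, , drop = FALSE] +
      matrix(stats::rnorm(length(todo) * 6), ncol = 6) %*% diag(sds)
    ok <- in_prior(prop, bounds)
    out[todo[ok], ] <- prop[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  weighted_particles(out, provenance = "second_level_prior")
}

#' Bootstrap particle filter update
#'
#' Reweights prior particles by the patient's likelihood:
#' `w_j' proportional to w_j * p(D | theta_j)`. The parameters are static, so
#' incremental weekly updates recompute the weights from the complete
#' observation record; filtering all observations at once and filtering
#' incrementally give identical weights.
#'
#' @param prior_particles An `rt_particles` object.
#' @param obs An [observation_set()] (may contain zero on-treatment
#'   measurements, in which case the weights are unchanged).
#' @param noise A [noise_params()] object.
#' @param ... Passed to the likelihood (e.g. `convention`).
#' @return An `rt_particles` object with provenance `"filtered"`; its
#'   `ess` attribute records the post-update effective sample size.
#' @export
particle_filter_update <- function(prior_particles, obs, noise, ...) {
  stopifnot(inherits(prior_particles, "rt_particles"))
  if (length(obs$times) == 0) {
    out <- prior_particles
    out$provenance <- "filtered"
    attr(out, "ess") <- effective_sample_size(out$weights)
    return(out)
  }
  ll <- log_likelihood(obs, prior_particles$theta, noise, ...)
  lw <- log(prior_particles$weights) + ll
  m <- max(lw)
  if (!is.finite(m))
    stop("particle filter degeneracy: all weights are zero ",
         "(prior unrepresentative of the patient)", call. = FALSE)
  w <- exp(lw - m)
  out <- weighted_particles(prior_particles$theta, w,
                            provenance = "filtered",
                            patient_id = prior_particles$patient_id)
  attr(out, "ess") <- effective_sample_size(out$weights)
  out
}
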