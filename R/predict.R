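#' Predict the tumour trajectory from weighted particles
#'
#' Simulates every particle noise-free over the patient's schedule and
#' summarises the weighted distribution of the predicted volume at each
#' time: weighted mean plus 50% and 95% credible bands. With `noise`
#' supplied, observation-level bands are returned instead: quantiles of the
#' weighted mixture of `Normal(V_j, sd(V_j)^2)` predictive distributions,
#' obtained by numerical inversion of the mixture CDF.
#'
#' @param particles An [weighted_particles()] object (ESS must be >= 2).
#' @param dose_times Dose schedule (days).
#' @param times Prediction times (days).
#' @param noise Optional [noise_params()] for observation-level bands.
#' @param compartment `"V"` (default) or `"N"` to summarise the necrotic
#'   volume instead.
#' @param ... Passed to [simulate_gtv()].
#' @return A data frame with columns `t`, `mean`, `q025`, `q25`, `q75`,
#'   `q975`. Particles whose simulation fails are dropped (with a warning)
#'   and the weights renormalised; the dropped count is recorded in the
#'   `dropped` attribute.
#' @export
predict_trajectory <- function(particles, dose_times, times, noise = NULL,
                               compartment = c("V", "N"), ...) {
  stopifnot(inherits(particles, "rt_particles"))
  compartment <- match.arg(compartment)
  if (effective_sample_size(particles$weights) < 2)
    warning("nearly degenerate particle set (ESS < 2); ",
            "bands may collapse to a point mass")
  sim <- simulate_gtv(particles$theta, dose_times, times,
                      compartments = compartment == "N", ...)
  X <- if (compartment == "N") sim$N else sim$V
  w <- particles$weights
  bad <- !sim$ok | !apply(is.finite(X), 1, all)
  if (any(bad)) {
    warning(sum(bad), " particle simulation(s) failed; dropped")
    X <- X[!bad, , drop = FALSE]
    w <- w[!bad] / sum(w[!bad])
  }
  qs <- c(0.025, 0.25, 0.75, 0.975)
  out <- data.frame(t = as.numeric(times))
  out$mean <- as.numeric(crossprod(w, X))
  qmat <- if (is.null(noise)) {
    vapply(seq_along(times), function(i)
      weighted_quantile(X[, i], w, qs), numeric(4))
  } else {
    vapply(seq_along(times), function(i)
      mixture_normal_quantile(X[, i], noise_sd(pmax(X[, i], 0), noise), w,
                              qs), numeric(4))
  }
  out$q025 <- qmat[1, ]; out$q25 <- qmat[2, ]
  out$q75 <- qmat[3, ]; out$q975 <- qmat[4, ]
  attr(out, "dropped") <- sum(bad)
  out
}

# Quantiles of sum_j w_j Normal(mu_j, sd_j^2) by bisection on the CDF.
mixture_normal_quantile <- function(mu, sd, w, probs) {
  lo <- min(mu - 6 * sd)
  hi <- max(mu + 6 * sd)
  vapply(probs, function(p) {
    stats::uniroot(function(x) sum(w * stats::pnorm(x, mu, sd)) - p,
                   c(lo, hi), tol = 1e-9)$root
  }, numeric(1))
}

#' Predict the final tumour volume
#'
#' Weighted mean and 50%/95% credible intervals of the noise-free
#' fold-change volume at the prediction horizon (default day 56, the
#' end-of-treatment reporting time).
#'
#' @inheritParams predict_trajectory
#' @param horizon Prediction time in days.
#' @return A one-row data frame (`t`, `mean`, `q025`, `q25`, `q75`, `q975`).
#' @export
predict_final_volume <- function(particles, dose_times, horizon = 56, ...) {
  predict_trajectory(particles, dose_times, horizon, ...)
}

#' Predict response-class probabilities
#'
#' Weighted class proportions of the particle set under the standard
#' schedule; before any data arrive this reproduces the prior's class
#' proportions.
#'
#' @inheritParams class_proportions
#' @return As [class_proportions()].
#' @export
predict_class_probs <- function(particles, schedule = standard_schedule(),
                                thresholds = classification_thresholds(),
                                ...) {
  class_proportions(particles, schedule, thresholds, ...)
}

#' Bayesian R-squared
#'
#' For each posterior sample, `R^2 = Var(V_fit) / (Var(V_fit) +
#' Var(V_fit - V_obs))` with sample (n-1) variances; the median over samples
#' is reported. An R-squared of 1 means zero residual variance; 0 means all
#' fitted values lie on a horizontal line (expected for poor responders).
#'
#' @param fitted A matrix of fitted values (rows = posterior samples,
#'   columns = observation times), or a single vector of fitted values.
#' @param observed Observed values (length = number of columns).
#' @return The median R-squared across samples, in `[0, 1]`.
#' @export
bayesian_r2 <- function(fitted, observed) {
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  if (ncol(fitted) != length(observed))
    stop("'fitted' columns must match 'observed' length", call. = FALSE)
  if (length(observed) < 2)
    stop("at least 2 observations are required", call. = FALSE)
  r2 <- apply(fitted, 1, function(f) {
    vf <- stats::var(f)
    vr <- stats::var(f - observed)
    if (vf == 0 && vr == 0) {
      warning("constant fit with zero residual variance; R^2 defined as 0")
      return(0)
    }
    vf / (vf + vr)
  })
  stats::median(r2)
}

#' Welch's unequal-variance t-test from summary statistics
#'
#' Two-sided Welch test computed from per-group mean, standard deviation and
#' count. Fractional counts are permitted (class counts from probabilistic
#' classification are non-integer) and the Welch-Satterthwaite degrees of
#' freedom are used without rounding: the t CDF accepts fractional df (via
#' the regularised incomplete beta function).
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`sd1 > 0`, `n1 > 1`).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A list with `statistic` (t), `df` (fractional), and `p.value`
#'   (two-sided).
#' @examples
#' welch_summary_test(16.8, 11.6, 35.0, 20.2, 7.3, 2.4)$p.value
#' @export
welch_summary_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (min(sd1, sd2) <= 0) stop("standard deviations must be > 0",
                               call. = FALSE)
  if (min(n1, n2) <= 1) stop("counts must exceed 1", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p.value = p)
}

#' Per-class initial-volume statistics under probabilistic classification
#'
#' Each patient contributes to each class with its class probability, so
#' class counts are fractional: `count_c = sum_i p_ic`, the class mean is
#' the probability-weighted mean of the initial volumes, and the spread is
#' the probability-weighted standard deviation.
#'
#' @param class_probs Matrix of per-patient class probabilities (rows =
#'   patients, columns named by [response_classes]); rows must sum to 1.
#' @param initial_volumes_cm3 Per-patient initial GTV in cm^3.
#' @return A data frame with one row per class: `count`, `mean`, `sd`
#'   (`NA` where the fractional count vanishes).
#' @export
class_volume_stats <- function(class_probs, initial_volumes_cm3) {
  if (is.null(dim(class_probs))) class_probs <- matrix(class_probs, nrow = 1)
  if (nrow(class_probs) != length(initial_volumes_cm3))
    stop("one initial volume per patient is required", call. = FALSE)
  if (any(abs(rowSums(class_probs) - 1) > 1e-8))
    stop("per-patient class probabilities must sum to 1", call. = FALSE)
  cls <- colnames(class_probs)
  if (is.null(cls)) cls <- response_classes[seq_len(ncol(class_probs))]
  v <- initial_volumes_cm3
  out <- data.frame(class = cls, count = NA_real_, mean = NA_real_,
                    sd = NA_real_)
  for (k in seq_along(cls)) {
    p <- class_probs[, k]
    cnt <- sum(p)
    out$count[k] <- cnt
    if (cnt > 0) {
      m <- sum(p * v) / cnt
      out$mean[k] <- m
      # weighted sd with fractional-count (n-1)-style correction
      denom <- cnt - 1
      out$sd[k] <- if (denom > 0) sqrt(sum(p * (v - m)^2) / denom)
                   else NA_real_
    }
  }
  out
}
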