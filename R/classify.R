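#' Response-classification thresholds
#'
#' The four response classes are defined by threshold criteria on a
#' noise-free measurement series normalised to the start-of-treatment
#' volume:
#' \itemize{
#'   \item poor responder: all measurements above `responder_floor` (85%);
#'   \item pseudo-progressor: a responder whose second post-onset measurement
#'     exceeds `pseudo_rise` (102%) times the first;
#'   \item plateaued: a responder, not pseudo-progressing, with final
#'     measurement above `plateau_final_floor` (20%) and final
#'     rate-of-change below `plateau_rate_frac` (10%) of the maximum
#'     rate-of-change;
#'   \item fast responder: any remaining responder.
#' }
#' Rates of change are successive finite differences of the measurement
#' series divided by the time gaps. The thresholds are configurable because
#' they were calibrated on a small cohort and may need revisiting.
#'
#' @param responder_floor,pseudo_rise,plateau_final_floor,plateau_rate_frac
#'   Dimensionless fractions; see above.
#' @return A classed list of thresholds.
#' @export
classification_thresholds <- function(responder_floor = 0.85,
                                      pseudo_rise = 1.02,
                                      plateau_final_floor = 0.20,
                                      plateau_rate_frac = 0.10) {
  x <- list(responder_floor = responder_floor, pseudo_rise = pseudo_rise,
            plateau_final_floor = plateau_final_floor,
            plateau_rate_frac = plateau_rate_frac)
  if (!all(vapply(x, function(v) is.finite(v) && v > 0, logical(1))))
    stop("all thresholds must be finite and positive", call. = FALSE)
  if (!(x$responder_floor < 1 && x$pseudo_rise > 1))
    stop("need responder_floor < 1 < pseudo_rise", call. = FALSE)
  structure(x, class = "rt_thresholds")
}

#' @rdname classification_thresholds
#' @format NULL
#' @export
response_classes <- c("fast_responder", "poor_responder", "plateaued",
                      "pseudo_progressor")

#' Classify a noise-free measurement series
#'
#' @param volumes Noise-free volumes at the classification measurement
#'   times, normalised so the start-of-treatment measurement is 1. The
#'   pre-treatment planning scan must already be excluded.
#' @param times Measurement times in days (same length as `volumes`).
#'   Defaults to weekly spacing, which only matters for the plateau
#'   rate-of-change criterion.
#' @param thresholds A [classification_thresholds()] object.
#' @return A factor of length 1 with levels [response_classes], carrying an
#'   attribute `eventual_response` (`TRUE` unless poor responder).
#' @examples
#' classify_series(c(1, .8, .6, .45, .42, .41, .405))  # plateaued
#' @export
classify_series <- function(volumes,
                            times = 7 * (seq_along(volumes) - 1),
                            thresholds = classification_thresholds()) {
  n <- length(volumes)
  if (n < 3)
    stop("at least 3 classification measurements are required", call. = FALSE)
  if (length(times) != n)
    stop("'times' and 'volumes' lengths differ", call. = FALSE)
  if (abs(volumes[1] - 1) > 1e-6)
    warning("series does not appear normalised to the start-of-treatment ",
            "measurement (first value != 1)")
  th <- thresholds
  label <- if (all(volumes > th$responder_floor)) {
    "poor_responder"
  } else if (volumes[2] > th$pseudo_rise * volumes[1]) {
    "pseudo_progressor"
  } else {
    rates <- diff(volumes) / diff(times)
    final_rate <- abs(rates[length(rates)])
    if (volumes[n] > th$plateau_final_floor &&
        final_rate < th$plateau_rate_frac * max(abs(rates)))
      "plateaued"
    else
      "fast_responder"
  }
  out <- factor(label, levels = response_classes)
  attr(out, "eventual_response") <- label != "poor_responder"
  out
}

#' Classify a parameter vector by noise-free simulation
#'
#' Simulates the model noise-free under the given schedule, normalises the
#' classification measurements to the start-of-treatment volume, and applies
#' [classify_series()]. A matrix of log-scale theta rows is classified in
#' batch.
#'
#' @param params An [model_params()] object, log-theta vector, or matrix of
#'   log-theta rows.
#' @param schedule A schedule list as from [standard_schedule()].
#' @param thresholds A [classification_thresholds()] object.
#' @param ... Passed to [simulate_gtv()] (e.g. `convention`).
#' @return For a single parameter set, as [classify_series()]; for a matrix,
#'   a factor vector with one label per row (`NA` for failed simulations).
#' @export
classify_params <- function(params, schedule = standard_schedule(),
                            thresholds = classification_thresholds(), ...) {
  ct <- schedule$meas_times[schedule$classify]
  if (is.matrix(params)) {
    sim <- simulate_gtv(params, schedule$dose_times, ct, ...)
    V <- sim$V / sim$V[, 1]
    labs <- rep(NA_character_, nrow(V))
    for (j in seq_len(nrow(V))) {
      if (!sim$ok[j] || !all(is.finite(V[j, ]))) next
      labs[j] <- as.character(classify_series(V[j, ], ct, thresholds))
    }
    return(factor(labs, levels = response_classes))
  }
  th <- if (inherits(params, "rt_params")) theta_log(params)
        else as.numeric(params)
  sim <- simulate_gtv(th, schedule$dose_times, ct, log_scale = TRUE, ...)
  classify_series(sim$V / sim$V[1], ct, thresholds)
}

#' Weighted class proportions of a particle set
#'
#' Classifies every particle noise-free under the schedule and returns the
#' weight-summed proportion of each response class, together with the
#' eventual-response proportion (1 minus the poor-responder proportion).
#'
#' @param particles A [weighted_particles()] object.
#' @param schedule,thresholds,... As in [classify_params()].
#' @param labels Optional precomputed factor of per-particle labels (skips
#'   re-simulation).
#' @return A named numeric vector over [response_classes] plus
#'   `eventual_response`; failed simulations are dropped with a warning and
#'   weights renormalised.
#' @export
class_proportions <- function(particles, schedule = standard_schedule(),
                              thresholds = classification_thresholds(),
                              labels = NULL, ...) {
  stopifnot(inherits(particles, "rt_particles"))
  if (nrow(particles$theta) == 0) stop("empty particle set", call. = FALSE)
  if (is.null(labels))
    labels <- classify_params(particles$theta, schedule, thresholds, ...)
  w <- particles$weights
  bad <- is.na(labels)
  if (any(bad)) {
    warning(sum(bad), " particle(s) failed to simulate; dropped")
    w <- w[!bad] / sum(w[!bad])
    labels <- labels[!bad]
  }
  prop <- vapply(response_classes,
                 function(cl) sum(w[labels == cl]), numeric(1))
  c(prop, eventual_response = unname(1 - prop["poor_responder"]))
}
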