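#' Sample a patient's posterior by robust adaptive Metropolis
#'
#' Random-walk Metropolis in log-theta space with Vihola-style robust
#' adaptive scaling: the proposal's Cholesky factor is updated after every
#' iteration by a rank-one correction so the empirical acceptance rate
#' approaches the target (0.234). Chains start at independent draws from the
#' box prior; proposals outside the box have zero prior density and are
#' rejected. The first half of each chain is discarded as burn-in and the
#' remainder thinned to `thin_to` pooled draws.
#'
#' With `noise = NULL` the sampler runs jointly over the six dynamical
#' parameters and the noise parameters `(alpha1, alpha2)` under independent
#' `U(0, noise_upper)` priors (used for cohort-level noise pre-estimation).
#'
#' @param obs An [observation_set()]. Zero measurements are allowed, in
#'   which case the posterior is the prior.
#' @param prior First-level [prior_spec()].
#' @param noise A fixed [noise_params()] object, or `NULL` to infer the
#'   noise parameters jointly.
#' @param iters Iterations per chain (default 25000).
#' @param chains Number of chains (default 4).
#' @param thin_to Total pooled post-burn-in draws to keep (default 2500).
#' @param seed Optional integer seed.
#' @param noise_upper Upper bound for the noise-parameter priors when
#'   `noise = NULL`.
#' @param target_accept Target acceptance rate of the robust adaptation.
#' @param rhat_max Split-R-hat threshold for the convergence check.
#' @param check_convergence `"warn"` (default), `"error"`, or `"none"`.
#' @param convention Dose convention, see [apply_dose()].
#' @return An object of class `"rt_posterior"`: `draws` (matrix of log-theta
#'   rows, plus `alpha1`, `alpha2` columns in joint mode), `acceptance`,
#'   `rhat`, `ess`, `patient_id`, `seed`.
#' @export
sample_posterior_mcmc <- function(obs, prior = prior_spec(), noise,
                                  iters = 25000, chains = 4, thin_to = 2500,
                                  seed = NULL, noise_upper = 0.5,
                                  target_accept = 0.234, rhat_max = 1.05,
                                  check_convergence = c("warn", "error",
                                                        "none"),
                                  convention = c("transfer", "exponential")) {
  check_convergence <- match.arg(check_convergence)
  convention <- match.arg(convention)
  joint <- is.null(noise)
  d <- if (joint) 8L else 6L
  if (!is.null(seed)) set.seed(seed)
  has_data <- length(obs$times) > 0

  logpost <- function(x) {
    theta <- x[1:6]
    if (!all(theta >= prior$lower & theta <= prior$upper)) return(-Inf)
    if (joint) {
      a <- x[7:8]
      if (any(a <= 0) || any(a >= noise_upper)) return(-Inf)
      ns <- list(alpha1 = a[1], alpha2 = a[2])
    } else ns <- noise
    if (!has_data) return(0)
    log_likelihood(obs, theta, ns, convention = convention)
  }

  burn <- floor(iters / 2)
  keep_per <- max(1L, ceiling(thin_to / chains))
  keep_idx <- unique(round(seq(burn + 1, iters, length.out = keep_per)))
  all_draws <- vector("list", chains)
  acc_rates <- numeric(chains)

  for (ch in seq_len(chains)) {
    x <- as.numeric(sample_prior(1, prior))
    if (joint) x <- c(x, stats::runif(2, 0, noise_upper))
    lp <- logpost(x)
    # conservative initial proposal scale: a tenth of each box width
    widths <- c(prior$upper - prior$lower, if (joint) rep(noise_upper, 2))
    S <- diag(widths / 10, d)
    out <- matrix(NA_real_, length(keep_idx), d)
    n_acc <- 0L
    ki <- 1L
    for (n in seq_len(iters)) {
      u <- stats::rnorm(d)
      xp <- x + as.numeric(S %*% u)
      lpp <- logpost(xp)
      alpha <- if (lpp == -Inf) 0 else min(1, exp(lpp - lp))
      if (stats::runif(1) < alpha) {
        x <- xp
        lp <- lpp
        n_acc <- n_acc + 1L
      }
      # robust adaptive rank-one update of the proposal factor
      eta <- min(1, d / n^(2 / 3))
      uu <- tcrossprod(u) / sum(u^2)
      M <- S %*% (diag(d) + eta * (alpha - target_accept) * uu) %*% t(S)
      S <- t(chol(M))
      if (ki <= length(keep_idx) && n == keep_idx[ki]) {
        out[ki, ] <- x
        ki <- ki + 1L
      }
    }
    acc_rates[ch] <- n_acc / iters
    all_draws[[ch]] <- out
  }

  if (all(acc_rates == 0))
    stop("MCMC failure: no proposals accepted in any chain", call. = FALSE)

  rhat <- vapply(seq_len(d), function(k)
    split_rhat(lapply(all_draws, function(m) m[, k])), numeric(1))
  draws <- do.call(rbind, all_draws)
  cn <- c(.theta_names, if (joint) c("alpha1", "alpha2"))
  colnames(draws) <- cn
  names(rhat) <- cn
  ess <- nrow(draws) / 2  # crude: thinned draws are near-independent
  if (check_convergence != "none" && any(rhat > rhat_max, na.rm = TRUE)) {
    msg <- paste0("split-R-hat above ", rhat_max, " for: ",
                  paste(cn[which(rhat > rhat_max)], collapse = ", "),
                  " (max ", round(max(rhat, na.rm = TRUE), 3), ")")
    if (check_convergence == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  structure(list(draws = draws, acceptance = acc_rates, rhat = rhat,
                 ess = ess, patient_id = obs$patient_id, seed = seed,
                 chains = chains, iters = iters),
            class = "rt_posterior")
}

#' @export
print.rt_posterior <- function(x, ...) {
  cat(sprintf(
    "Posterior for patient %s: %d draws (%d chains x %d iters), ",
    x$patient_id, nrow(x$draws), x$chains, x$iters))
  cat(sprintf("mean acceptance %.2f, max split-R-hat %.3f\n",
              mean(x$acceptance), max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

# Split-R-hat across chains: each chain is halved, then the standard
# between/within variance ratio is computed over the 2 * chains sequences.
split_rhat <- function(chain_list) {
  halves <- list()
  for (x in chain_list) {
    n <- length(x)
    if (n < 4) return(NA_real_)
    h <- floor(n / 2)
    halves <- c(halves, list(x[1:h], x[(n - h + 1):n]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}
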