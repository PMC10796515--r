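#' Patient-specific model parameters
#'
#' Bundles the six dynamical parameters of the two-compartment tumour model.
#' Volumes are expressed as fold change (FC) relative to the initial gross
#' tumour volume (GTV), so `K` is a fold-change carrying capacity and the
#' initial state is `V(0) = 1`.
#'
#' @param lambda Cell proliferation rate (per day), > 0.
#' @param K Carrying capacity (fold change relative to initial GTV), > 0.
#' @param gamma Radiotherapy response strength: the fraction of living volume
#'   transferred to the necrotic compartment at each dose, in (0, 1).
#' @param zeta Necrotic debris decay rate (per day), > 0.
#' @param eta Cell necrosis rate (per day), > 0.
#' @param phi0 Initial necrotic proportion of the tumour, in (0, 1).
#'
#' @return An object of class `"rt_params"`: a named numeric vector of the six
#'   natural-scale parameters.
#' @seealso [theta_log()], [params_from_log()], [simulate_gtv()]
#' @examples
#' p <- model_params(lambda = 0.07, K = 2, gamma = 0.05, zeta = 0.2,
#'                   eta = 0.01, phi0 = 0.2)
#' all.equal(params_from_log(theta_log(p)), p)
#' @export
model_params <- function(lambda, K, gamma, zeta, eta, phi0) {
  x <- c(lambda = lambda, K = K, gamma = gamma, zeta = zeta, eta = eta,
         phi0 = phi0)
  if (!all(is.finite(x)))
    stop("all parameters must be finite", call. = FALSE)
  if (any(x <= 0))
    stop("all parameters must be strictly positive", call. = FALSE)
  if (gamma >= 1)
    stop("'gamma' must be < 1 (a per-dose fraction)", call. = FALSE)
  if (phi0 >= 1)
    stop("'phi0' must be < 1 (a proportion)", call. = FALSE)
  structure(x, class = "rt_params")
}

#' @rdname model_params
#' @param params An `rt_params` object (or named vector in the same order).
#' @return `theta_log()`: the log-scale parameter vector
#'   \eqn{\theta = (\log\lambda, \log K, \log\gamma, \log\zeta, \log\eta,
#'   \log\phi_0)} used throughout inference.
#' @export
theta_log <- function(params) {
  stats::setNames(log(as.numeric(params)[1:6]), .theta_names)
}

#' @rdname model_params
#' @param theta A numeric vector of length 6 on the log scale.
#' @export
params_from_log <- function(theta) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == 6)
  x <- exp(theta)
  model_params(x[1], x[2], x[3], x[4], x[5], x[6])
}

.theta_names <- c("log_lambda", "log_K", "log_gamma", "log_zeta", "log_eta",
                  "log_phi0")
.param_names <- c("lambda", "K", "gamma", "zeta", "eta", "phi0")

#' @export
print.rt_params <- function(x, ...) {
  cat("Two-compartment tumour model parameters:\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' First-level box prior on the log-scale parameters
#'
#' Independent uniform distributions on each component of
#' \eqn{\theta = (\log\lambda, \log K, \log\gamma, \log\zeta, \log\eta,
#' \log\phi_0)}. The defaults are the uninformative bounds used to calibrate
#' training-set patients: \eqn{\log\lambda \sim U(-10, 0)},
#' \eqn{\log K \sim U(0, 5)}, \eqn{\log\gamma \sim U(-10, 0)},
#' \eqn{\log\zeta \sim U(-10, 3)}, \eqn{\log\eta \sim U(-10, 3)},
#' \eqn{\log\phi_0 \sim U(-5, 0)}.
#'
#' @param lower,upper Numeric length-6 vectors of log-space bounds, in the
#'   order lambda, K, gamma, zeta, eta, phi0.
#' @return An object of class `"rt_prior"` with elements `lower` and `upper`.
#' @examples
#' pr <- prior_spec()
#' th <- sample_prior(5, pr, seed = 1)
#' all(in_prior(th, pr))
#' @export
prior_spec <- function(lower = c(-10, 0, -10, -10, -10, -5),
                       upper = c(0, 5, 0, 3, 3, 0)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == 6, length(upper) == 6)
  if (!all(lower < upper))
    stop("prior bounds must satisfy lower < upper in every dimension",
         call. = FALSE)
  structure(list(lower = stats::setNames(lower, .theta_names),
                 upper = stats::setNames(upper, .theta_names)),
            class = "rt_prior")
}

#' @export
print.rt_prior <- function(x, ...) {
  cat("Independent log-uniform box prior:\n")
  print(data.frame(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' @rdname prior_spec
#' @param n Number of draws.
#' @param prior An `rt_prior` object.
#' @param seed Optional integer seed.
#' @return `sample_prior()`: an `n` x 6 matrix of log-scale draws.
#' @export
sample_prior <- function(n, prior = prior_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(n * 6), nrow = n)
  m <- sweep(m, 2, prior$upper - prior$lower, `*`)
  m <- sweep(m, 2, prior$lower, `+`)
  colnames(m) <- .theta_names
  m
}

#' @rdname prior_spec
#' @param theta A log-scale vector, or a matrix with one row per vector.
#' @return `in_prior()`: logical, whether each vector lies inside the box.
#' @export
in_prior <- function(theta, prior = prior_spec()) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  ok <- rep(TRUE, nrow(theta))
  for (k in 1:6)
    ok <- ok & theta[, k] >= prior$lower[k] & theta[, k] <= prior$upper[k]
  ok
}

# log density of the box prior (unnormalised would do; use the proper one)
log_prior_density <- function(theta, prior) {
  if (all(theta >= prior$lower & theta <= prior$upper))
    -sum(log(prior$upper - prior$lower))
  else
    -Inf
}
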