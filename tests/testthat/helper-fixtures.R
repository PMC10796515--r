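# Shared fixtures: small parameter sets and synthetic records built in code.

fx_params <- function() {
  # a clearly responsive patient: moderate growth, strong per-dose kill,
  # fast necrotic clearance
  model_params(lambda = 0.05, K = 2, gamma = 0.15, zeta = 0.3,
               eta = 0.01, phi0 = 0.2)
}

fx_poor_params <- function() {
  # negligible radiotherapy effect and necrosis: tumour keeps growing
  model_params(lambda = 0.05, K = 3, gamma = 1e-4, zeta = 1e-4,
               eta = 1e-4, phi0 = 0.05)
}

fx_noise <- function() noise_params(0.05, 0.10)

# a prior box concentrated on strongly responding parameters
fx_responder_prior <- function() {
  prior_spec(lower = c(log(0.01), log(1.2), log(0.1), log(0.1),
                       log(0.005), log(0.05)),
             upper = c(log(0.1), log(3), log(0.6), log(1),
                       log(0.05), log(0.4)))
}

hpd_interval <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, floor(level * n))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}
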