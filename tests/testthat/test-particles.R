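# Particle containers, pooling, kernel expansion and the bootstrap filter.

test_that("particle sets validate weights and normalise them", {
  th <- sample_prior(10, prior_spec(), seed = 2)
  p <- weighted_particles(th, weights = rep(2, 10), provenance = "prior")
  expect_equal(sum(p$weights), 1, tolerance = 1e-12)
  expect_error(weighted_particles(th, weights = rep(-1, 10)),
               "nonnegative")
  expect_error(weighted_particles(th[, 1:5]), "6 columns")
})

test_that("effective sample size has its closed-form values", {
  expect_equal(effective_sample_size(rep(1 / 100, 100)), 100)
  expect_equal(effective_sample_size(c(1, rep(0, 9))), 1)
  expect_equal(effective_sample_size(c(0.75, 0.25)), 1.6)
})

test_that("weighted quantiles invert the left-continuous weighted ECDF", {
  set.seed(3)
  x <- rnorm(10)
  w <- runif(10); w <- w / sum(w)
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  got <- weighted_quantile(x, w, qs)
  # brute force: scan the sorted support for the first crossing
  o <- order(x); xs <- x[o]; cw <- cumsum(w[o])
  want <- vapply(qs, function(p) xs[min(which(cw >= p - 1e-12))],
                 numeric(1))
  expect_equal(got, want)
})

test_that("pooling concatenates equal-count posteriors with uniform weights", {
  d1 <- sample_prior(50, prior_spec(), seed = 4)
  d2 <- sample_prior(50, prior_spec(), seed = 5)
  pooled <- pool_posteriors(list(a = d1, b = d2))
  expect_equal(nrow(pooled$theta), 100)
  expect_equal(pooled$weights, rep(1 / 100, 100))
  expect_equal(pooled$patient_id, rep(c("a", "b"), each = 50))
  # mixture mean is the average of per-patient means
  expect_equal(colMeans(pooled$theta), (colMeans(d1) + colMeans(d2)) / 2)
  one <- pool_posteriors(list(only = d1))
  expect_equal(one$theta, d1, ignore_attr = TRUE)
  expect_error(pool_posteriors(list(d1, d2[1:10, ])), "thin")
})

test_that("the expanded Silverman covariance follows the dimensional formula", {
  set.seed(6)
  th <- matrix(rnorm(6000), ncol = 6)
  colnames(th) <- colnames(sample_prior(1, prior_spec()))
  k <- silverman_covariance(th, beta = 2)
  expect_equal(k$factor, 2 * (4 / (1000 * 8))^(1 / 10), tolerance = 1e-12)
  expect_equal(k$factor, 0.93524, tolerance = 1e-4)
  expect_equal(diag(k$Sigma_eps), k$factor * apply(th, 2, var),
               ignore_attr = TRUE)
  expect_equal(silverman_covariance(th, beta = 0)$factor, 0)
  # scaling every sample by 2 quadruples the kernel covariance
  k2 <- silverman_covariance(2 * th, beta = 2)
  expect_equal(diag(k2$Sigma_eps), 4 * diag(k$Sigma_eps))
  expect_error(silverman_covariance(cbind(th[, 1:5], 1)), "degenerate")
})

test_that("the second-level prior lives inside the box and degenerates to a bootstrap at beta 0", {
  set.seed(8)
  pr <- prior_spec()
  pooled <- weighted_particles(sample_prior(400, pr),
                               provenance = "pooled_posterior")
  p2 <- build_second_level_prior(pooled, M = 3000, bounds = pr, seed = 9)
  expect_equal(nrow(p2$theta), 3000)
  expect_true(all(in_prior(p2$theta, pr)))
  expect_equal(p2$weights, rep(1 / 3000, 3000))
  boot <- build_second_level_prior(pooled,
                                   silverman_covariance(pooled, beta = 0),
                                   M = 500, bounds = pr, seed = 10)
  in_pool <- apply(boot$theta, 1, function(r)
    any(colSums(abs(t(pooled$theta) - r)) < 1e-12))
  expect_true(all(in_pool))
})

test_that("pre-truncation kernel expansion adds the kernel variance", {
  # base cloud tight in the box interior: truncation never triggers
  set.seed(12)
  centre <- (prior_spec()$lower + prior_spec()$upper) / 2
  th <- sweep(matrix(rnorm(2000 * 6, 0, 0.05), ncol = 6), 2, centre, `+`)
  colnames(th) <- names(centre)
  pooled <- weighted_particles(th, provenance = "pooled_posterior")
  k <- silverman_covariance(pooled, beta = 2)
  p2 <- build_second_level_prior(pooled, k, M = 40000, seed = 13)
  expect_equal(apply(p2$theta, 2, var),
               apply(th, 2, var) + diag(k$Sigma_eps),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("filter reweighting multiplies prior weights by the likelihood", {
  sched <- standard_schedule()
  pat <- generate_patient(fx_responder_prior(), noise = fx_noise(),
                          seed = 14)
  th <- sample_prior(10, prior_spec(), seed = 15)
  prior_p <- weighted_particles(th, weights = runif(10, 0.5, 2),
                                provenance = "second_level_prior")
  post <- particle_filter_update(prior_p, pat$obs, fx_noise())
  ll <- log_likelihood(pat$obs, th, fx_noise())
  want <- prior_p$weights * exp(ll - max(ll))
  expect_equal(post$weights, want / sum(want), tolerance = 1e-12)
  expect_equal(attr(post, "ess"), effective_sample_size(post$weights))
  # no data: weights unchanged
  empty <- observation_set(numeric(0), numeric(0), sched$dose_times)
  expect_equal(particle_filter_update(prior_p, empty, fx_noise())$weights,
               prior_p$weights)
  # two particles with a 3:1 likelihood ratio
  v1 <- simulate_gtv(th[1, ], sched$dose_times, 7, log_scale = TRUE)$V
  obs1 <- observation_set(7, v1, sched$dose_times)
  ns <- noise_params(0.2, 0)
  ll2 <- log_likelihood(obs1, th[1:2, ], ns)
  w12 <- exp(ll2) / sum(exp(ll2))
  post2 <- particle_filter_update(
    weighted_particles(th[1:2, ], provenance = "second_level_prior"),
    obs1, ns)
  expect_equal(post2$weights, w12, tolerance = 1e-10)
})
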