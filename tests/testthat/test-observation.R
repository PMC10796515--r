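# Volume-dependent Gaussian observation model and noise pre-estimation.

test_that("measurement sd is linear in volume", {
  ns <- noise_params(0.1, 0.05)
  expect_equal(noise_sd(2, ns), 0.2)
  expect_equal(noise_sd(0, ns), 0.1)
  expect_equal(noise_sd(c(1, 3), noise_params(0.2, 0)), c(0.2, 0.2))
  expect_error(noise_sd(-1, ns), ">= 0")
  expect_error(noise_params(0, 0), "at least one")
  expect_error(noise_params(-0.1, 0.2), ">= 0")
})

test_that("log likelihood is an independent Gaussian product around the model volume", {
  th <- theta_log(fx_params())
  sched <- standard_schedule()
  vmod <- simulate_gtv(th, sched$dose_times, sched$meas_times,
                       log_scale = TRUE)$V
  # one observation exactly at the prediction, sd = 1
  obs1 <- observation_set(sched$meas_times[1], vmod[1], sched$dose_times)
  expect_equal(log_likelihood(obs1, th, noise_params(1, 0)),
               -0.5 * log(2 * pi), tolerance = 1e-10)
  # independence: two-point record is the sum of one-point records
  obs2 <- observation_set(sched$meas_times[1:2], vmod[1:2] + c(0.1, -0.2),
                          sched$dose_times)
  ll_a <- log_likelihood(observation_set(sched$meas_times[1],
                                         vmod[1] + 0.1,
                                         sched$dose_times),
                         th, fx_noise())
  ll_b <- log_likelihood(observation_set(sched$meas_times[2],
                                         vmod[2] - 0.2,
                                         sched$dose_times),
                         th, fx_noise())
  expect_equal(log_likelihood(obs2, th, fx_noise()), ll_a + ll_b,
               tolerance = 1e-10)
  # brute-force oracle over several particles
  set.seed(11)
  th_m <- sample_prior(5, prior_spec())
  obs <- observation_set(sched$meas_times, vmod + rnorm(7, 0, 0.05),
                         sched$dose_times)
  ll <- log_likelihood(obs, th_m, fx_noise())
  for (j in 1:5) {
    vj <- simulate_gtv(th_m[j, ], sched$dose_times, sched$meas_times,
                       log_scale = TRUE)$V
    expect_equal(ll[j],
                 sum(dnorm(obs$v_obs, vj, noise_sd(vj, fx_noise()),
                           log = TRUE)),
                 tolerance = 1e-8)
  }
})

test_that("joint GTV + necrosis records add independent necrosis terms", {
  th <- theta_log(fx_params())
  sched <- standard_schedule()
  sim <- simulate_gtv(th, sched$dose_times, sched$meas_times,
                      log_scale = TRUE, compartments = TRUE)
  obs_v <- observation_set(sched$meas_times, sim$V + 0.02,
                           sched$dose_times)
  obs_vn <- observation_set(sched$meas_times, sim$V + 0.02,
                            sched$dose_times, n_obs = sim$N - 0.01)
  ns <- fx_noise()
  extra <- sum(dnorm(sim$N - 0.01, sim$N,
                     noise_sd(sim$N, ns), log = TRUE))
  expect_equal(log_likelihood(obs_vn, th, ns),
               log_likelihood(obs_v, th, ns) + extra, tolerance = 1e-8)
})

test_that("likelihood peaks when the trajectory matches the data pointwise", {
  th <- theta_log(fx_params())
  sched <- standard_schedule()
  vmod <- simulate_gtv(th, sched$dose_times, sched$meas_times,
                       log_scale = TRUE)$V
  obs <- observation_set(sched$meas_times, vmod, sched$dose_times)
  ns <- noise_params(0.1, 0)  # constant sd: pointwise-closest maximises
  ll_true <- log_likelihood(obs, th, ns)
  set.seed(5)
  for (i in 1:10) {
    other <- th + rnorm(6, 0, 0.3)
    expect_gte(ll_true, log_likelihood(obs, other, ns))
  }
})

test_that("added noise has the modelled mean and spread and is seed-reproducible", {
  v <- 1.7
  ns <- fx_noise()
  x <- add_noise(rep(v, 1e5), ns, seed = 31)
  expect_lt(abs(mean(x) - v), 4 * noise_sd(v, ns) / sqrt(1e5))
  expect_lt(abs(sd(x) / noise_sd(v, ns) - 1), 0.02)
  expect_identical(add_noise(c(1, 0.5), ns, seed = 8),
                   add_noise(c(1, 0.5), ns, seed = 8))
  # vanishing noise returns the input
  expect_equal(add_noise(c(1, 0.5), noise_params(1e-300, 0), seed = 1),
               c(1, 0.5))
})

test_that("the pooled noise-parameter mode is order-invariant and single-patient pooling is the patient's posterior", {
  set.seed(21)
  a1 <- rnorm(2000, 0.06, 0.01); a2 <- rnorm(2000, 0.11, 0.02)
  m1 <- radresp:::kde2d_mode(a1, a2)
  o <- sample.int(2000)
  m2 <- radresp:::kde2d_mode(a1[o], a2[o])
  expect_equal(m1, m2, tolerance = 1e-12)

  pat <- generate_patient(fx_responder_prior(), noise = fx_noise(),
                          seed = 4)
  est <- estimate_noise_params(list(pat$obs), prior_spec(), iters = 1200,
                               chains = 2, thin_to = 200, seed = 10,
                               check_convergence = "none")
  pooled <- attr(est, "pooled")
  expect_equal(nrow(pooled), 200)
  expect_true(all(pooled > 0 & pooled < 0.5))
  expect_true(est$alpha1 >= 0 && est$alpha2 >= 0)
})
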