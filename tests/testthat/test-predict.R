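# Prediction summaries and evaluation statistics.

test_that("trajectory bands collapse onto a single or fully weighted particle", {
  sched <- standard_schedule()
  th <- rbind(theta_log(fx_params()), theta_log(fx_poor_params()))
  tr1 <- simulate_gtv(th[1, ], sched$dose_times, sched$meas_times,
                      log_scale = TRUE)$V
  dup <- weighted_particles(th[c(1, 1), ], provenance = "filtered")
  pred <- predict_trajectory(dup, sched$dose_times, sched$meas_times)
  expect_equal(pred$mean, tr1, tolerance = 1e-10)
  expect_equal(pred$q025, tr1, tolerance = 1e-10)
  expect_equal(pred$q975, tr1, tolerance = 1e-10)
  # all weight on particle 1: quantiles equal its trajectory
  p10 <- weighted_particles(th, weights = c(1, 0),
                            provenance = "filtered")
  pred10 <- suppressWarnings(
    predict_trajectory(p10, sched$dose_times, sched$meas_times))
  expect_equal(pred10$q25, tr1, tolerance = 1e-10)
  expect_equal(pred10$mean, tr1, tolerance = 1e-10)
})

test_that("prediction quantiles match a brute-force weighted ECDF", {
  sched <- standard_schedule()
  set.seed(16)
  th <- sample_prior(10, prior_spec())
  w <- runif(10); w <- w / sum(w)
  p <- weighted_particles(th, weights = w, provenance = "filtered")
  pred <- predict_trajectory(p, sched$dose_times, c(7, 21))
  V <- simulate_gtv(th, sched$dose_times, c(7, 21))$V
  for (i in 1:2) {
    o <- order(V[, i]); cw <- cumsum(w[o])
    for (q in c("q025", "q25", "q75", "q975")) {
      pr <- c(q025 = 0.025, q25 = 0.25, q75 = 0.75, q975 = 0.975)[[q]]
      expect_equal(pred[[q]][i], V[o, i][min(which(cw >= pr - 1e-12))])
    }
    expect_equal(pred$mean[i], sum(w * V[, i]))
  }
  # intervals are nested and ordered
  expect_true(all(pred$q025 <= pred$q25 & pred$q25 <= pred$q75 &
                  pred$q75 <= pred$q975))
})

test_that("observation-level bands widen the mean-level bands", {
  sched <- standard_schedule()
  th <- sample_prior(400, prior_spec(), seed = 17)
  p <- weighted_particles(th, provenance = "filtered")
  mean_lvl <- predict_trajectory(p, sched$dose_times, c(14, 39))
  obs_lvl <- predict_trajectory(p, sched$dose_times, c(14, 39),
                                noise = fx_noise())
  expect_true(all(obs_lvl$q975 - obs_lvl$q025 >
                  mean_lvl$q975 - mean_lvl$q025))
})

test_that("growth-only particles predict a final volume above baseline", {
  th <- matrix(rep(theta_log(fx_poor_params()), 3), nrow = 3, byrow = TRUE)
  th <- th + cbind(matrix(rnorm(3 * 1, 0, 0.01), ncol = 1),
                   matrix(0, 3, 5))
  p <- weighted_particles(th, provenance = "filtered")
  fv <- predict_final_volume(p, standard_schedule()$dose_times,
                             horizon = 42)
  expect_gt(fv$q025, 1)
  # degenerate (identical) particle set is a point mass
  pd <- weighted_particles(th[c(1, 1), ], provenance = "filtered")
  fvd <- predict_final_volume(pd, standard_schedule()$dose_times, 42)
  expect_equal(fvd$q025, fvd$q975)
})

test_that("prior particles reproduce prior class proportions and responders mirror poor mass", {
  th <- sample_prior(500, prior_spec(), seed = 18)
  p <- weighted_particles(th, provenance = "prior")
  labs <- classify_params(th)
  cp <- predict_class_probs(p)
  expect_equal(unname(cp["fast_responder"]),
               mean(labs == "fast_responder"), tolerance = 1e-12)
  expect_equal(unname(cp["eventual_response"]),
               1 - unname(cp["poor_responder"]), tolerance = 1e-12)
  one <- weighted_particles(rbind(theta_log(fx_params()),
                                  theta_log(fx_params())),
                            provenance = "filtered")
  expect_equal(unname(predict_class_probs(one)["fast_responder"]), 1)
})

test_that("Bayesian R-squared matches its closed-form cases", {
  expect_equal(bayesian_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_warning(r0 <- bayesian_r2(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(r0, 0)
  expect_equal(bayesian_r2(rep(1.5, 4), c(1, 2, 1, 2)), 0)
  expect_equal(bayesian_r2(c(1, 2, 3), c(1.1, 1.9, 3.2)),
               1 / (1 + 0.023333333 / 1), tolerance = 1e-6)
  # median across samples; invariant to adding a constant to both
  fit <- rbind(c(1, 2, 3), c(1, 2, 3) * 1.2, c(3, 2, 1))
  obs <- c(1.1, 1.9, 3.2)
  expect_equal(bayesian_r2(fit, obs), bayesian_r2(fit + 5, obs + 5),
               tolerance = 1e-12)
  expect_error(bayesian_r2(c(1, 2, 3), c(1, 2)), "match")
  expect_error(bayesian_r2(matrix(c(1, 2), ncol = 1), 2), "at least 2")
})

test_that("Welch summary test reproduces a direct t computation with fractional df", {
  w <- welch_summary_test(0, 1, 10, 1, 1, 10)
  expect_equal(w$df, 18, tolerance = 1e-12)
  expect_equal(w$p.value, 2 * pt(-abs(-1 / sqrt(0.2)), 18),
               tolerance = 1e-12)
  expect_equal(w$p.value, 0.038, tolerance = 0.02)
  # fractional counts flow through the df without rounding
  wf <- welch_summary_test(1, 2, 5.5, 0, 3, 2.7)
  v1 <- 4 / 5.5; v2 <- 9 / 2.7
  expect_equal(wf$df, (v1 + v2)^2 / (v1^2 / 4.5 + v2^2 / 1.7),
               tolerance = 1e-12)
  expect_error(welch_summary_test(0, 1, 1, 1, 1, 10), "exceed 1")
  expect_error(welch_summary_test(0, 0, 10, 1, 1, 10), "> 0")
})

test_that("fractional class counts give probability-weighted volume statistics", {
  probs <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
  colnames(probs) <- response_classes
  st <- class_volume_stats(probs, c(10, 20, 30))
  expect_equal(st$count, c(3, 0, 0, 0))
  expect_equal(st$mean[1], 20)
  expect_true(all(is.na(st$mean[2:4])))
  # hand-set probabilistic classification
  probs2 <- rbind(c(0.6, 0.4, 0, 0), c(0.2, 0.8, 0, 0),
                  c(0.9, 0.1, 0, 0))
  colnames(probs2) <- response_classes
  st2 <- class_volume_stats(probs2, c(10, 20, 30))
  expect_equal(sum(st2$count), 3, tolerance = 1e-12)
  expect_equal(st2$count[1], 1.7)
  expect_equal(st2$mean[1], (0.6 * 10 + 0.2 * 20 + 0.9 * 30) / 1.7)
  expect_error(class_volume_stats(rbind(c(0.5, 0.4, 0, 0)), 1), "sum to 1")
})

test_that("prediction uncertainty shrinks on average as scans accumulate", {
  sched <- standard_schedule()
  pr <- fx_responder_prior()
  prior_p <- weighted_particles(sample_prior(1500, pr, seed = 19),
                                provenance = "second_level_prior")
  widths <- matrix(NA_real_, 8, 3)
  set.seed(20)
  seeds <- sample.int(1e6, 8)
  for (r in 1:8) {
    pat <- generate_patient(pr, noise = fx_noise(), seed = seeds[r])
    for (k in 1:3) {
      upto <- c(7, 21, 39)[k]
      flt <- particle_filter_update(prior_p,
                                    observations_upto(pat$obs, upto),
                                    fx_noise())
      fv <- predict_final_volume(flt, sched$dose_times, 42)
      widths[r, k] <- fv$q975 - fv$q025
    }
  }
  mw <- colMeans(widths)
  expect_true(mw[3] <= mw[2] && mw[2] <= mw[1])
})
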