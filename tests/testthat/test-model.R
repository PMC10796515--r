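# Two-compartment dynamics, dose impulses and the standard schedule.

test_that("initial composition splits a unit volume by the necrotic proportion", {
  expect_equal(unname(initial_state(0.2)[c("L", "N")]), c(0.8, 0.2))
  expect_equal(unname(initial_state(1e-12)[c("L", "N")]), c(1, 0),
               tolerance = 1e-9)
  expect_equal(sum(initial_state(0.5)[c("L", "N")]), 1)
  expect_error(initial_state(0), "phi0")
  expect_error(initial_state(1), "phi0")
})

test_that("dose impulses transfer living volume and conserve the total", {
  s <- initial_state(0.2)
  expect_equal(unname(apply_dose(s, 0.25)[c("L", "N")]), c(0.6, 0.4))
  # identity limit
  expect_equal(unname(apply_dose(s, 1e-14)[c("L", "N")]),
               unname(s[c("L", "N")]), tolerance = 1e-12)
  # conservation across random states and doses, both conventions
  set.seed(41)
  for (i in 1:50) {
    st <- c(L = runif(1, 0, 3), N = runif(1, 0, 3), t = 0)
    g <- runif(1, 1e-6, 1 - 1e-6)
    for (cv in c("transfer", "exponential")) {
      post <- apply_dose(st, g, cv)
      expect_lt(abs(sum(post[c("L", "N")]) - sum(st[c("L", "N")])),
                8 * .Machine$double.eps * sum(st[c("L", "N")]))
      expect_true(post[["L"]] < st[["L"]] && post[["N"]] > st[["N"]])
    }
  }
  expect_error(apply_dose(s, 1), "gamma")
  expect_error(apply_dose(s, 0), "gamma")
})

test_that("smooth dynamics match closed-form solutions", {
  # pure logistic growth (no necrosis, no decay): K/(1 + (K/L0 - 1) e^-lt)
  p <- model_params(0.1, 2, 0.5, 1e-14, 1e-14, 1e-14)
  st <- c(L = 1, N = 0, t = 0)
  out <- integrate_smooth(st, p, 0, 7)
  expect_equal(out[["L"]], 2 / (1 + exp(-0.7)), tolerance = 1e-8)
  # pure necrotic decay from a fully necrotic state
  p2 <- model_params(0.1, 2, 0.5, 0.3, 1e-14, 1e-14)
  st2 <- c(L = 0, N = 0.4, t = 0)
  out2 <- integrate_smooth(st2, p2, 0, 5)
  expect_equal(out2[["N"]], 0.4 * exp(-0.3 * 5), tolerance = 1e-8)
  expect_equal(out2[["L"]], 0, tolerance = 1e-10)
  expect_error(integrate_smooth(st, p, 3, 2), "t1")
})

test_that("integration agrees with an independent reference solver", {
  skip_if_not_installed("deSolve")
  p <- model_params(0.08, 2.5, 0.3, 0.25, 0.04, 0.3)
  rhs <- function(t, y, parms)
    list(c(parms$lambda * y[1] * (1 - y[1] / parms$K) - parms$eta * y[1],
           parms$eta * y[1] - parms$zeta * y[2]))
  ref <- deSolve::lsoda(c(L = 0.7, N = 0.3), c(0, 20), rhs,
                        list(lambda = 0.08, K = 2.5, zeta = 0.25,
                             eta = 0.04),
                        rtol = 1e-11, atol = 1e-13)
  out <- integrate_smooth(c(L = 0.7, N = 0.3, t = 0), p, 0, 20)
  expect_equal(out[["L"]], unname(ref[2, "L"]), tolerance = 1e-8)
  expect_equal(out[["N"]], unname(ref[2, "N"]), tolerance = 1e-8)
})

test_that("impulsive simulation composes smooth flow with dose maps", {
  p <- fx_params()
  sched <- standard_schedule()
  tr <- simulate_gtv(p, sched$dose_times, sched$meas_times,
                     compartments = TRUE)
  # step-by-step composition with integrate_smooth + apply_dose
  ev <- sort(unique(c(sched$dose_times, sched$meas_times)))
  st <- initial_state(p[["phi0"]])
  got <- list()
  for (tt in ev) {
    st <- integrate_smooth(st, p, st[["t"]], tt)
    if (tt %in% sched$dose_times)
      st <- apply_dose(st, p[["gamma"]])
    if (tt %in% sched$meas_times) got[[as.character(tt)]] <- st
  }
  man <- do.call(rbind, got)
  expect_equal(tr$L, unname(man[, "L"]), tolerance = 1e-7)
  expect_equal(tr$N, unname(man[, "N"]), tolerance = 1e-7)
  expect_equal(tr$V, tr$L + tr$N)
})

test_that("a vanishing dose effect is schedule-independent and internal transfers preserve volume", {
  th <- theta_log(model_params(0.05, 2, 1e-12, 0.2, 0.01, 0.2))
  sched <- standard_schedule()
  with_doses <- simulate_gtv(th, sched$dose_times, sched$meas_times,
                             log_scale = TRUE)
  without <- simulate_gtv(th, numeric(0), sched$meas_times,
                          log_scale = TRUE)
  expect_equal(with_doses$V, without$V, tolerance = 1e-9)
  # lambda = eta = zeta ~ 0: a dose only moves volume between compartments
  th2 <- theta_log(model_params(1e-12, 2, 0.3, 1e-12, 1e-12, 0.2))
  tr2 <- simulate_gtv(th2, 1, c(0, 0.5, 1, 2, 5), log_scale = TRUE)
  expect_equal(tr2$V, rep(1, 5), tolerance = 1e-9)
})

test_that("volume is continuous across dose instants and invariant to grid splitting", {
  th <- theta_log(fx_params())
  sched <- standard_schedule()
  t_dose <- sched$dose_times[8]
  eps <- 1e-9
  v <- simulate_gtv(th, sched$dose_times,
                    c(t_dose - eps, t_dose, t_dose + eps),
                    log_scale = TRUE)$V
  expect_lt(max(abs(diff(v))), 1e-7)
  # extra interior observation points do not perturb shared times
  base <- simulate_gtv(th, sched$dose_times, sched$meas_times,
                       log_scale = TRUE)
  fine_t <- sort(unique(c(sched$meas_times, seq(0.5, 38.5, by = 1.7))))
  fine <- simulate_gtv(th, sched$dose_times, fine_t, log_scale = TRUE)
  expect_equal(fine$V[match(sched$meas_times, fine_t)], base$V,
               tolerance = 1e-8)
  expect_true(all(fine$V >= 0))
})

test_that("standard schedule lays out weekday fractions and weekly scans", {
  s6 <- standard_schedule(start_day = 14, weeks = 6)
  expect_length(s6$dose_times, 30)
  expect_equal(min(s6$dose_times), 14)
  expect_equal(max(s6$dose_times), 53)
  expect_equal(sum(s6$classify), 7)  # 6 week starts + final dose
  expect_equal(s6$meas_times[!s6$classify], 0)  # diagnosis scan excluded
  s1 <- standard_schedule(start_day = 0, weeks = 1)
  expect_equal(s1$dose_times, 0:4)
  expect_equal(s1$meas_times[s1$classify], c(0, 4))
  s0 <- standard_schedule()
  expect_equal(s0$meas_times, c(0, 7, 14, 21, 28, 35, 39))
  expect_true(all(s0$classify))
})
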