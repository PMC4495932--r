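test_that("the perfect integrator always restores the goal rate", {
  p <- neuron_params(10, 50, 300, r_goal = 1)
  traj <- simulate_rate(p, input_protocol("step", amplitude = 1, onset = 500),
                        duration = 20000, record_dt = 10)
  n <- length(traj$pop_rate)
  expect_equal(traj$pop_rate[n], 1, tolerance = 1e-6)
})

test_that("slow homeostasis settles exponentially with tau3/alpha", {
  p <- neuron_params(10, 50, 5000, alpha = 2, r_goal = 1)
  traj <- simulate_rate(p, input_protocol("constant", amplitude = 2),
                        duration = 30000, record_dt = 10,
                        init = list(r1 = 1.5, r2 = 1.5, r3 = 1))
  dev <- traj$pop_rate - 1
  k <- traj$time > 2000 & traj$time < 20000 & dev > 1e-8
  fit <- lm(log(dev[k]) ~ traj$time[k])
  expect_equal(-1 / coef(fit)[[2]], 5000 / 2, tolerance = 0.05)
})

test_that("a system at its fixed point stays there", {
  p <- neuron_params(10, 50, 100, r_goal = 2)
  traj <- simulate_rate(p, input_protocol("constant", amplitude = 0),
                        duration = 2000)
  expect_lt(max(abs(traj$r1 - 2)), 1e-10)
  expect_lt(max(abs(diff(traj$r3[1, ]))), 1e-10)
})

test_that("integration agrees with an independent adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- neuron_params(10, 50, 120, alpha = 1.5, r_goal = 1)
  wm <- 0.4
  traj <- simulate_rate(p, input_protocol("constant", amplitude = 0.8),
                        recurrence = wm, duration = 2000, record_dt = 50,
                        init = list(r1 = 0, r2 = 0, r3 = 0))
  rhs <- function(t, y, parms) {
    x <- wm / p$alpha * y[1] + 0.8 - y[3]
    list(c((-y[1] + p$alpha * x) / p$tau1,
           (-y[2] + y[1]) / p$tau2,
           (y[2] - p$r_goal) / p$tau3))
  }
  ref <- deSolve::lsoda(c(0, 0, 0), times = traj$time, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(traj$r1[1, ], unname(ref[, 2]), tolerance = 1e-6)
})

test_that("halving the step changes the deterministic solution negligibly", {
  p <- neuron_params(10, 50, 300)
  t1 <- simulate_rate(p, input_protocol("step", 1, onset = 100),
                      duration = 3000, dt = 0.1)
  t2 <- simulate_rate(p, input_protocol("step", 1, onset = 100),
                      duration = 3000, dt = 0.05)
  expect_lt(abs(t1$pop_rate[length(t1$pop_rate)] -
                  t2$pop_rate[length(t2$pop_rate)]), 1e-4)
})

test_that("seeded noisy runs are reproducible and rectification holds", {
  p <- neuron_params(10, 50, 100)
  inp <- input_protocol("constant", amplitude = 0.2)
  set.seed(42)
  a <- simulate_rate(p, inp, noise = noise_spec(0.5, 1), duration = 2000,
                     rectify = TRUE)
  set.seed(42)
  b <- simulate_rate(p, inp, noise = noise_spec(0.5, 1), duration = 2000,
                     rectify = TRUE)
  expect_identical(a$r1, b$r1)
  expect_true(all(a$r1 >= 0))
})

test_that("simulated growth and decay rates track the dominant eigenvalue", {
  set.seed(31)
  for (i in 1:6) {
    t3 <- runif(1, 20, 500); wm <- runif(1, 0, 0.8)
    p <- neuron_params(10, 50, t3, r_goal = 1)
    lam <- eigmax(build_single_mode_matrix(p, wm))
    if (abs(lam) < 5e-4) next
    traj <- simulate_rate(p, input_protocol("constant", amplitude = 1),
                          recurrence = wm, duration = 4000, record_dt = 5,
                          init = list(r1 = 1.02, r2 = 1,
                                      r3 = wm * 1 + 1 - 1))
    # distance of the full state from the fixed point avoids the zero
    # crossings of any single oscillating coordinate
    dev <- sqrt((traj$r1[1, ] - 1)^2 + (traj$r2[1, ] - 1)^2 +
                  (traj$r3[1, ] - wm)^2)
    k <- traj$time > 500 & traj$time < 3000 & dev > 1e-12 & dev < 10
    fit <- lm(log(dev[k]) ~ traj$time[k])
    expect_equal(coef(fit)[[2]], lam, tolerance = 0.05)
  }
})

test_that("empirical regime detection matches the step-response phenomenology", {
  run <- function(wm, t3 = 500) {
    p <- neuron_params(10, 50, t3, r_goal = 1)
    simulate_rate(p, input_protocol("step", amplitude = 0.5, onset = 2000),
                  recurrence = wm, duration = 30000, record_dt = 1,
                  rectify = TRUE)
  }
  expect_equal(detect_regime_empirical(run(0), transient = 4000), "monotone")
  expect_equal(detect_regime_empirical(run(0.8), transient = 4000),
               "damped_oscillatory")
  expect_equal(detect_regime_empirical(run(0.95), transient = 4000),
               "sustained_oscillation")
})

test_that("empirical and analytic regime calls agree off the boundaries", {
  set.seed(32)
  agree <- 0; total <- 0
  for (t3 in c(3, 30, 120, 400, 1200)) {
    for (wm in c(0, 0.3, 0.6, 0.9)) {
      p <- neuron_params(10, 50, t3, r_goal = 1)
      cls <- classify_regime(p, wm)
      # skip near-marginal cells where finite-window calls are arbitrary
      if (abs(t3 - cls$tau3_crit) < 0.25 * cls$tau3_crit) next
      if (abs(t3 - cls$tau3_osc_free) < 0.25 * cls$tau3_osc_free) next
      traj <- simulate_rate(p, input_protocol("step", amplitude = 0.5,
                                              onset = 1000),
                            recurrence = wm, rectify = TRUE,
                            duration = max(20000, 40 * t3), record_dt = 2)
      # analyse from the step onset so damped transients are visible
      emp <- detect_regime_empirical(traj, transient = 1000)
      lab <- c(stable = "monotone",
               damped_oscillatory = "damped_oscillatory",
               unstable = "sustained_oscillation")[cls$regime]
      total <- total + 1
      if (emp == lab) agree <- agree + 1
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("heterogeneity: degenerate draws and destabilizing trend", {
  set.seed(33)
  spec <- heterogeneity_spec(means = c(10, 50, 100), n = 10, trials = 12)
  sw <- heterogeneity_sweep(spec, cvs = c(0, 0.5, 1.2))
  hom <- critical_recurrence(neuron_params(10, 50, 100))
  expect_equal(sw$mean_wc[1], hom, tolerance = 1e-4)
  expect_equal(sw$sd_wc[1], 0)
  # strong heterogeneity destabilizes on average, and single draws fall on
  # both sides of the homogeneous value at moderate heterogeneity
  expect_lt(sw$mean_wc[3], hom)
  expect_gt(sw$sd_wc[2], 0)
})

test_that("interference with an integrating network vanishes for slow control", {
  inp <- input_protocol("biphasic_pulse", amplitude = 1, onset = 2000,
                        offset = 10000, width = 100)
  fast <- integrator_interference(1000, 7000, inp)
  slow <- integrator_interference(1000, 420000, inp)
  # rapid homeostasis rings and distorts the integrator response strongly;
  # oscillation-free homeostasis leaves only a slow residual droop
  expect_gt(fast$discrepancy, 3 * slow$discrepancy)
  expect_gt(fast$discrepancy, 1)
  expect_lt(slow$discrepancy, 0.5)

  # removing the feedback recovers the ideal integrator exactly
  p <- neuron_params(10, 50, 7000, r_goal = 0)
  a <- simulate_rate(p, inp, recurrence = 0.99, duration = 3000,
                     homeostasis = FALSE, init = "zero")
  b <- simulate_rate(p, inp, recurrence = 0.99, duration = 3000,
                     homeostasis = TRUE, hgain = 0, init = "zero")
  expect_identical(a$r1, b$r1)
})
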