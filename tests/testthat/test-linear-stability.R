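test_that("single-neuron critical integrator time constant", {
  expect_equal(tau3_min_single(10, 50, 1), 25 / 3, tolerance = 1e-12)
  expect_equal(tau3_min_single(10, 10, 1), 5)
  expect_equal(tau3_min_single(10, 1e12, 1), 10, tolerance = 1e-6)
  expect_error(tau3_min_single(-1, 50), "positive")
})

test_that("network critical integrator time constant", {
  expect_equal(tau3_crit_network(10, 50, 1, 0), tau3_min_single(10, 50, 1))
  expect_equal(tau3_crit_network(10, 50, 1, 0.99), 100 * 500 / 10.5,
               tolerance = 1e-12)                      # ~4.8 s
  expect_equal(tau3_crit_network(10, 50, 1, 0.999), 1000 * 500 / 10.05,
               tolerance = 1e-12)                      # ~50 s
  expect_equal(tau3_crit_network(10, 50, 1, 0.8), 125)
  expect_error(tau3_crit_network(10, 50, 1, 1), "wm")

  # monotone in recurrence
  wm <- seq(0, 0.99, length.out = 40)
  expect_true(all(diff(tau3_crit_network(10, 50, 1, wm)) > 0))
})

test_that("complex-eigenvalue boundary: reductions, limits, and root oracle", {
  for (wr in c(-0.5, 0, 0.7)) {
    expect_equal(tau3_crit_complex(10, 50, wr, 0),
                 tau3_crit_network(10, 50, 1, wr), tolerance = 1e-10)
  }
  expect_equal(tau3_crit_complex(10, 50, 0.5, 1e8), 50 / 0.5,
               tolerance = 1e-4)

  set.seed(11)
  for (i in 1:30) {
    wr <- runif(1, -0.5, 0.9); wi <- runif(1, 0.02, 3)
    t1 <- runif(1, 2, 50); t2 <- runif(1, 5, 200)
    expect_equal(tau3_crit_complex(t1, t2, wr, wi),
                 tau3_boundary_oracle(t1, t2, wr, wi),
                 tolerance = 1e-6)
  }
})

test_that("oscillation-free boundary: worked value, closed form, singularity", {
  b <- tau3_osc_free(10, 50, 0)
  expect_gt(b, 220)
  expect_equal(b, tau3_osc_free_closed(10, 50, 0), tolerance = 1e-5)

  # just below the boundary the cubic has complex roots; just above, real
  co_lo <- polyroot(mode_poly(10, 50, b * 0.999))
  co_hi <- polyroot(mode_poly(10, 50, b * 1.001))
  expect_gt(max(abs(Im(co_lo))), 1e-6)
  expect_lt(max(abs(Im(co_hi))) / max(abs(Re(co_hi))), 1e-2)

  # removable singularity of the closed form at tau1 = (1 - wm) tau2
  wm_star <- 1 - 10 / 50
  vals <- vapply(wm_star + c(-1e-3, 0, 1e-3), function(w)
    tau3_osc_free(10, 50, w), numeric(1))
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(diff(vals))) / vals[2], 0.02)

  # strong-recurrence quadratic scaling of the bound
  wm <- 1 - 10 / c(1000, 3000, 10000)
  ratio <- tau3_osc_free(10, 50, wm[3]) /
    vapply(wm, function(w) tau3_osc_free(10, 50, w), numeric(1))[1]
  expect_equal(log(ratio) / log(10), 2, tolerance = 0.05)

  # always at least as slow as the sustained-oscillation boundary
  set.seed(12)
  for (i in 1:20) {
    t1 <- runif(1, 2, 50); t2 <- runif(1, 5, 300); w <- runif(1, 0, 0.95)
    expect_gte(tau3_osc_free(t1, t2, w) * (1 + 1e-6),
               tau3_crit_network(t1, t2, 1, w))
  }
})

test_that("network-bound approximations hold in their regimes", {
  a <- 1.4
  # slow sensor relative to the network mode ((1-wm)*tau2 >> tau1):
  # tau3 ~ alpha * tau1 / (1 - wm)^2
  expect_equal(tau3_crit_network(10, 1e4, a, 0.9), a * 10 / (1 - 0.9)^2,
               tolerance = 0.05)
  # fast sensor relative to the network mode ((1-wm)*tau2 << tau1):
  # tau3 ~ alpha * tau2 / (1 - wm)
  expect_equal(tau3_crit_network(10, 0.05, a, 0.999), a * 0.05 / (1 - 0.999),
               tolerance = 0.05)
})

test_that("Routh-Hurwitz real cubic", {
  expect_true(routh_hurwitz_real(c(1, 3, 3, 1)))
  expect_false(routh_hurwitz_real(c(2, 1, 1, 1)))   # root-sign oracle case
  expect_identical(routh_hurwitz_real(c(2, 1, 1, 1)),
                   max(Re(polyroot(c(2, 1, 1, 1)))) < 0)
  expect_false(routh_hurwitz_real(c(1, -0.1, 3, 1)))
  expect_error(routh_hurwitz_real(c(1, 2, 3)), "degree")
})

test_that("Routh-Hurwitz complex cubic agrees with direct roots", {
  # real coefficients reduce to the real test
  set.seed(13)
  for (i in 1:50) {
    co <- runif(4, 0.1, 3)
    expect_identical(routh_hurwitz_complex(co[3] / co[4], co[2] / co[4],
                                           co[1] / co[4]),
                     routh_hurwitz_real(co))
  }
  # random complex coefficients vs the root-sign oracle
  n_checked <- 0
  for (i in 1:500) {
    c1 <- complex(real = rnorm(1), imaginary = rnorm(1))
    c2 <- complex(real = rnorm(1), imaginary = rnorm(1))
    c3 <- complex(real = rnorm(1), imaginary = rnorm(1))
    mr <- max(Re(polyroot(c(c3, c2, c1, 1))))
    if (abs(mr) < 1e-9) next
    n_checked <- n_checked + 1
    expect_identical(routh_hurwitz_complex(c1, c2, c3), mr < 0)
  }
  expect_gt(n_checked, 450)
})

test_that("complex RH conditions and the closed-form boundary agree", {
  set.seed(14)
  for (i in 1:20) {
    t1 <- runif(1, 2, 50); t2 <- runif(1, 5, 200)
    wr <- runif(1, -0.5, 0.9); wi <- runif(1, 0.05, 2)
    wn <- complex(real = wr, imaginary = wi)
    bound <- tau3_crit_complex(t1, t2, wr, wi)
    rh_at <- function(t3) {
      routh_hurwitz_complex(1 / t2 + (1 - wn) / t1, (1 - wn) / (t1 * t2),
                            1 / (t1 * t2 * t3))
    }
    expect_true(rh_at(bound * 1.001))
    expect_false(rh_at(bound * 0.999))
  }
})

test_that("regime classification matches the phase diagram and oracles", {
  p <- function(t3) neuron_params(10, 50, t3)
  expect_equal(classify_regime(p(5))$regime, "unstable")
  expect_equal(classify_regime(p(100))$regime, "damped_oscillatory")
  expect_equal(classify_regime(p(300))$regime, "stable")

  rep <- classify_regime(p(100))
  expect_equal(rep$tau3_crit, 25 / 3, tolerance = 1e-9)
  expect_gt(rep$tau3_osc_free, 220)

  # oracle equivalence across four orders of magnitude in every parameter
  set.seed(15)
  n_checked <- 0
  for (i in 1:400) {
    t1 <- 10^runif(1, 0, 3); t2 <- 10^runif(1, 0, 3)
    t3 <- 10^runif(1, 0, 4); a <- 10^runif(1, -1, 1)
    w <- runif(1, -1, 0.99)
    m <- build_single_mode_matrix(neuron_params(t1, t2, t3, alpha = a), w)
    mre <- eigmax(m)
    if (abs(mre) < 1e-9) next
    n_checked <- n_checked + 1
    cls <- classify_regime(neuron_params(t1, t2, t3, alpha = a), w)
    expect_identical(cls$regime == "unstable", mre > 0)
    expect_identical(routh_hurwitz_real(mode_poly(t1, t2, t3, a, w)),
                     mre < 0)
  }
  expect_gt(n_checked, 350)
})

test_that("critical recurrence: closed form, full spectrum, no feedback", {
  p <- neuron_params(10, 50, 100)
  wc <- critical_recurrence(p)
  # inversion consistency: the network bound at wc equals tau3
  expect_equal(tau3_crit_network(10, 50, 1, wc), 100, tolerance = 1e-9)

  set.seed(16)
  W <- random_weight_matrix(8, "symmetric_gaussian", target = 0.9)
  net <- network_spec(W, p)
  expect_equal(critical_recurrence(net, tol = 1e-7), wc, tolerance = 1e-5)
  expect_equal(critical_recurrence(net, feedback = FALSE, tol = 1e-7), 1,
               tolerance = 1e-5)
  expect_equal(critical_recurrence(p, feedback = FALSE), 1)
})
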