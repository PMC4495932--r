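test_that("single-mode matrix reproduces the printed entries and structure", {
  m <- build_single_mode_matrix(neuron_params(10, 50, 100, alpha = 1))
  expect_equal(unclass(m)[1, ], c(-0.1, 0, -0.1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(m)[2, ], c(0.02, -0.02, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(m)[3, ], c(0, 0.01, 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # perfect integrator: no leak on the threshold row, for any parameters
  set.seed(1)
  for (i in 1:20) {
    p <- neuron_params(runif(1, 1, 100), runif(1, 1, 500), runif(1, 1, 1e4),
                       alpha = runif(1, 0.1, 5))
    m <- build_single_mode_matrix(p, recurrence = runif(1, -1, 0.99))
    expect_identical(unclass(m)[3, 3], 0)
  }

  # recurrence 0 equals the N = 1 network build
  p <- neuron_params(10, 50, 77, alpha = 1.3)
  expect_equal(unclass(build_single_mode_matrix(p, 0)),
               unclass(build_network_matrix(network_spec(matrix(0, 1, 1), p))),
               ignore_attr = TRUE)
  expect_warning(build_single_mode_matrix(p, recurrence = 1.2),
                 "unstable")
})

test_that("gain can be absorbed into the integrator time constant", {
  set.seed(2)
  for (i in 1:25) {
    t1 <- runif(1, 1, 100); t2 <- runif(1, 1, 500); t3 <- runif(1, 1, 1e4)
    a <- runif(1, 0.1, 4); cc <- runif(1, 0.2, 5)
    ev1 <- eigen(unclass(build_single_mode_matrix(
      neuron_params(t1, t2, t3, alpha = a))))$values
    ev2 <- eigen(unclass(build_single_mode_matrix(
      neuron_params(t1, t2, t3 * cc, alpha = a * cc))))$values
    expect_spectra_equal(ev1, ev2, tol = 1e-10)
  }
})

test_that("symmetric network spectrum is the union of per-mode spectra", {
  set.seed(3)
  p <- neuron_params(10, 50, 140, alpha = 1)
  W <- random_weight_matrix(6, "symmetric_gaussian", target = 0.8)
  net <- network_spec(W, p)
  expect_true(net$symmetric)
  full <- eigen(unclass(build_network_matrix(net)), only.values = TRUE)$values
  wn <- eigen(W, only.values = TRUE)$values
  per_mode <- unlist(lapply(Re(wn), function(w)
    eigen(unclass(build_single_mode_matrix(p, w)), only.values = TRUE)$values))
  expect_spectra_equal(full, per_mode, tol = 1e-8)
})

test_that("degenerate heterogeneity reproduces the homogeneous network", {
  set.seed(4)
  W <- random_weight_matrix(5, "symmetric_gaussian", target = 0.7)
  spec <- heterogeneity_spec(means = c(10, 50, 100), cv = 0, n = 5)
  hom <- build_network_matrix(network_spec(W, neuron_params(10, 50, 100)))
  het <- build_network_matrix(network_spec(W, draw_params(spec)))
  expect_equal(unclass(het), unclass(hom))
})

test_that("f-I linearization finds the set-point and slope", {
  expect_equal(fi_linearize(fi_curve("linear", slope = 1), 1),
               list(set_point_input = 1, alpha = 1))
  tl <- fi_linearize(fi_curve("threshold_linear", slope = 2), 4)
  expect_equal(tl$set_point_input, 2)
  expect_equal(tl$alpha, 2)

  # tabulated sigmoid: analytic slope vs independent finite difference
  xs <- seq(-6, 6, length.out = 2001)
  f <- fi_curve("tabulated", x = xs, y = 10 / (1 + exp(-xs)))
  lin <- fi_linearize(f, 3)
  h <- 1e-4
  fd <- (fi_eval(f, lin$set_point_input + h) -
           fi_eval(f, lin$set_point_input - h)) / (2 * h)
  expect_equal(lin$alpha, fd, tolerance = 1e-6)

  expect_error(fi_linearize(fi_curve("sigmoid", rmax = 5), 7), "reachable")
})

test_that("envelope slope: linear, quadratic toy, and concave cases", {
  expect_equal(fi_envelope_slope(fi_curve("linear", slope = 2), 3)$beta, 1,
               tolerance = 1e-9)

  env <- fi_envelope_slope(
    fi_curve("custom", fn = function(x) x^2, domain = c(0, 2)), 1)
  expect_equal(env$max_ratio, 3, tolerance = 1e-6)
  expect_equal(env$alpha, 2, tolerance = 1e-6)
  expect_equal(env$beta, 1.5, tolerance = 1e-6)

  # concave saturating curve with maximum slope at the set-point
  env2 <- fi_envelope_slope(fi_curve("sigmoid", rmax = 10, x0 = 0, width = 1),
                            5)
  expect_equal(env2$beta, 1, tolerance = 1e-6)
})

test_that("f-I curves are validated and envelope dominates the tangent", {
  expect_error(fi_curve("tabulated", x = 1:3, y = c(0, 2, 1)), "monotonic")
  set.seed(5)
  for (i in 1:10) {
    rmax <- runif(1, 5, 20); w <- runif(1, 0.3, 3)
    f <- fi_curve("sigmoid", rmax = rmax, x0 = runif(1, -2, 2), width = w)
    rg <- runif(1, 0.1, 0.9) * rmax
    env <- fi_envelope_slope(f, rg)
    expect_gte(env$max_ratio, env$alpha * (1 - 1e-9))
  }
})
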