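test_that("input protocols evaluate as piecewise-constant drives", {
  st <- input_protocol("step", amplitude = 2, onset = 100, baseline = 0.5)
  expect_equal(protocol_eval(st, c(0, 99.9, 100, 500)), c(0.5, 0.5, 2, 2))
  bp <- input_protocol("biphasic_pulse", amplitude = 1, onset = 10,
                       offset = 50, width = 5)
  expect_equal(protocol_eval(bp, c(5, 12, 20, 52, 60)), c(0, 1, 0, -1, 0))
  expect_error(input_protocol("samples", times = c(2, 1), values = c(1, 2)),
               "non-decreasing")
  expect_error(input_protocol("samples", times = 1, values = Inf), "finite")
})

test_that("weight fixtures achieve their target spectra", {
  set.seed(61)
  W <- random_weight_matrix(10, "symmetric_gaussian", target = 0.8)
  expect_lt(max(abs(W - t(W))), 1e-12)
  expect_equal(max(Re(eigen(W)$values)), 0.8, tolerance = 1e-8)

  R1 <- random_weight_matrix(8, "rank_one", target = 0.5)
  ev <- eigen(R1, only.values = TRUE)$values
  expect_equal(max(Re(ev)), 0.5, tolerance = 1e-8)
  expect_lt(sort(Mod(ev), decreasing = TRUE)[2], 1e-10)

  A <- random_weight_matrix(12, "asymmetric_gaussian", target = 0.9)
  expect_gt(max(abs(Im(eigen(A, only.values = TRUE)$values))), 1e-6)
  expect_warning(random_weight_matrix(4, "symmetric_gaussian", target = 1.2),
                 "unstable")
})

test_that("matrices and trajectories round-trip through CSV exactly", {
  set.seed(62)
  W <- random_weight_matrix(7, "asymmetric_gaussian", target = 0.8)
  path <- tempfile(fileext = ".csv")
  write_matrix_csv(W, path)
  expect_identical(read_matrix_csv(path), unname(W))

  traj <- simulate_rate(neuron_params(10, 50, 100),
                        input_protocol("step", 1, onset = 50),
                        duration = 200, record_dt = 1)
  tpath <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, tpath)
  back <- read.csv(tpath)
  expect_identical(back$r1, as.data.frame(traj)$r1)
})

test_that("configs parse from YAML and JSON alike", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("experiment: cascade", "seed: 7"), y)
  j <- tempfile(fileext = ".json")
  writeLines('{"experiment": "cascade", "seed": 7}', j)
  expect_equal(read_config(y), read_config(j))
})

test_that("experiment runner writes deterministic, self-describing bundles", {
  cfg <- list(experiment = "single-phase-diagram",
              tau2 = c(20, 50, 100), tau3 = c(5, 50, 500, 3000))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  run_experiment(cfg, d1, seed = 3)
  run_experiment(cfg, d2, seed = 3)
  f1 <- file.path(d1, "single-phase-diagram.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1),
                   readLines(file.path(d2, "single-phase-diagram.csv")))
  smry <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(smry$experiment, "single-phase-diagram")
  expect_equal(smry$seed, 3)
  expect_true(nzchar(smry$config_hash))

  grid <- read.csv(f1)
  # labels consistent with the closed-form boundaries
  for (i in seq_len(nrow(grid))) {
    expected <- if (grid$tau3[i] < grid$tau3_crit[i]) "unstable"
      else if (grid$tau3[i] < grid$tau3_osc_free[i]) "damped_oscillatory"
      else "stable"
    expect_equal(grid$regime[i], expected)
  }
  expect_error(run_experiment(list(experiment = "nope"), tempdir()),
               "unknown experiment")
})

test_that("stability reports serialize to JSON", {
  rep <- classify_regime(neuron_params(10, 50, 100))
  js <- stability_report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$regime, "damped_oscillatory")
  expect_equal(parsed$tau3_crit_ms, 25 / 3, tolerance = 1e-9)
})

test_that("the command-line front end parses cleanly", {
  cli <- system.file("cli", "homeostab.R", package = "homeostab")
  expect_true(nzchar(cli))
  expect_silent(parse(cli))
})
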