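# Numerical experiments on the rate model: heterogeneity of time constants,
# input-noise amplification near the stability transition, and interference
# of homeostasis with an integrating network.

#' Critical recurrence under heterogeneous time constants
#'
#' For each coefficient of variation, draws per-neuron time constants from
#' gamma distributions (`trials` independent draws), builds the full
#' 3N-dimensional system on a fixed random weight matrix, and finds the
#' critical recurrence of every draw by bisection on the global scale of the
#' matrix (the per-mode reduction is unavailable once parameters differ
#' across neurons).  With `cv = 0` every draw reproduces the homogeneous
#' network exactly.
#'
#' @param spec a [heterogeneity_spec()]; its `cv` field is ignored in favour
#'   of `cvs`.
#' @param cvs coefficients of variation to sweep.
#' @param W fixed weight matrix (dominant eigenvalue is rescaled during the
#'   bisection); defaults to a symmetric Gaussian fixture.
#' @param tol bisection tolerance.
#' @return A data frame with columns `cv`, `mean_wc`, `sd_wc`, `trials`.
#' @export
heterogeneity_sweep <- function(spec, cvs = c(0, 0.1, 0.25, 0.5, 0.75, 1),
                                W = NULL, tol = 1e-5) {
  stopifnot(inherits(spec, "heterogeneity_spec"))
  if (is.null(W))
    W <- suppressWarnings(
      random_weight_matrix(spec$n, "symmetric_gaussian", target = 1))
  out <- lapply(cvs, function(cv) {
    sp <- spec; sp$cv <- cv
    wc <- vapply(seq_len(spec$trials), function(i) {
      net <- network_spec(W, draw_params(sp))
      critical_recurrence(net, tol = tol)
    }, numeric(1))
    data.frame(cv = cv, mean_wc = mean(wc), sd_wc = sd(wc),
               trials = spec$trials)
  })
  do.call(rbind, out)
}

#' Population-rate fluctuations versus recurrence
#'
#' Simulates a noisy homeostatic network over a grid of recurrence values
#' and measures the standard deviation of the population rate in the
#' steady-state window (the transient, at least `20 * max(tau)`, is
#' discarded).  Three conditions are reported: homeostasis with noise,
#' homeostasis without noise (fluctuations appear only beyond the critical
#' recurrence, where the instability drives sustained oscillations bounded
#' by rate rectification), and noise without homeostasis.
#'
#' @param params shared [neuron_params()].
#' @param noise a [noise_spec()].
#' @param recurrences recurrence grid.
#' @param n network size.
#' @param W fixed weight matrix; defaults to a symmetric Gaussian fixture,
#'   rescaled so its dominant eigenvalue equals each probed recurrence.
#' @param u_baseline constant external drive (keeps rates away from the
#'   rectification boundary in the stable regime).
#' @param duration,dt simulation length and step (ms).
#' @return A data frame with columns `recurrence`, `sd_homeo_noise`,
#'   `sd_homeo_nonoise`, `sd_nohomeo_noise`.
#' @export
fluctuation_vs_recurrence <- function(params, noise,
                                      recurrences = seq(0, 0.95, by = 0.05),
                                      n = 10, W = NULL, u_baseline = 2,
                                      duration = NULL, dt = 0.1) {
  stopifnot(inherits(params, "neuron_params"))
  if (is.null(W)) W <- suppressWarnings(
    random_weight_matrix(n, "symmetric_gaussian", target = 1))
  taumax <- max(params$tau1, params$tau2, params$tau3)
  transient <- 20 * taumax
  if (is.null(duration)) duration <- transient + 40 * taumax
  input <- input_protocol("constant", amplitude = u_baseline)

  one <- function(w, with_noise, with_homeo) {
    net <- network_spec(w * W, params)
    # noise-free runs start slightly off the fixed point so an unstable
    # system actually leaves the (unstable) equilibrium
    init <- if (with_noise) "fixed_point" else
      list(r1 = params$r_goal * 1.05, r2 = params$r_goal,
           r3 = rep(0, n))
    if (!with_noise) {
      xstar <- params$r_goal / params$alpha
      init$r3 <- as.numeric(w * W %*% rep(params$r_goal, n)) +
        u_baseline - xstar
    }
    traj <- simulate_rate(net, input,
                          noise = if (with_noise) noise else NULL,
                          duration = duration, dt = dt, record_dt = 1,
                          rectify = TRUE, homeostasis = with_homeo,
                          init = init)
    keep <- traj$time >= transient
    sd(traj$pop_rate[keep])
  }
  out <- lapply(recurrences, function(w) {
    data.frame(recurrence = w,
               sd_homeo_noise = one(w, TRUE, TRUE),
               sd_homeo_nonoise = one(w, FALSE, TRUE),
               sd_nohomeo_noise = one(w, TRUE, FALSE))
  })
  do.call(rbind, out)
}

#' Homeostatic interference with an integrating network
#'
#' Compares the response of an ideal leaky integrator (network mode with
#' time constant `tau_network`, no homeostasis) with the same mode under
#' homeostatic control with integrator time constant `tau3`, for a common
#' input protocol.  Fast homeostasis superimposes damped oscillations on the
#' integrator's response; only oscillation-free homeostasis (`tau3` beyond
#' [tau3_osc_free()]) approximates the ideal response.
#'
#' @param tau_network network mode time constant `tau1/(1-wm)` (ms).
#' @param tau3 homeostatic integrator time constant (ms).
#' @param input an [input_protocol()]; e.g. a pulse plus a biphasic pulse.
#' @param tau1,tau2 loop time constants (ms).
#' @param duration,dt simulation length and step (ms).
#' @return A list with `time`, `ideal`, `homeostatic` (population-rate
#'   deviations), the recurrence used, and the relative L2 `discrepancy`.
#' @export
integrator_interference <- function(tau_network, tau3, input,
                                    tau1 = 10, tau2 = 50,
                                    duration = 20000, dt = 0.1) {
  stopifnot(tau_network >= tau1)
  wm <- 1 - tau1 / tau_network
  params <- neuron_params(tau1, tau2, tau3, alpha = 1, r_goal = 0)
  run <- function(homeo)
    simulate_rate(params, input, recurrence = wm, duration = duration,
                  dt = dt, record_dt = 1, homeostasis = homeo,
                  init = "zero")
  ideal <- run(FALSE)
  homeo <- run(TRUE)
  nrm <- sqrt(sum(ideal$pop_rate^2))
  l2 <- sqrt(sum((homeo$pop_rate - ideal$pop_rate)^2)) / max(nrm, 1e-12)
  list(time = ideal$time, ideal = ideal$pop_rate,
       homeostatic = homeo$pop_rate, recurrence = wm, discrepancy = l2)
}
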