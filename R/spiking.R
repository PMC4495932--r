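#' Configuration of the homeostatic spiking network
#'
#' Leaky integrate-and-fire network with excitatory exponential-conductance
#' synapses and a homeostatic bias current: the population rate is filtered
#' (`tau2`) into a sensor `r2`, the rate error is accumulated by a perfect
#' integrator (`tau3`) into `r3`, and every neuron receives the bias
#' `-h * r3` (pA).  Units: time ms, voltage mV, current pA, conductance nS.
#'
#' The default size is a reduced network of 2000 neurons with the
#' connection probability raised so the mean in-degree (320) of the
#' full-size network (16000 neurons at 2% connectivity) is preserved; the
#' coupling knob `g_step` (conductance increment per presynaptic spike) is
#' the quantity calibrated against the rate model, with the default tuned
#' so the recurrence is about 0.6.  The synaptic reversal `E_e` uses the
#' standard AMPA-like value of 0 mV, making the synaptic current
#' `g_e * (E_e - V)` depolarizing.
#'
#' @param N number of neurons.
#' @param p_conn connection probability.
#' @param tau_mem membrane time constant (ms).
#' @param V_rest,V_thr,V_reset resting, threshold, reset potential (mV).
#' @param R membrane resistance (MOhm).
#' @param refractory absolute refractory period (ms).
#' @param tau_syn synaptic conductance decay time (ms).
#' @param E_e excitatory reversal potential (mV).
#' @param g_step conductance increment per spike (nS).
#' @param h bias-current gain (pA/Hz).
#' @param r_goal homeostatic target rate (Hz).
#' @param noise_sigma std of the independent Gaussian current noise (pA)
#'   each neuron receives per 0.5 ms step; for other `dt` the per-step
#'   sample is scaled as `1/sqrt(dt)` (white noise), keeping the membrane
#'   voltage diffusion independent of the integration step.  The noise
#'   desynchronises the population and smooths the f-I curve near
#'   rheobase.
#' @param tau2 sensor filter time constant (ms).
#' @param tau3 integrator time constant (ms).
#' @param dt integration step (ms).
#' @return An object of class `spiking_config`.
#' @export
spiking_config <- function(N = 2000, p_conn = 0.16, tau_mem = 20,
                           V_rest = -60, V_thr = -50, V_reset = V_rest,
                           R = 1, refractory = 5, tau_syn = 5, E_e = 0,
                           g_step = 0.026, h = 1, r_goal = 4,
                           noise_sigma = 75, tau2 = 50, tau3 = 200,
                           dt = 0.5) {
  stopifnot(N >= 1, p_conn > 0, p_conn <= 1, V_reset <= V_thr,
            all(c(tau_mem, tau_syn, tau2, tau3, dt, refractory) > 0))
  structure(list(N = as.integer(N), p_conn = p_conn, tau_mem = tau_mem,
                 V_rest = V_rest, V_thr = V_thr, V_reset = V_reset, R = R,
                 refractory = refractory, tau_syn = tau_syn, E_e = E_e,
                 g_step = g_step, h = h, r_goal = r_goal,
                 noise_sigma = noise_sigma, tau2 = tau2, tau3 = tau3,
                 dt = dt),
            class = "spiking_config")
}

# rheobase current of the isolated neuron (pA)
rheobase <- function(cfg) (cfg$V_thr - cfg$V_rest) / (cfg$R * 1e-3)

#' Simulate the homeostatic spiking network
#'
#' Forward-Euler integration of the LIF network defined by a
#' [spiking_config()].  The external drive (pA, shared by all neurons)
#' follows an [input_protocol()]; each neuron additionally receives
#' independent Gaussian current noise each step.  Membrane potentials are
#' initialised uniformly between reset and threshold to desynchronise the
#' population.
#'
#' @param cfg a [spiking_config()].
#' @param input an [input_protocol()] for the external current (pA).
#' @param homeostasis enable the bias-current feedback loop.
#' @param duration run length (ms).
#' @param tau3 override of `cfg$tau3` (ms).
#' @param g_step override of `cfg$g_step` (nS); 0 disconnects the network.
#' @param r3_init initial integrator value; `"auto"` starts near the
#'   operating point implied by the first drive value and the target rate,
#'   shortening the slow integrator transient.
#' @param record_dt resolution of the recorded rate traces (ms).
#' @param record_spikes keep individual spike times.
#' @param rate_cap population-rate bound (Hz) beyond which the run is
#'   truncated and flagged.
#' @return An object of class `spike_record`: `time`, traces `r2`, `r3`,
#'   `inst_rate`, a `spikes` data frame (if recorded), the config, and a
#'   `truncated` flag.
#' @export
simulate_spiking <- function(cfg, input, homeostasis = TRUE, duration = 10000,
                             tau3 = NULL, g_step = NULL, r3_init = "auto",
                             record_dt = 1, record_spikes = FALSE,
                             rate_cap = 2000) {
  stopifnot(inherits(cfg, "spiking_config"), inherits(input, "input_protocol"))
  if (!is.null(tau3)) cfg$tau3 <- tau3
  if (!is.null(g_step)) cfg$g_step <- g_step
  if (identical(r3_init, "auto")) {
    u0 <- protocol_eval(input, 0)
    if (homeostasis) {
      # mean recurrent current at the target rate, driving force at rest
      i_rec <- cfg$N * cfg$p_conn * cfg$g_step * (cfg$tau_syn * 1e-3) *
        cfg$r_goal * (cfg$E_e - cfg$V_rest)
      r3_init <- (u0 + i_rec - rheobase(cfg)) / cfg$h
    } else r3_init <- 0
  }
  stride <- max(1L, as.integer(round(record_dt / cfg$dt)))
  out <- spiking_sim_cpp(cfg$N, cfg$p_conn, cfg$tau_mem, cfg$V_rest, cfg$R,
                         cfg$V_thr, cfg$V_reset, cfg$refractory, cfg$tau_syn,
                         cfg$E_e, cfg$g_step, cfg$h, cfg$r_goal,
                         cfg$noise_sigma, input$times, input$values,
                         cfg$tau2, cfg$tau3, homeostasis, r3_init, cfg$dt,
                         duration, stride, record_spikes, rate_cap)
  spikes <- if (record_spikes)
    data.frame(time_ms = out$spike_time, neuron_id = out$spike_id)
  else NULL
  structure(list(time = as.numeric(out$time), r2 = as.numeric(out$r2),
                 r3 = as.numeric(out$r3),
                 inst_rate = as.numeric(out$inst_rate), spikes = spikes,
                 config = cfg, homeostasis = homeostasis,
                 truncated = out$truncated),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike record: N = %d, %.4g ms, final r2 = %.3g Hz%s\n",
              x$config$N, max(x$time), x$r2[length(x$r2)],
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

# adjust the external drive so the homeostasis-off baseline rate sits at
# the target rate (the operating point homeostasis itself would enforce)
find_operating_current <- function(cfg, g_step, I_start, target = cfg$r_goal,
                                   gain_guess = 0.3, iters = 5,
                                   probe_ms = 2500) {
  I <- I_start
  for (k in seq_len(iters)) {
    rec <- simulate_spiking(cfg, input_protocol("constant", amplitude = I),
                            homeostasis = FALSE, duration = probe_ms,
                            g_step = g_step, record_dt = 2)
    r <- mean(rec$inst_rate[rec$time > probe_ms / 3])
    if (abs(r - target) < 0.25) break
    I <- I - (r - target) / gain_guess
  }
  I
}

# cycle-averaged step response of the population rate (homeostasis off)
step_response <- function(cfg, g_step, I_base, I_step, cycles = 8,
                          half_period = 400, bin = 2) {
  times <- seq(0, by = half_period, length.out = 2 * cycles)
  vals <- rep(c(I_base, I_base + I_step), cycles)
  input <- input_protocol("samples", times = times, values = vals)
  rec <- simulate_spiking(cfg, input, homeostasis = FALSE,
                          duration = 2 * cycles * half_period,
                          g_step = g_step, record_dt = bin)
  nb <- as.integer(round(half_period / bin))
  grab <- function(onset) {
    idx <- which(rec$time > onset & rec$time <= onset + half_period)
    out <- rep(NA_real_, nb)
    idx <- idx[seq_len(min(length(idx), nb))]
    out[seq_along(idx)] <- rec$inst_rate[idx]
    out
  }
  on <- matrix(NA_real_, cycles - 1, nb)
  off <- matrix(NA_real_, cycles - 1, nb)
  for (cy in 2:cycles) { # discard the first cycle (initial transient)
    on[cy - 1, ] <- grab((2 * (cy - 1) + 1) * half_period)
    off[cy - 1, ] <- grab(2 * (cy - 1) * half_period)
  }
  list(t = seq_len(nb) * bin, rate = colMeans(on, na.rm = TRUE),
       rate_off = colMeans(off, na.rm = TRUE))
}

# shared-time-constant exponential fit of the onset and offset responses:
# tau is profiled on a log grid, amplitudes/offsets are linear per branch.
# A short running mean removes bin shot noise before fitting.
fit_step_tau <- function(t, y_on, y_off, skip_ms = 4, smooth_bins = 5) {
  if (smooth_bins > 1) {
    k <- rep(1 / smooth_bins, smooth_bins)
    sm <- function(y) as.numeric(stats::filter(y, k, sides = 2))
    y_on <- sm(y_on); y_off <- sm(y_off)
    ok <- !is.na(y_on) & !is.na(y_off)
    t <- t[ok]; y_on <- y_on[ok]; y_off <- y_off[ok]
  }
  keep <- t > skip_ms
  ts <- t[keep]
  sse_branch <- function(y, tau) {
    basis <- exp(-ts / tau)
    sum(stats::lm.fit(cbind(1, basis), y)$residuals^2)
  }
  taus <- exp(seq(log(2), log(2000), length.out = 200))
  sse <- vapply(taus, function(tau)
    sse_branch(y_on[keep], tau) + sse_branch(y_off[keep], tau), numeric(1))
  best <- which.min(sse)
  tot <- sum((y_on[keep] - mean(y_on[keep]))^2) +
    sum((y_off[keep] - mean(y_off[keep]))^2)
  list(tau = taus[best], r2 = 1 - sse[best] / tot)
}

#' Calibrate spiking-network recurrence against the rate model
#'
#' With homeostasis off, a small current step train is applied at each
#' coupling strength and the cycle-averaged population-rate response is
#' measured, with the baseline drive re-adjusted per coupling so the
#' operating point stays at the target rate.  In the rate model the
#' steady-state response to a step `dI` is `alpha * dI / (1 - wm)`, so the
#' ratio of the unconnected gain to the connected gain yields the
#' recurrence directly: `wm(g) = 1 - gain(0)/gain(g)`, anchored at `wm = 0`
#' for the unconnected network and diverging (`wm -> 1`) at the critical
#' coupling.  The equilibration time constant `tau1/(1 - wm)` is fitted
#' jointly on the step onset and offset branches with a shared time
#' constant; the unconnected fit provides the effective `tau1` and the fit
#' quality is checked against `min_r2`.  A linear map `wm = wm_per_g * g`
#' is then fitted through the origin.
#'
#' @param cfg a [spiking_config()].
#' @param g_grid coupling strengths to probe (nS); must start at 0.
#' @param I_base starting guess for the baseline drive (pA); defaults to
#'   slightly below rheobase.
#' @param I_step step size (pA), small against the width of the f-I knee.
#' @param cycles step repetitions averaged per coupling.
#' @param half_period half period of the step train (ms).
#' @param min_r2 minimum variance-explained of the unconnected
#'   equilibration fit; poorer fits raise an error (non-exponential
#'   response).  The default accounts for the slow intrinsic population
#'   fluctuations that cycle averaging cannot remove at these network
#'   sizes.
#' @return A list: `tau1` (ms, unconnected equilibration fit), `alpha_hat`
#'   (Hz/pA, unconnected gain), `wm_per_g` (recurrence per nS), the
#'   function `g_for_wm(wm)`, and the per-coupling table `fits` with
#'   columns `g_step`, `I_op`, `gain`, `wm`, `tau_eff`, `fit_r2`.
#' @export
calibrate_recurrence <- function(cfg, g_grid = seq(0, 0.008, by = 0.002),
                                 I_base = NULL, I_step = 5, cycles = 48,
                                 half_period = 252, min_r2 = 0.3) {
  if (is.null(I_base)) I_base <- rheobase(cfg) - 20
  if (g_grid[1] != 0) stop("g_grid must start at 0 (the wm = 0 anchor)",
                           call. = FALSE)
  fits <- lapply(g_grid, function(g) {
    I_op <- find_operating_current(cfg, g, I_base)
    sr <- step_response(cfg, g, I_op, I_step, cycles, half_period)
    late <- sr$t > 0.6 * max(sr$t)
    gain <- (mean(sr$rate[late]) - mean(sr$rate_off[late])) / I_step
    ft <- fit_step_tau(sr$t, sr$rate, sr$rate_off)
    data.frame(g_step = g, I_op = I_op, gain = gain,
               tau_eff = ft$tau, fit_r2 = ft$r2)
  })
  fits <- do.call(rbind, fits)
  fits$wm <- 1 - fits$gain[1] / fits$gain
  if (!is.finite(fits$tau_eff[1]))
    stop("calibration failure: non-exponential step response", call. = FALSE)
  if (fits$fit_r2[1] < min_r2)
    stop("calibration failure: poor equilibration fit (R2 < min_r2)",
         call. = FALSE)
  wm_per_g <- coef(lm(wm ~ 0 + g_step, data = fits))[[1]]
  list(tau1 = fits$tau_eff[1], alpha_hat = fits$gain[1],
       wm_per_g = wm_per_g,
       g_for_wm = function(wm) wm / wm_per_g, fits = fits)
}

#' Measure the f-I curve of the unconnected network
#'
#' With coupling and homeostasis off, the mean population rate is measured
#' for each drive on a grid, yielding a tabulated empirical f-I curve.  The
#' local slope `alpha` at the target-rate set-point and the envelope ratio
#' `beta` are extracted with [fi_envelope_slope()].  Small non-monotonic
#' wiggles from finite sampling are removed by a running maximum before the
#' curve is tabulated.
#'
#' @param cfg a [spiking_config()].
#' @param drives drive grid (pA); defaults to a range around rheobase.
#' @param duration per-point simulation length (ms).
#' @param transient discarded initial portion (ms).
#' @return A list: `curve` (an [fi_curve()], tabulated, in pA), `alpha`
#'   (Hz/pA), `beta`, `loop_gain` (`alpha * h`, dimensionless), and the
#'   measurement table.
#' @export
measure_fi <- function(cfg, drives = NULL, duration = 3000,
                       transient = 500) {
  if (is.null(drives)) {
    rb <- rheobase(cfg)
    drives <- rb + seq(-40, 60, by = 5)
  }
  rate <- vapply(drives, function(I) {
    rec <- simulate_spiking(cfg, input_protocol("constant", amplitude = I),
                            homeostasis = FALSE, duration = duration,
                            g_step = 0, record_dt = 1)
    keep <- rec$time >= transient
    mean(rec$inst_rate[keep])
  }, numeric(1))
  mono <- cummax(rate)
  curve <- fi_curve("tabulated", x = drives, y = mono)
  env <- fi_envelope_slope(curve, cfg$r_goal)
  list(curve = curve, alpha = env$alpha, beta = env$beta,
       loop_gain = env$alpha * cfg$h,
       data = data.frame(drive_pA = drives, rate_Hz = rate))
}

#' Homeostatic stability experiment on the spiking network
#'
#' Runs the connected network (coupling set for the requested recurrence
#' via a calibration) under a step-stimulus protocol for each integrator
#' time constant and labels the population-rate response with
#' [detect_regime_empirical()].  Oscillation amplitudes below
#' `min_amplitude` (well above the asynchronous shot-noise floor of the
#' filtered rate) count as stable.
#'
#' @param cfg a [spiking_config()].
#' @param tau3s integrator time constants to probe (ms).
#' @param wm target recurrence.
#' @param calib result of [calibrate_recurrence()]; `NULL` uses the
#'   config's default coupling as is.
#' @param I_base,I_step baseline drive and step amplitude (pA).
#' @param duration run length per condition (ms).
#' @param step_at step onset (ms).
#' @param min_amplitude oscillation amplitude floor for the detector (Hz).
#' @return A data frame with columns `tau3`, `regime`, `mean_rate`
#'   (post-step mean of the filtered rate, Hz) and `sd_rate`.
#' @export
stability_experiment <- function(cfg, tau3s, wm = 0.6, calib = NULL,
                                 I_base = NULL, I_step = 10,
                                 duration = 16000, step_at = 8000,
                                 min_amplitude = 1) {
  if (is.null(I_base)) I_base <- rheobase(cfg) - 15
  g <- if (is.null(calib)) cfg$g_step else calib$g_for_wm(wm)
  out <- lapply(tau3s, function(t3) {
    input <- input_protocol("step", amplitude = I_base + I_step,
                            onset = step_at, baseline = I_base)
    rec <- simulate_spiking(cfg, input, homeostasis = TRUE,
                            duration = duration, tau3 = t3, g_step = g,
                            record_dt = 2)
    late <- rec$time >= step_at + (duration - step_at) / 3
    regime <- detect_regime_empirical(rec$r2, rec$time,
                                      transient = step_at + 1000,
                                      smooth_ms = 10,
                                      min_amplitude = min_amplitude)
    data.frame(tau3 = t3, regime = regime,
               mean_rate = mean(rec$r2[late]), sd_rate = sd(rec$r2[late]))
  })
  do.call(rbind, out)
}
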