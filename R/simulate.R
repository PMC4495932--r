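#' Simulate the homeostatic rate model
#'
#' Fixed-step integration of
#' `tau1 dr1/dt = -r1 + g(V r1 + u(t) + eta(t) - r3)`,
#' `tau2 dr2/dt = -r2 + r1`, `tau3 dr3/dt = r2 - r_goal`,
#' for a single mode or a full network, with an arbitrary f-I curve `g`,
#' piecewise-constant input `u(t)` and optional Ornstein-Uhlenbeck input
#' noise `eta(t)`.  Deterministic runs use classic fourth-order Runge-Kutta;
#' noisy runs use Euler-Maruyama with the exact one-step noise update.
#' Runs that overflow (unstable linear systems) are truncated and flagged
#' rather than raising an error.
#'
#' @param system a [network_spec()] or [neuron_params()] object.  For
#'   `neuron_params` a single critical mode with the given `recurrence` is
#'   simulated.
#' @param input an [input_protocol()] object.
#' @param f an [fi_curve()]; `NULL` means the linear curve with the
#'   parameters' slope `alpha`.  Nonlinear curves receive the raw weight
#'   matrix `V = W/alpha`.
#' @param noise a [noise_spec()] or `NULL`.
#' @param recurrence mode recurrence when `system` is `neuron_params`.
#' @param duration run length (ms).
#' @param dt integration step (ms); a warning is given if
#'   `dt > min(tau)/10`.
#' @param record_dt recording resolution (ms, a multiple of `dt`).
#' @param rectify clip `r1` at zero after every step.
#' @param homeostasis if `FALSE` the threshold is frozen (no feedback).
#' @param hgain feedback gain on the threshold; `hgain = 0` with
#'   `homeostasis = TRUE` also disables the loop.
#' @param init `"fixed_point"`, `"zero"`, or a list with `r1`, `r2`, `r3`.
#' @return A `trajectory` object: `time` (ms), matrices `r1`, `r2`, `r3`
#'   (neurons x samples), `pop_rate`, the integration metadata, and a
#'   `truncated` flag.
#' @examples
#' traj <- simulate_rate(neuron_params(10, 50, 300),
#'                       input_protocol("step", 1, onset = 100),
#'                       duration = 2000)
#' @export
simulate_rate <- function(system, input, f = NULL, noise = NULL,
                          recurrence = 0, duration = 1000, dt = 0.1,
                          record_dt = NULL, rectify = FALSE,
                          homeostasis = TRUE, hgain = 1,
                          init = "fixed_point") {
  if (inherits(system, "neuron_params")) {
    net <- network_spec(matrix(recurrence, 1, 1), system)
  } else {
    stopifnot(inherits(system, "network_spec"))
    net <- system
  }
  n <- net$n
  p1 <- net$params[[1]]
  t1 <- vapply(net$params, `[[`, numeric(1), "tau1")
  t2 <- vapply(net$params, `[[`, numeric(1), "tau2")
  t3 <- vapply(net$params, `[[`, numeric(1), "tau3")
  alpha <- p1$alpha
  r_goal <- p1$r_goal

  if (is.null(f)) f <- fi_curve("linear", slope = alpha)
  V <- net$W / alpha
  if (dt > min(t1, t2, t3) / 10)
    warning("dt larger than min(tau)/10; integration may be inaccurate")

  stopifnot(inherits(input, "input_protocol"))
  fi <- fi_to_cpp(f)

  if (!homeostasis) hgain <- 0
  if (identical(init, "fixed_point")) {
    u0 <- protocol_eval(input, 0)
    r1 <- rep(r_goal, n); r2 <- rep(r_goal, n)
    r3 <- if (hgain != 0) {
      xstar <- fi_invert(f, r_goal)
      as.numeric(V %*% r1) + u0 - xstar
    } else rep(0, n)
  } else if (identical(init, "zero")) {
    r1 <- r2 <- r3 <- rep(0, n)
  } else {
    r1 <- rep_len(init$r1, n); r2 <- rep_len(init$r2, n)
    r3 <- rep_len(init$r3, n)
  }

  if (is.null(record_dt)) record_dt <- dt
  stride <- max(1L, as.integer(round(record_dt / dt)))
  nsteps <- as.integer(round(duration / dt))

  sig <- if (is.null(noise)) 0 else noise$sigma
  tauc <- if (is.null(noise)) 1 else noise$tau_corr

  out <- rate_sim_cpp(V, t1, t2, t3, r_goal, fi$kind, fi$par, fi$x, fi$y,
                      input$times, input$values, sig, tauc, dt, nsteps,
                      stride, rectify, hgain, hgain != 0, r1, r2, r3)
  if (out$truncated)
    warning("trajectory overflowed and was truncated (unstable run)")
  structure(list(time = as.numeric(out$time), r1 = out$r1, r2 = out$r2,
                 r3 = out$r3, pop_rate = colMeans(out$r1),
                 dt = dt, record_dt = record_dt, n = n,
                 params = net$params, truncated = out$truncated),
            class = "trajectory")
}

fi_to_cpp <- function(f) {
  empty <- numeric(0)
  switch(f$kind,
    linear = list(kind = 0L, par = unname(f$par), x = empty, y = empty),
    threshold_linear = list(kind = 1L, par = unname(f$par), x = empty,
                            y = empty),
    sigmoid = list(kind = 2L, par = unname(f$par), x = empty, y = empty),
    tabulated = list(kind = 3L, par = empty, x = f$x, y = f$y),
    custom = { # tabulate on a fine grid over the declared domain
      xs <- seq(f$domain[1], f$domain[2], length.out = 4001)
      list(kind = 3L, par = empty, x = xs, y = f$fn(xs))
    })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d neuron(s), %.4g ms at dt = %g ms%s\n",
              x$n, max(x$time), x$dt,
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  nt <- length(x$time)
  data.frame(t = rep(x$time, each = x$n),
             neuron = rep(seq_len(x$n), nt),
             r1 = as.vector(x$r1), r2 = as.vector(x$r2),
             r3 = as.vector(x$r3))
}

#' Empirical regime detection on a simulated response
#'
#' Classifies a population-rate time course after a transient as
#' `"monotone"` (fewer than two reversals of the derivative),
#' `"damped_oscillatory"` (decaying excursions) or
#' `"sustained_oscillation"` (late-window excursion amplitude at least
#' `ratio` times the early-window amplitude).  Reversals are counted with a
#' hysteresis of `tol` times the analysed range so small noise does not
#' register; an optional running-mean smoother suppresses spiking noise.
#' A window too short to hold several oscillation cycles is reported
#' `"inconclusive"`.
#'
#' @param x a `trajectory` object (its population rate is analysed) or a
#'   numeric vector of rate samples.
#' @param time sample times (ms) when `x` is a numeric vector.
#' @param transient initial portion to discard (ms); defaults to
#'   `20 * max(tau)` for trajectories.
#' @param smooth_ms running-mean window (ms), 0 for none.
#' @param ratio sustained-vs-damped amplitude ratio threshold.
#' @param tol hysteresis fraction of the range for counting reversals.
#' @param min_amplitude absolute excursion amplitude (rate units) below
#'   which a trace counts as non-oscillatory; raises the detector above a
#'   known measurement-noise floor (e.g. spiking shot noise).
#' @return One of `"monotone"`, `"damped_oscillatory"`,
#'   `"sustained_oscillation"`, `"inconclusive"`.
#' @export
detect_regime_empirical <- function(x, time = NULL, transient = NULL,
                                    smooth_ms = 0, ratio = 0.9, tol = 0.02,
                                    min_amplitude = 0) {
  if (inherits(x, "trajectory")) {
    if (is.null(transient)) {
      taus <- unlist(lapply(x$params, function(p) c(p$tau1, p$tau2, p$tau3)))
      transient <- 20 * max(taus)
    }
    time <- x$time
    x <- x$pop_rate
  }
  stopifnot(length(time) == length(x))
  if (is.null(transient)) transient <- 0
  keep <- time >= transient
  if (sum(keep) < 16) return("inconclusive")
  tt <- time[keep]; xx <- x[keep]
  dtr <- stats::median(diff(tt))
  if (smooth_ms > 0) {
    k <- max(1L, as.integer(round(smooth_ms / dtr)))
    if (k > 1) {
      xx <- stats::filter(xx, rep(1 / k, k), sides = 2)
      ok <- !is.na(xx)
      xx <- as.numeric(xx[ok]); tt <- tt[ok]
    }
  }
  rng <- max(xx) - min(xx)
  scale <- max(abs(xx), 1)
  if (rng < 1e-7 * scale || rng < 2 * min_amplitude) return("monotone")

  # reversal counting with hysteresis
  thr <- max(tol * rng, min_amplitude)
  dir <- 0L; rev <- 0L
  hi_v <- xx[1]; lo_v <- xx[1]
  rev_idx <- integer(0)
  for (i in seq_along(xx)) {
    v <- xx[i]
    if (v > hi_v) hi_v <- v
    if (v < lo_v) lo_v <- v
    if (dir >= 0 && hi_v - v > thr) {        # was rising, now falling
      if (dir == 1L) { rev <- rev + 1L; rev_idx <- c(rev_idx, i) }
      dir <- -1L; lo_v <- v
    } else if (dir <= 0 && v - lo_v > thr) { # was falling, now rising
      if (dir == -1L) { rev <- rev + 1L; rev_idx <- c(rev_idx, i) }
      dir <- 1L; hi_v <- v
    }
  }
  if (rev < 2L) return("monotone")

  period <- 2 * mean(diff(tt[rev_idx]))
  if (is.finite(period) && (max(tt) - min(tt)) < 5 * period)
    return("inconclusive")

  nq <- length(xx) %/% 4
  ref <- stats::median(xx[(length(xx) - 2 * nq):length(xx)])
  dev <- abs(xx - ref)
  a_early <- max(dev[seq_len(nq)])
  a_late <- max(dev[(length(xx) - nq + 1):length(xx)])
  if (a_late >= ratio * a_early && a_late > max(thr, min_amplitude))
    "sustained_oscillation"
  else "damped_oscillatory"
}
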