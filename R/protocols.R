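#' External input protocols
#'
#' Builds the time course `u(t)` of the external drive as a piecewise
#' constant function.  Kinds:
#' \describe{
#'   \item{`constant`}{`amplitude` for the whole run.}
#'   \item{`step`}{0 until `onset`, then `amplitude` (until `offset` if
#'     finite).}
#'   \item{`biphasic_pulse`}{a positive pulse of `amplitude` on
#'     `[onset, onset + width]` and a negative one on
#'     `[offset, offset + width]`.}
#'   \item{`samples`}{explicit breakpoints: `times` (ms, non-decreasing) and
#'     `values`, held zero-order.}
#' }
#'
#' @param kind protocol kind.
#' @param amplitude drive amplitude (rate units).
#' @param onset,offset,width times in ms.
#' @param times,values explicit breakpoints for `kind = "samples"`.
#' @param baseline value before the first breakpoint / outside pulses.
#' @return An object of class `input_protocol` with fields `times`, `values`.
#' @examples
#' input_protocol("step", amplitude = 1, onset = 100)
#' @export
input_protocol <- function(kind = c("constant", "step", "biphasic_pulse",
                                    "samples"),
                           amplitude = 1, onset = 0, offset = Inf,
                           width = 500, times = NULL, values = NULL,
                           baseline = 0) {
  kind <- match.arg(kind)
  pc <- switch(kind,
    constant = list(times = 0, values = amplitude),
    step = {
      tt <- c(0, onset); vv <- c(baseline, amplitude)
      if (is.finite(offset)) { tt <- c(tt, offset); vv <- c(vv, baseline) }
      list(times = tt, values = vv)
    },
    biphasic_pulse = list(
      times = c(0, onset, onset + width, offset, offset + width),
      values = c(baseline, baseline + amplitude, baseline,
                 baseline - amplitude, baseline)),
    samples = {
      if (is.null(times) || is.null(values) || length(times) != length(values))
        stop("samples need matching times and values", call. = FALSE)
      if (is.unsorted(times)) stop("times must be non-decreasing", call. = FALSE)
      list(times = as.numeric(times), values = as.numeric(values))
    })
  if (any(!is.finite(pc$values)))
    stop("amplitudes must be finite", call. = FALSE)
  structure(c(pc, list(kind = kind)), class = "input_protocol")
}

#' Evaluate an input protocol at given times
#'
#' Zero-order-hold evaluation of `u(t)`, mirroring the convention used by
#' the integrators (the value is 0 before the first breakpoint).
#'
#' @param p an [input_protocol()].
#' @param t times (ms).
#' @return Drive values at `t`.
#' @export
protocol_eval <- function(p, t) {
  idx <- findInterval(t, p$times)
  out <- rep(0, length(t))
  out[idx > 0] <- p$values[idx[idx > 0]]
  out
}

#' Ornstein-Uhlenbeck input-noise specification
#'
#' Additive Gaussian input noise with stationary standard deviation `sigma`
#' (rate units) and correlation time `tau_corr` (ms).  The process is
#' advanced with its exact one-step update (exponential decay plus a scaled
#' Gaussian increment), so the stationary variance is independent of the
#' integration step.
#'
#' @param sigma stationary standard deviation (rate units).
#' @param tau_corr correlation time (ms).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.1, tau_corr = 1) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (tau_corr <= 0) stop("tau_corr must be > 0", call. = FALSE)
  structure(list(sigma = sigma, tau_corr = tau_corr), class = "noise_spec")
}

#' Heterogeneity specification for network time constants
#'
#' Per-neuron time constants are drawn from gamma distributions with the
#' given means and a common coefficient of variation
#' (shape `1/CV^2`, scale `mean * CV^2`); `CV = 0` yields the degenerate
#' (homogeneous) case.
#'
#' @param means named or positional means of `(tau1, tau2, tau3)` in ms.
#' @param cv coefficient of variation (`>= 0`).
#' @param n number of neurons.
#' @param trials number of independent draws.
#' @return An object of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(means = c(10, 50, 100), cv = 0, n = 10,
                               trials = 100) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  stopifnot(length(means) == 3, all(means > 0), n >= 1, trials >= 1)
  structure(list(means = as.numeric(means), cv = cv, n = n, trials = trials),
            class = "heterogeneity_spec")
}

# one draw of per-neuron parameters under a heterogeneity spec
draw_params <- function(spec, alpha = 1, r_goal = 1) {
  draw1 <- function(mean) {
    if (spec$cv == 0) return(rep(mean, spec$n))
    rgamma(spec$n, shape = 1 / spec$cv^2, scale = mean * spec$cv^2)
  }
  t1 <- draw1(spec$means[1]); t2 <- draw1(spec$means[2])
  t3 <- draw1(spec$means[3])
  lapply(seq_len(spec$n), function(i)
    neuron_params(t1[i], t2[i], t3[i], alpha = alpha, r_goal = r_goal))
}
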