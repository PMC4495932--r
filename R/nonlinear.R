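# Sector-based (Aizerman) global stability criteria for nonlinear f-I
# curves.  The local slope alpha at the set-point is replaced by the slope
# of the steepest line through the set-point enveloping the curve; the
# resulting bound certifies stability against arbitrary-size perturbations
# (sufficiency only -- the criterion is not claimed tight).

#' Global (sector) integrator bound for a single nonlinear neuron
#'
#' Integrator time constant above which the three-stage loop of a single
#' neuron with f-I curve `f` is globally stable:
#' `tau3 >= max(g~(x)/x) * tau1*tau2/(tau1 + tau2)`, with `g~` the curve
#' re-centered on the set-point.  For a linear curve this coincides with
#' [tau3_min_single()]; for any curve whose envelope exceeds the tangent
#' (`beta > 1`) it is strictly larger.
#'
#' @param f an [fi_curve()] object.
#' @param tau1,tau2 rate-filter and sensor time constants (ms).
#' @param r_goal target rate (Hz).
#' @return `tau3` bound in ms (`Inf`, with a warning, if the envelope ratio
#'   is unbounded).
#' @examples
#' f <- fi_curve("custom", fn = function(x) x^2, domain = c(0, 2))
#' aizerman_tau3_single(f, 10, 50, r_goal = 1)  # 3 * 500/60 = 25 ms
#' @export
aizerman_tau3_single <- function(f, tau1, tau2, r_goal) {
  env <- fi_envelope_slope(f, r_goal)
  env$max_ratio * tau1 * tau2 / (tau1 + tau2)
}

#' Sector condition check for a homeostatic loop
#'
#' Verifies the sector inequality `0 < g~(x)/x < tau3/tau3_0` over a dense
#' sample of the curve's domain, where `tau3_0` is the single-neuron linear
#' bound.  The strict lower bound is enforced as `g~(x) * x > 0` wherever
#' `g~(x) != 0`: a flat segment of the re-centered curve through zero
#' (ratio tending to zero from above) is tolerated, since rectified rates
#' make the strict inequality unattainable below threshold.
#'
#' @param f an [fi_curve()] object.
#' @param params a [neuron_params()] object supplying `tau1`, `tau2`,
#'   `tau3` and `r_goal`.
#' @param n number of sample points.
#' @return `TRUE` iff the sector condition holds on the sampled domain.
#' @export
sector_check <- function(f, params, n = 4001) {
  lin <- fi_linearize(f, params$r_goal)
  xstar <- lin$set_point_input
  upper <- params$tau3 / tau3_min_single(params$tau1, params$tau2, 1)
  d <- seq(f$domain[1] - xstar, f$domain[2] - xstar, length.out = n)
  d <- d[abs(d) > 1e-9 * max(1, diff(f$domain))]
  gt <- fi_eval(f, xstar + d) - params$r_goal
  ratio <- gt / d
  nonzero <- abs(gt) > 1e-12 * max(1, max(abs(gt)))
  all(ratio[nonzero] > 0) && all(ratio < upper)
}

#' Global (sector) integrator bound for a network mode
#'
#' Per-mode Aizerman bound for a network with recurrence `wm`:
#' `tau3 >= alpha*beta/(1 - beta*wm) * tau1*tau2/(tau1 + (1-beta*wm)*tau2)`
#' where `beta = max(g~(x)/x)/alpha` is the envelope-to-tangent ratio of the
#' f-I curve.  With `beta = 1` this reduces to the linear network bound
#' [tau3_crit_network()].  Applying the three-dimensional sector criterion
#' mode-by-mode assumes the eigenmodes couple at most weakly through the
#' nonlinearity; the result is flagged as heuristic accordingly.
#'
#' @inheritParams aizerman_tau3_single
#' @param wm network recurrence; requires `beta * wm < 1`.
#' @return A list: `tau3` (ms; `Inf` if `beta*wm >= 1`, meaning no finite
#'   bound exists), `alpha`, `beta`, and `heuristic = TRUE`.
#' @export
aizerman_tau3_network <- function(f, tau1, tau2, wm, r_goal) {
  env <- fi_envelope_slope(f, r_goal)
  beta <- env$beta
  alpha <- env$alpha
  if (beta * wm >= 1) {
    warning("beta * wm >= 1: no finite sector bound for this mode")
    t3 <- Inf
  } else {
    t3 <- alpha * beta / (1 - beta * wm) *
      tau1 * tau2 / (tau1 + (1 - beta * wm) * tau2)
  }
  list(tau3 = t3, alpha = alpha, beta = beta, heuristic = TRUE)
}
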