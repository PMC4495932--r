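# Two integral controllers acting in parallel on the same error signal.

#' Spectrum of a mode with two parallel integral controllers
#'
#' Two perfect integrators (time constants `params$tau3` and `tau3b`) read
#' the same sensor error and their outputs sum into the threshold.  The
#' division of labour between the loops is unobservable, so the 4x4 mode
#' matrix carries one structural zero eigenvalue; it is identified, checked
#' against `tol`, and excluded before the regime is classified.  The
#' remaining three eigenvalues equal those of a single controller with the
#' harmonically combined integrator time constant
#' `tau_eff = 1 / (1/tau3 + 1/tau3b)` -- the quicker loop dominates, and a
#' second loop can only lower the effective time constant, never raise it.
#'
#' @param params a [neuron_params()] object (its `tau3` is the first loop).
#' @param tau3b integrator time constant of the second loop (ms).
#' @param recurrence mode eigenvalue of the gain-scaled weight matrix.
#' @param tol tolerance for locating the structural zero eigenvalue (1/ms).
#' @return A list with `eigenvalues` (the three non-structural ones),
#'   `zero_eigenvalue`, `tau_eff`, and a `stability_report` in `report`.
#' @export
parallel_controller_spectrum <- function(params, tau3b, recurrence = 0,
                                         tol = 1e-9) {
  m <- build_parallel_matrix(params, tau3b, recurrence)
  ev <- eigen(unclass(m), only.values = TRUE)$values
  iz <- which.min(Mod(ev))
  if (Mod(ev[iz]) > 1e-6 * max(Mod(ev)) + tol)
    warning("structural zero eigenvalue not found within tolerance")
  tau_eff <- 1 / (1 / params$tau3 + 1 / tau3b)
  peff <- params
  peff$tau3 <- tau_eff
  rep <- report_from_spectrum(ev[-iz], peff, recurrence, tol,
                              method = "4x4 parallel-controller matrix")
  list(eigenvalues = ev[-iz], zero_eigenvalue = ev[iz],
       tau_eff = tau_eff, report = rep)
}

#' Maximum recurrence with parallel controllers
#'
#' Largest recurrence for which the mode with two parallel integral
#' controllers stays stable.  Equals the single-controller critical
#' recurrence evaluated at the harmonically combined integrator time
#' constant, so it never exceeds the single-controller value and approaches
#' it as `tau3b -> Inf`.
#'
#' @inheritParams parallel_controller_spectrum
#' @return Critical recurrence (dimensionless).
#' @export
parallel_max_recurrence <- function(params, tau3b) {
  peff <- params
  peff$tau3 <- 1 / (1 / params$tau3 + 1 / tau3b)
  critical_recurrence(peff)
}
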