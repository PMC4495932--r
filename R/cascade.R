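# Multi-stage homeostatic feedback cascades: characteristic polynomial,
# roots, and the largest recurrence the surrounding network tolerates.

# ascending coefficients of 1 + l*tauK*(1 - wm + l*tau1) prod(1 + l*tauk)
cascade_coeffs <- function(taus, wm = 0) {
  k <- length(taus)
  p <- c(1 - wm, taus[1])
  if (k > 2) for (tk in taus[2:(k - 1)]) p <- poly_mul(p, c(1, tk))
  c(1, taus[k] * p)
}

#' Roots of a homeostatic cascade's characteristic polynomial
#'
#' For a cascade of `K` first-order stages (rate filter, `K-2` relay
#' filters, perfect integrator) inside a network with recurrence `wm`, the
#' characteristic polynomial is
#' `1 + l*tauK*(1 - wm + l*tau1) * prod_{k=2}^{K-1} (1 + l*tauk)`, of degree
#' `K`.  The coefficients are expanded by exact convolution of the linear
#' factors and all roots computed at once; the root multiset is invariant
#' under permutation of the intermediate time constants `tau2..tau(K-1)`.
#'
#' @param spec a [cascade_spec()] object.
#' @return Complex vector of the `K` eigenvalues (1/ms).
#' @examples
#' cascade_roots(cascade_spec(c(10, 50, 100)))
#' @export
cascade_roots <- function(spec) {
  stopifnot(inherits(spec, "cascade_spec"))
  poly_roots(cascade_coeffs(spec$taus, spec$recurrence))
}

#' Maximum recurrence tolerated by a feedback cascade
#'
#' Largest network recurrence `wm` for which every root of the cascade
#' polynomial stays in the closed left half-plane, found by bisection on
#' `[0, 1]`.  A two-stage cascade (sensor feeding the integrator directly)
#' tolerates the full recurrence `wm = 1` of the homeostasis-free network;
#' any additional finite stage strictly reduces the tolerated recurrence.
#'
#' @param taus ordered cascade time constants (ms), `K >= 2`.
#' @param tol bisection tolerance on `wm`.
#' @return Maximum recurrence (dimensionless, in `[0, 1]`).
#' @examples
#' cascade_max_recurrence(c(10, 50))       # 1: two stages never destabilize
#' cascade_max_recurrence(c(10, 50, 50))   # about 0.642
#' @export
cascade_max_recurrence <- function(taus, tol = 1e-6) {
  taus <- as.numeric(taus)
  if (length(taus) < 2 || any(taus <= 0))
    stop("need K >= 2 positive time constants", call. = FALSE)
  stable_at <- function(w)
    max(Re(poly_roots(cascade_coeffs(taus, w)))) <= 1e-9
  if (stable_at(1)) return(1)
  lo <- 0; hi <- 1
  if (!stable_at(0)) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stable_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sweep cascade depth against tolerated recurrence
#'
#' Evaluates [cascade_max_recurrence()] for truncations of a time-constant
#' schedule at depths `2..K`, as used to compare linear, constant and
#' exponential cascade schedules.
#'
#' @param taus full schedule of time constants (ms).
#' @return A data frame with columns `K` and `max_recurrence`.
#' @export
cascade_depth_sweep <- function(taus) {
  ks <- 2:length(taus)
  data.frame(K = ks,
             max_recurrence = vapply(ks, function(k)
               cascade_max_recurrence(taus[seq_len(k)]), numeric(1)))
}
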