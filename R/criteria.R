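#' Critical integrator time constant for a single neuron
#'
#' Smallest integrator time constant for which the three-stage homeostatic
#' loop of a single (unconnected) neuron is stable:
#' `tau3_0 = alpha * tau1 * tau2 / (tau1 + tau2)`.  Faster integration
#' (smaller `tau3`) makes the loop unstable, producing sustained rate
#' oscillations.
#'
#' @param tau1,tau2 time constants of the rate filter and activity sensor (ms).
#' @param alpha slope of the f-I curve at the set-point.
#' @return Critical `tau3` in ms.
#' @examples
#' tau3_min_single(10, 50)  # 25/3 ms
#' @export
tau3_min_single <- function(tau1, tau2, alpha = 1) {
  check_pos(tau1, tau2, alpha)
  alpha * tau1 * tau2 / (tau1 + tau2)
}

#' Critical integrator time constant for a recurrent network mode
#'
#' Routh-Hurwitz stability boundary of the critical eigenmode of a recurrent
#' network with recurrence `wm` (largest real eigenvalue of the gain-scaled
#' weight matrix):
#' `tau3_crit = alpha/(1-wm) * tau1*tau2 / (tau1 + (1-wm)*tau2)`.
#' At `wm = 0` this reduces to [tau3_min_single()].  The bound grows with
#' the network time constant `tau1/(1-wm)`: strongly recurrent networks
#' need much slower homeostasis.
#'
#' @inheritParams tau3_min_single
#' @param wm recurrence of the network (`< 1`).
#' @return Critical `tau3` in ms.
#' @examples
#' tau3_crit_network(10, 50, 1, 0.99)   # ~4.8 s for a 1 s network
#' @export
tau3_crit_network <- function(tau1, tau2, alpha = 1, wm = 0) {
  check_pos(tau1, tau2, alpha)
  if (any(wm >= 1))
    stop("wm must be < 1: the network is unstable without homeostasis",
         call. = FALSE)
  alpha / (1 - wm) * tau1 * tau2 / (tau1 + (1 - wm) * tau2)
}

#' Critical integrator time constant for a complex network eigenmode
#'
#' Stability boundary of a mode whose gain-scaled weight-matrix eigenvalue is
#' complex, `w = wr + 1i*wi` (non-symmetric networks; unit loop gain).  The
#' boundary is located where the characteristic cubic
#' `l^3 + c1 l^2 + c2 l + c3` (with `c1 = 1/tau2 + (1-w)/tau1`,
#' `c2 = (1-w)/(tau1*tau2)`, `c3 = 1/(tau1*tau2*tau3)`) acquires a purely
#' imaginary root: eliminating the crossing frequency from the real and
#' imaginary parts gives a quadratic in the frequency and a closed-form
#' critical `tau3` for each admissible crossing; the binding (largest) value
#' is returned.  At `wi = 0` this reduces exactly to [tau3_crit_network()]
#' with `alpha = 1`; for `wi -> Inf` it approaches `tau2/(1-wr)`, the bound
#' that guarantees stability for arbitrary complex eigenvalues.
#'
#' @inheritParams tau3_crit_network
#' @param wr,wi real and imaginary part of the mode eigenvalue (`wr < 1`).
#' @return Critical `tau3` in ms.
#' @export
tau3_crit_complex <- function(tau1, tau2, wr = 0, wi = 0) {
  check_pos(tau1, tau2)
  if (wr >= 1) stop("wr must be < 1", call. = FALSE)
  c1r <- 1 / tau2 + (1 - wr) / tau1
  c1i <- -wi / tau1
  c2r <- (1 - wr) / (tau1 * tau2)
  c2i <- -wi / (tau1 * tau2)
  disc <- c1i^2 + 4 * c2r
  # numerically stable quadratic roots (avoid cancellation at large |wi|)
  om1 <- (-c1i - sign(c1i + (c1i == 0)) * sqrt(disc)) / 2
  om <- c(om1, -c2r / om1)
  cand <- c1r * om^2 + c2i * om
  cand <- cand[cand > 0]
  if (!length(cand)) stop("no imaginary-axis crossing found", call. = FALSE)
  max(1 / (tau1 * tau2 * cand))
}

# ascending coefficients of the critical-mode characteristic polynomial
# (1 - wm + tau1*l)(1 + tau2*l) tau3*l + alpha
mode_poly_coeffs <- function(tau1, tau2, tau3, alpha = 1, wm = 0) {
  c(alpha, (1 - wm) * tau3, (tau1 + (1 - wm) * tau2) * tau3,
    tau1 * tau2 * tau3)
}

# discriminant of a real cubic given ascending coefficients c(d, c, b, a)
cubic_discriminant <- function(co) {
  d <- co[1]; cc <- co[2]; b <- co[3]; a <- co[4]
  18 * a * b * cc * d - 4 * b^3 * d + b^2 * cc^2 - 4 * a * cc^3 -
    27 * a^2 * d^2
}

#' Minimal integrator time constant for oscillation-free homeostasis
#'
#' Smallest `tau3` for which all three roots of the critical-mode
#' characteristic polynomial `(1 - wm + tau1*l)(1 + tau2*l)*tau3*l + 1` are
#' real, so the response to perturbations shows no (even damped) ringing.
#' The boundary is located numerically as the zero of the cubic's
#' discriminant in `tau3` (bisection to `tol` relative accuracy), which is
#' robust for all parameter values including the removable singularity of
#' the closed form at `tau1 = (1-wm)*tau2`; the closed form
#' [tau3_osc_free_closed()] is available as a cross-check.  In the
#' strong-recurrence limit the bound behaves as `4*tau1/(1-wm)^2`, i.e. it
#' scales quadratically with the network time constant `tau1/(1-wm)`.
#'
#' @inheritParams tau3_crit_network
#' @param tol relative bisection tolerance.
#' @return Minimal oscillation-free `tau3` in ms (unit loop gain; for gain
#'   `alpha` multiply the result by `alpha`).
#' @examples
#' tau3_osc_free(10, 50)  # about 221.5 ms
#' @export
tau3_osc_free <- function(tau1, tau2, wm = 0, tol = 1e-6) {
  check_pos(tau1, tau2)
  if (wm >= 1) stop("wm must be < 1", call. = FALSE)
  disc <- function(t3) cubic_discriminant(mode_poly_coeffs(tau1, tau2, t3,
                                                           1, wm))
  lo <- tau3_crit_network(tau1, tau2, 1, wm)
  if (disc(lo) > 0) return(lo)      # degenerate: real already at the boundary
  hi <- lo
  for (i in 1:60) {
    hi <- hi * 4
    if (disc(hi) > 0) break
  }
  if (disc(hi) <= 0) stop("no all-real-roots boundary found", call. = FALSE)
  while (hi / lo - 1 > tol) {
    mid <- sqrt(lo * hi)
    if (disc(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Closed form of the oscillation-free boundary
#'
#' Closed-form expression for [tau3_osc_free()], obtained from the condition
#' that the local minimum of the characteristic cubic dips below zero.  With
#' `tau2p = (1-wm)*tau2`:
#' \deqn{\tau_3 = \frac{(\tau_1 - 2\tau_2')(2\tau_1 - \tau_2')(\tau_1 +
#'   \tau_2') + 2(\tau_1^2 - \tau_1\tau_2' + \tau_2'^2)^{3/2}}
#'   {(1-w_m)^2 (\tau_1 - \tau_2')^2}.}
#' The expression has a removable singularity at `tau1 = tau2p`; use
#' [tau3_osc_free()] near that point.
#'
#' @inheritParams tau3_crit_network
#' @return Minimal oscillation-free `tau3` in ms (unit loop gain).
#' @export
tau3_osc_free_closed <- function(tau1, tau2, wm = 0) {
  check_pos(tau1, tau2)
  t2p <- (1 - wm) * tau2
  num <- (tau1 - 2 * t2p) * (2 * tau1 - t2p) * (tau1 + t2p) +
    2 * (tau1^2 - tau1 * t2p + t2p^2)^1.5
  num / ((1 - wm)^2 * (tau1 - t2p)^2)
}

#' Classify the homeostatic regime of one mode
#'
#' Computes the eigenvalues of the 3x3 single-mode matrix and classifies the
#' response as `"stable"` (all eigenvalues real and negative),
#' `"damped_oscillatory"` (stable with a complex pair) or `"unstable"`
#' (an eigenvalue with positive real part, leading in practice to sustained
#' rate oscillations).  Eigenvalues within `tol` (1/ms) of the imaginary
#' axis are flagged as marginal rather than silently binned.
#'
#' @param params a [neuron_params()] object.
#' @param recurrence mode eigenvalue of the gain-scaled weight matrix.
#' @param tol classification tolerance on real and imaginary parts (1/ms).
#' @return An object of class `stability_report`: regime, marginal flag,
#'   dominant eigenvalue, full spectrum, both critical `tau3` values
#'   (sustained-oscillation and oscillation-free boundaries) and the method
#'   that produced each number.
#' @examples
#' classify_regime(neuron_params(10, 50, 100))  # damped oscillations
#' @export
classify_regime <- function(params, recurrence = 0, tol = 1e-9) {
  stopifnot(inherits(params, "neuron_params"))
  m <- build_single_mode_matrix(params, recurrence)
  ev <- eigen(unclass(m), only.values = TRUE)$values
  report_from_spectrum(ev, params, recurrence, tol,
                       method = "eigenvalues of the 3x3 mode matrix")
}

report_from_spectrum <- function(ev, params, recurrence, tol = 1e-9,
                                 method = "spectrum") {
  dom <- ev[which.max(Re(ev))]
  maxre <- max(Re(ev))
  oscil <- any(abs(Im(ev)) > tol)
  regime <- if (maxre > tol) "unstable"
            else if (oscil) "damped_oscillatory" else "stable"
  t3c <- if (recurrence < 1)
    tau3_crit_network(params$tau1, params$tau2, params$alpha, recurrence)
  else Inf
  t3o <- if (recurrence < 1)
    params$alpha * tau3_osc_free(params$tau1, params$tau2, recurrence)
  else Inf
  structure(list(regime = regime, marginal = abs(maxre) <= tol,
                 dominant_eigenvalue = dom, eigenvalues = ev,
                 tau3_crit = t3c, tau3_osc_free = t3o,
                 params = params, recurrence = recurrence,
                 method = c(regime = method,
                            tau3_crit = "Routh-Hurwitz closed form",
                            tau3_osc_free = "discriminant bisection")),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("regime: %s%s\n", x$regime,
              if (isTRUE(x$marginal)) " (marginal)" else ""))
  cat(sprintf("dominant eigenvalue: %.6g %+.6gi 1/ms\n",
              Re(x$dominant_eigenvalue), Im(x$dominant_eigenvalue)))
  cat(sprintf("tau3 critical: %.6g ms, oscillation-free: %.6g ms\n",
              x$tau3_crit, x$tau3_osc_free))
  invisible(x)
}

#' Critical recurrence of a homeostatic mode or network
#'
#' The critical recurrence `w_c` is the largest recurrence for which the
#' homeostatic system is still stable (damped oscillations allowed), i.e.
#' where the real part of its dominant eigenvalue crosses zero.  Without
#' homeostatic feedback `w_c = 1`; homeostasis lowers it.
#'
#' For a [neuron_params()] object the Routh-Hurwitz boundary is inverted in
#' closed form (quadratic in `1 - w`).  For a [network_spec()] the full
#' 3N-dimensional spectrum is examined (required for heterogeneous
#' parameters, where the per-mode reduction is unavailable) while bisecting
#' a global scale factor applied to `W`; the returned value is the largest
#' real part of the eigenvalues of the rescaled weight matrix at the
#' crossing.
#'
#' @param x a [neuron_params()] or [network_spec()] object.
#' @param feedback if `FALSE` the homeostatic feedback is removed
#'   (threshold gain set to zero), in which case the critical recurrence is 1.
#' @param tol relative bisection tolerance (network method).
#' @param ... passed to methods.
#' @return Critical recurrence (dimensionless).
#' @export
critical_recurrence <- function(x, ...) UseMethod("critical_recurrence")

#' @rdname critical_recurrence
#' @export
critical_recurrence.neuron_params <- function(x, feedback = TRUE, ...) {
  if (!feedback) return(1)
  a <- x$tau2 * x$tau3
  b <- x$tau1 * x$tau3
  cc <- -x$alpha * x$tau1 * x$tau2
  q <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  1 - q
}

#' @rdname critical_recurrence
#' @export
critical_recurrence.network_spec <- function(x, feedback = TRUE, tol = 1e-6,
                                             ...) {
  wtop <- max(Re(eigen(x$W, only.values = TRUE)$values))
  if (wtop <= 0) stop("W must have an eigenvalue with positive real part",
                      call. = FALSE)
  stable_at <- function(s) {
    net <- x
    net$W <- (s / wtop) * x$W
    m <- unclass(build_network_matrix(net))
    if (!feedback) {
      # drop the integrator rows: without feedback they only contribute
      # structural zero eigenvalues
      keep <- seq_len(2 * x$n)
      m <- m[keep, keep]
    }
    max(Re(eigen(m, only.values = TRUE)$values)) < 0
  }
  lo <- 0; hi <- 2
  # a heterogeneous draw can be unstable even without coupling (some loop
  # has tau3 below its own single-neuron bound): critical recurrence 0
  if (!stable_at(lo + 1e-9)) return(0)
  if (stable_at(hi)) stop("no instability bracket found in [0, 2]",
                          call. = FALSE)
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (stable_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

check_pos <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("parameters must be positive and finite", call. = FALSE)
  invisible(TRUE)
}
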