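#' Parameters of one homeostatic control loop
#'
#' Bundles the time constants and gains that define a single three-stage
#' homeostatic loop: the firing-rate filter (`tau1`), the activity sensor
#' (`tau2`), the perfect-integrator threshold controller (`tau3`), the slope
#' `alpha` of the f-I curve at the set-point, and the target rate `r_goal`.
#'
#' All time constants are in ms, rates in Hz.  The conversion constant
#' `gamma` between the integrator output (a rate) and the threshold
#' (a current) is kept explicit for unit bookkeeping but fixed at 1, so the
#' equations are written in dimensionless units: scaling `alpha` by a factor
#' is equivalent to scaling `tau3` down by the same factor.
#'
#' @param tau1 time constant of the firing-rate dynamics (ms).
#' @param tau2 time constant of the activity sensor (ms).
#' @param tau3 integrator time constant of the threshold update (ms).
#' @param alpha slope of the f-I curve at the set-point (dimensionless).
#' @param r_goal target firing rate (Hz).
#' @param gamma rate-to-current conversion constant; fixed at 1 unless
#'   explicitly overridden.
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params(tau1 = 10, tau2 = 50, tau3 = 100)
#' @export
neuron_params <- function(tau1 = 10, tau2 = 50, tau3 = 100,
                          alpha = 1, r_goal = 1, gamma = 1) {
  stopifnot(is.numeric(tau1), is.numeric(tau2), is.numeric(tau3))
  if (any(c(tau1, tau2, tau3) <= 0))
    stop("all time constants must be > 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (r_goal < 0) stop("r_goal must be >= 0", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, tau3 = tau3,
                 alpha = alpha, r_goal = r_goal, gamma = gamma),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "homeostatic loop: tau1 = %g ms, tau2 = %g ms, tau3 = %g ms, alpha = %g, r_goal = %g Hz\n",
    x$tau1, x$tau2, x$tau3, x$alpha, x$r_goal))
  invisible(x)
}

#' Specification of a homeostatic feedback cascade
#'
#' An ordered list of `K >= 2` first-order stages: the first time constant
#' belongs to the firing-rate filter, intermediate ones to relay stages, and
#' the last to the perfect integrator that sets the threshold.
#'
#' @param taus ordered time constants (ms); length gives the cascade depth K.
#' @param recurrence largest eigenvalue of the gain-scaled weight matrix of
#'   the surrounding network (dimensionless, `< 1`).
#' @return An object of class `cascade_spec`.
#' @export
cascade_spec <- function(taus, recurrence = 0) {
  taus <- as.numeric(taus)
  if (length(taus) < 2) stop("a cascade needs at least 2 stages", call. = FALSE)
  if (any(taus <= 0)) stop("all time constants must be > 0", call. = FALSE)
  if (recurrence >= 1)
    stop("recurrence must be < 1 (network unstable without homeostasis)",
         call. = FALSE)
  structure(list(taus = taus, recurrence = recurrence), class = "cascade_spec")
}

#' Specification of a recurrent homeostatic network
#'
#' Holds the gain-scaled weight matrix `W = alpha * V` together with the
#' homeostatic loop parameters, shared by all neurons or given per neuron.
#' For symmetric `W` the 3N-dimensional stability problem factorises into
#' independent three-dimensional problems, one per eigenmode of `W`.
#'
#' @param W square gain-scaled weight matrix (dimensionless).
#' @param params a [neuron_params()] object shared by all neurons, or a list
#'   of N such objects for a heterogeneous network.
#' @param symmetric optional; declare the matrix symmetric.  If `NULL` it is
#'   detected with tolerance `1e-10` relative to `max(abs(W))`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(W, params = neuron_params(), symmetric = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  n <- nrow(W)
  if (inherits(params, "neuron_params")) {
    plist <- rep(list(params), n)
    homogeneous <- TRUE
  } else {
    plist <- params
    if (length(plist) != n)
      stop("per-neuron parameter list must have length N", call. = FALSE)
    if (!all(vapply(plist, inherits, logical(1), "neuron_params")))
      stop("params must be neuron_params objects", call. = FALSE)
    homogeneous <- FALSE
  }
  if (is.null(symmetric)) {
    scale <- max(abs(W), 1e-300)
    symmetric <- max(abs(W - t(W))) < 1e-10 * scale
  }
  structure(list(W = W, params = plist, n = n,
                 symmetric = symmetric, homogeneous = homogeneous),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("homeostatic network: N = %d, %s, %s parameters\n", x$n,
              if (x$symmetric) "symmetric" else "non-symmetric",
              if (x$homogeneous) "shared" else "per-neuron"))
  invisible(x)
}
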