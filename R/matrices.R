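#' Linearized system matrix of one homeostatic eigenmode
#'
#' Builds the 3x3 matrix (entries in 1/ms) governing small deviations of a
#' single network eigenmode with recurrence `w` around the homeostatic
#' set-point:
#' \deqn{\tau_1 \dot r_1 = -(1-w) r_1 - \alpha r_3, \quad
#'       \tau_2 \dot r_2 = -r_2 + r_1, \quad
#'       \tau_3 \dot r_3 = r_2.}
#' The third row has no diagonal leak: the threshold controller is a perfect
#' integrator.  With `recurrence = 0` this is the single-neuron system.
#'
#' @param params a [neuron_params()] object.
#' @param recurrence eigenvalue `w` of the gain-scaled weight matrix for this
#'   mode (dimensionless).  Values `>= 1` are allowed (the mode is unstable
#'   even without homeostasis) but flagged with a warning.
#' @return A 3x3 matrix of class `system_matrix` with `mode_labels`
#'   attribute `c("r1", "r2", "r3")`.
#' @examples
#' build_single_mode_matrix(neuron_params(10, 50, 100))
#' @export
build_single_mode_matrix <- function(params, recurrence = 0) {
  stopifnot(inherits(params, "neuron_params"))
  if (recurrence >= 1)
    warning("recurrence >= 1: mode unstable without homeostasis")
  m <- matrix(c(-(1 - recurrence) / params$tau1, 0, -params$alpha / params$tau1,
                1 / params$tau2, -1 / params$tau2, 0,
                0, 1 / params$tau3, 0),
              nrow = 3, byrow = TRUE)
  structure(m, class = c("system_matrix", "matrix"),
            mode_labels = c("r1", "r2", "r3"))
}

#' Linearized system matrix of a full homeostatic network
#'
#' Builds the 3N x 3N block matrix for N neurons coupled by the gain-scaled
#' weight matrix `W`:
#' rows 1..N carry `(W - I)/tau1` and the threshold feedback
#' `-alpha/tau1`, rows N+1..2N the sensor filter, rows 2N+1..3N the perfect
#' integrators.  With per-neuron parameters each diagonal entry uses that
#' neuron's own time constants (the heterogeneous case).
#'
#' For symmetric `W` the spectrum of this matrix is exactly the union over
#' the eigenvalues `w_n` of `W` of the 3x3 single-mode spectra.
#'
#' @param net a [network_spec()] object.
#' @return A 3N x 3N matrix of class `system_matrix`.
#' @export
build_network_matrix <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  n <- net$n
  t1 <- vapply(net$params, `[[`, numeric(1), "tau1")
  t2 <- vapply(net$params, `[[`, numeric(1), "tau2")
  t3 <- vapply(net$params, `[[`, numeric(1), "tau3")
  al <- vapply(net$params, `[[`, numeric(1), "alpha")
  m <- matrix(0, 3 * n, 3 * n)
  i1 <- seq_len(n); i2 <- n + i1; i3 <- 2 * n + i1
  m[i1, i1] <- (net$W - diag(n)) / t1
  m[cbind(i1, i3)] <- -al / t1
  m[cbind(i2, i1)] <- 1 / t2
  m[cbind(i2, i2)] <- -1 / t2
  m[cbind(i3, i2)] <- 1 / t3
  structure(m, class = c("system_matrix", "matrix"),
            mode_labels = rep(c("r1", "r2", "r3"), each = n))
}

#' Per-mode system matrix with two parallel integral controllers
#'
#' Two perfect integrators (time constants `tau3` from `params` and `tau3b`)
#' read the same sensor error `r2 - r_goal`; the threshold is the sum of
#' their outputs.  Because the system is invariant to the division of labour
#' between the two loops, this 4x4 matrix has one structural zero eigenvalue.
#'
#' @inheritParams build_single_mode_matrix
#' @param tau3b integrator time constant of the second controller (ms).
#' @return A 4x4 matrix of class `system_matrix`.
#' @export
build_parallel_matrix <- function(params, tau3b, recurrence = 0) {
  stopifnot(inherits(params, "neuron_params"), tau3b > 0)
  m <- matrix(c(
    -(1 - recurrence) / params$tau1, 0, -params$alpha / params$tau1,
      -params$alpha / params$tau1,
    1 / params$tau2, -1 / params$tau2, 0, 0,
    0, 1 / params$tau3, 0, 0,
    0, 1 / tau3b, 0, 0), nrow = 4, byrow = TRUE)
  structure(m, class = c("system_matrix", "matrix"),
            mode_labels = c("r1", "r2", "r3a", "r3b"))
}
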