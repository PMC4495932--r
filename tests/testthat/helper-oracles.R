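# shared oracles, independent of the implementation paths they check

eigmax <- function(m) max(Re(eigen(unclass(m), only.values = TRUE)$values))

# mode characteristic polynomial (ascending coefficients), complex-capable
mode_poly <- function(tau1, tau2, tau3, alpha = 1, wn = 0) {
  c(alpha, (1 - wn) * tau3, (tau1 + (1 - wn) * tau2) * tau3,
    tau1 * tau2 * tau3)
}

# root-based stability call for the mode polynomial
roots_stable <- function(tau1, tau2, tau3, alpha = 1, wn = 0) {
  max(Re(polyroot(mode_poly(tau1, tau2, tau3, alpha, wn)))) < 0
}

# critical tau3 for a complex mode eigenvalue by bisection on polyroot
tau3_boundary_oracle <- function(tau1, tau2, wr, wi, tol = 1e-9) {
  f <- function(lt3) max(Re(polyroot(mode_poly(tau1, tau2, exp(lt3), 1,
                                               complex(real = wr,
                                                       imaginary = wi)))))
  lo <- log(1e-4); hi <- log(1e10)
  if (f(hi) > 0) return(Inf)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

sorted_spectrum <- function(ev) ev[order(Re(ev), Im(ev))]

expect_spectra_equal <- function(a, b, tol = 1e-8) {
  a <- sorted_spectrum(a); b <- sorted_spectrum(b)
  expect_equal(length(a), length(b))
  expect_lt(max(Mod(a - b)), tol)
}
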