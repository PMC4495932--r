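#' Routh-Hurwitz test for a real cubic
#'
#' For the polynomial `c0 + c1*l + c2*l^2 + c3*l^3` with real coefficients
#' (positive leading coefficient), all roots have negative real parts iff
#' (1) every coefficient is positive and (2) `c0*c3 < c1*c2`.
#'
#' @param coeffs numeric vector `c(c0, c1, c2, c3)`, ascending powers.
#' @return `TRUE` iff the polynomial is Hurwitz stable.
#' @examples
#' routh_hurwitz_real(c(1, 3, 3, 1))  # (l + 1)^3: stable
#' @export
routh_hurwitz_real <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != 4) stop("degree must be exactly 3", call. = FALSE)
  if (coeffs[4] < 0) coeffs <- -coeffs
  all(coeffs > 0) && coeffs[1] * coeffs[4] < coeffs[2] * coeffs[3]
}

#' Routh-Hurwitz test for a monic cubic with complex coefficients
#'
#' Tests whether every root of `l^3 + c1*l^2 + c2*l + c3` with complex
#' coefficients has a negative real part.  The imaginary parts are
#' eliminated by multiplying with the conjugate-coefficient polynomial:
#' the product has real coefficients and the same real-part root pattern,
#' so the standard Hurwitz determinant conditions of the resulting sixth
#' degree polynomial decide stability exactly.
#'
#' @param c1,c2,c3 complex coefficients of the monic cubic.
#' @return `TRUE` iff all roots lie strictly in the left half-plane.
#' @examples
#' routh_hurwitz_complex(3, 3, 1)  # real coefficients: reduces to real test
#' @export
routh_hurwitz_complex <- function(c1, c2, c3) {
  p <- c(c3, c2, c1, 1 + 0i)
  pb <- Conj(p)
  q <- rep(0 + 0i, 7)
  for (i in 1:4) for (j in 1:4) q[i + j - 1] <- q[i + j - 1] + p[i] * pb[j]
  hurwitz_det_all(Re(q))
}

# Hurwitz determinant test for a real polynomial, ascending coefficients,
# positive leading coefficient assumed after normalization.
hurwitz_det_all <- function(a) {
  n <- length(a) - 1
  if (a[n + 1] < 0) a <- -a
  ad <- rev(a)                       # ad[1] = leading
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- 2 * j - i + 1
    if (k >= 1 && k <= n + 1) H[i, j] <- ad[k]
  }
  for (k in seq_len(n)) {
    if (det(H[seq_len(k), seq_len(k), drop = FALSE]) <= 0) return(FALSE)
  }
  TRUE
}

# multiply two polynomials given as ascending coefficient vectors
poly_mul <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

# roots of an ascending-coefficient polynomial
poly_roots <- function(coeffs) {
  nz <- which(abs(coeffs) > 0)
  if (!length(nz)) stop("zero polynomial", call. = FALSE)
  coeffs <- coeffs[seq_len(max(nz))]
  polyroot(coeffs)
}
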