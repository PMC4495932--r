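#' Random weight matrices with controlled spectra
#'
#' Generates dense random weight matrices for network experiments, rescaled
#' so the dominant eigenvalue (largest real part) equals `target` to within
#' `1e-8`:
#' \describe{
#'   \item{`symmetric_gaussian`}{Gaussian entries, symmetrised; real
#'     spectrum.}
#'   \item{`asymmetric_gaussian`}{independent Gaussian entries; complex
#'     eigenvalue pairs.}
#'   \item{`rank_one`}{outer product of uniform vectors; a single nonzero
#'     eigenvalue.}
#' }
#'
#' @param n matrix dimension.
#' @param ensemble one of `"symmetric_gaussian"`, `"asymmetric_gaussian"`,
#'   `"rank_one"`.
#' @param target dominant eigenvalue after rescaling.  Values `>= 1` are
#'   allowed (the network is then unstable without homeostasis) but
#'   flagged with a warning.
#' @return An `n x n` matrix.
#' @examples
#' W <- random_weight_matrix(10, "symmetric_gaussian", target = 0.8)
#' max(eigen(W)$values)  # 0.8
#' @export
random_weight_matrix <- function(n,
                                 ensemble = c("symmetric_gaussian",
                                              "asymmetric_gaussian",
                                              "rank_one"),
                                 target = 0.8) {
  ensemble <- match.arg(ensemble)
  if (target >= 1) warning("target recurrence >= 1: unstable without homeostasis")
  W <- switch(ensemble,
    symmetric_gaussian = {
      a <- matrix(rnorm(n * n), n, n)
      (a + t(a)) / 2
    },
    asymmetric_gaussian = matrix(rnorm(n * n), n, n),
    rank_one = {
      u <- runif(n); v <- runif(n)
      outer(u, v)
    })
  ev <- eigen(W, only.values = TRUE)$values
  top <- max(Re(ev))
  if (abs(top) < 1e-12) stop("degenerate draw: dominant eigenvalue ~ 0",
                             call. = FALSE)
  W * (target / top)
}
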