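#' Static f-I curves
#'
#' Constructs the static input-output relation `g()` mapping net input to
#' firing rate.  Supported kinds:
#' \describe{
#'   \item{`linear`}{`g(x) = slope * x`.}
#'   \item{`threshold_linear`}{`g(x) = slope * max(0, x - threshold)`.}
#'   \item{`sigmoid`}{`g(x) = rmax / (1 + exp(-(x - x0) / width))`.}
#'   \item{`tabulated`}{monotone table `(x, y)`, linearly interpolated;
#'     this is also the representation used for f-I curves measured from
#'     spiking simulations.}
#'   \item{`custom`}{an arbitrary R function `fn`, evaluated on `domain`.}
#' }
#' Curves must be monotonically non-decreasing with non-negative output on
#' their domain; this is checked on construction by dense sampling.
#'
#' @param kind one of `"linear"`, `"threshold_linear"`, `"sigmoid"`,
#'   `"tabulated"`, `"custom"`.
#' @param slope,threshold,rmax,x0,width kind-specific shape parameters.
#' @param x,y samples for `kind = "tabulated"`.
#' @param fn function for `kind = "custom"`.
#' @param domain valid input range; required for `custom`, defaults to the
#'   table range for `tabulated` and to `c(-1e3, 1e3)` otherwise.
#' @return An object of class `fi_curve`, callable via [fi_eval()].
#' @examples
#' f <- fi_curve("threshold_linear", slope = 2)
#' fi_eval(f, c(-1, 0.5, 2))
#' @export
fi_curve <- function(kind = c("linear", "threshold_linear", "sigmoid",
                              "tabulated", "custom"),
                     slope = 1, threshold = 0, rmax = 100, x0 = 0, width = 1,
                     x = NULL, y = NULL, fn = NULL, domain = NULL) {
  kind <- match.arg(kind)
  obj <- switch(kind,
    linear = list(kind = kind, par = c(slope = slope)),
    threshold_linear = list(kind = kind,
                            par = c(slope = slope, threshold = threshold)),
    sigmoid = list(kind = kind, par = c(rmax = rmax, x0 = x0, width = width)),
    tabulated = {
      if (is.null(x) || is.null(y) || length(x) != length(y))
        stop("tabulated curves need matching x and y", call. = FALSE)
      o <- order(x)
      list(kind = kind, x = as.numeric(x[o]), y = as.numeric(y[o]))
    },
    custom = {
      if (!is.function(fn)) stop("custom curves need fn", call. = FALSE)
      if (is.null(domain)) stop("custom curves need a domain", call. = FALSE)
      list(kind = kind, fn = fn)
    })
  if (is.null(domain)) {
    domain <- if (kind == "tabulated") range(obj$x) else c(-1e3, 1e3)
  }
  obj$domain <- as.numeric(domain)
  obj <- structure(obj, class = "fi_curve")

  xs <- seq(obj$domain[1], obj$domain[2], length.out = 513)
  ys <- fi_eval(obj, xs)
  if (any(!is.finite(ys))) stop("f-I curve not finite on domain", call. = FALSE)
  if (any(diff(ys) < -1e-9 * max(abs(ys), 1)))
    stop("f-I curve must be monotonically non-decreasing", call. = FALSE)
  if (kind != "linear" && any(ys < -1e-9 * max(abs(ys), 1)))
    stop("f-I curve output must be non-negative", call. = FALSE)
  obj
}

#' Evaluate an f-I curve
#'
#' @param f an [fi_curve()] object.
#' @param x net input values.
#' @return Firing rates `g(x)`.
#' @export
fi_eval <- function(f, x) {
  stopifnot(inherits(f, "fi_curve"))
  switch(f$kind,
    linear = f$par[["slope"]] * x,
    threshold_linear = f$par[["slope"]] * pmax(0, x - f$par[["threshold"]]),
    sigmoid = f$par[["rmax"]] / (1 + exp(-(x - f$par[["x0"]]) / f$par[["width"]])),
    tabulated = {
      yl <- f$y[1]; yr <- f$y[length(f$y)]
      stats::approx(f$x, f$y, xout = x, yleft = yl, yright = yr)$y
    },
    custom = f$fn(x))
}

# inverse g^{-1}(r) on the domain, by monotone root bracketing
fi_invert <- function(f, r) {
  lo <- f$domain[1]; hi <- f$domain[2]
  flo <- fi_eval(f, lo); fhi <- fi_eval(f, hi)
  if (r < flo - 1e-12 || r > fhi + 1e-12)
    stop("rate not reachable on the curve's domain", call. = FALSE)
  if (f$kind == "linear") return(r / f$par[["slope"]])
  uniroot(function(x) fi_eval(f, x) - r, c(lo, hi),
          tol = 1e-12 * max(1, hi - lo))$root
}

#' Linearize an f-I curve at the homeostatic set-point
#'
#' Finds the set-point input `x* = g^{-1}(r_goal)` and the local slope
#' `alpha` of the curve there (analytic where available, otherwise a central
#' finite difference).
#'
#' @param f an [fi_curve()] object.
#' @param r_goal target rate (Hz); must lie in the range of `f`.
#' @return A list with elements `set_point_input` and `alpha`.
#' @examples
#' fi_linearize(fi_curve("threshold_linear", slope = 2), r_goal = 4)
#' @export
fi_linearize <- function(f, r_goal) {
  stopifnot(inherits(f, "fi_curve"))
  xstar <- fi_invert(f, r_goal)
  alpha <- switch(f$kind,
    linear = f$par[["slope"]],
    threshold_linear = if (xstar > f$par[["threshold"]]) f$par[["slope"]] else NA_real_,
    sigmoid = {
      s <- fi_eval(f, xstar) / f$par[["rmax"]]
      f$par[["rmax"]] * s * (1 - s) / f$par[["width"]]
    },
    {
      hh <- max(1e-6, 1e-6 * diff(f$domain))
      (fi_eval(f, xstar + hh) - fi_eval(f, xstar - hh)) / (2 * hh)
    })
  if (!is.finite(alpha) || alpha <= 0)
    stop("curve is not invertible at r_goal (zero or undefined slope)",
         call. = FALSE)
  list(set_point_input = xstar, alpha = alpha)
}

#' Envelope slope of a re-centered f-I curve
#'
#' Computes `max_ratio = sup_{x != 0} g~(x)/x` where
#' `g~(x) = g(x + x*) - r_goal` is the f-I curve re-centered on the
#' set-point, i.e. the slope of the steepest line through the set-point that
#' envelopes the curve.  `beta = max_ratio / alpha` is the factor by which
#' the envelope exceeds the tangent; `beta = 1` for linear curves and for
#' concave saturating curves whose maximum slope is at the set-point.
#'
#' The supremum is located by a dense grid search (2001 points across the
#' declared domain) followed by local golden-section refinement.  A vertical
#' segment (unbounded ratio) is reported as `Inf` with a warning.
#'
#' @inheritParams fi_linearize
#' @return A list with `max_ratio`, `beta`, `alpha` and `set_point_input`.
#' @examples
#' f <- fi_curve("custom", fn = function(x) x^2, domain = c(0, 2))
#' fi_envelope_slope(f, r_goal = 1)  # max ratio 3, beta 1.5
#' @export
fi_envelope_slope <- function(f, r_goal) {
  lin <- fi_linearize(f, r_goal)
  xstar <- lin$set_point_input
  ratio <- function(d) (fi_eval(f, xstar + d) - r_goal) / d
  lo <- f$domain[1] - xstar
  hi <- f$domain[2] - xstar
  eps <- 1e-9 * max(1, hi - lo)
  ds <- seq(lo, hi, length.out = 2001)
  ds <- ds[abs(ds) > eps]
  rs <- vapply(ds, ratio, numeric(1))
  ok <- is.finite(rs)
  ds <- ds[ok]; rs <- rs[ok]
  best <- which.max(rs)
  # golden-section refinement in the bracketing interval around the best
  bl <- ds[max(1, best - 1)]; bu <- ds[min(length(ds), best + 1)]
  if (bl < -eps && bu > eps) { # straddles the set-point: limit is alpha
    ref <- max(rs[best], lin$alpha)
  } else {
    opt <- optimize(ratio, lower = bl, upper = bu, maximum = TRUE,
                    tol = 1e-10 * max(1, abs(bu)))
    ref <- max(rs[best], opt$objective)
  }
  max_ratio <- max(ref, lin$alpha)
  if (!is.finite(max_ratio)) {
    warning("unbounded envelope ratio (vertical segment in the curve)")
    max_ratio <- Inf
  }
  list(max_ratio = max_ratio, beta = max_ratio / lin$alpha,
       alpha = lin$alpha, set_point_input = xstar)
}
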