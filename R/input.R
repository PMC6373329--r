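#' Parameters of the plasma input model
#'
#' A Feng-type arterial input: an initial linear ramp damped by a fast
#' exponential plus two slower washout exponentials, delayed by an appearance
#' time `t0`.  The tracer quantification implemented here never uses an
#' arterial input directly; the curve only drives the simulated reference
#' region, so its absolute scale is arbitrary.
#'
#' @param a1 Ramp amplitude (kBq/mL/min).
#' @param a2,a3 Exponential amplitudes (kBq/mL).
#' @param lam1,lam2,lam3 Decay rates (1/min), `lam1 > lam2 > lam3 > 0`.
#' @param t0 Appearance delay (min).
#' @return Object of class `feng_params`.
#' @export
feng_params <- function(a1 = 800, a2 = 20, a3 = 10,
                        lam1 = 4, lam2 = 0.5, lam3 = 0.01, t0 = 0.5) {
  if (!(lam1 > lam2 && lam2 > lam3 && lam3 > 0))
    stop("need lam1 > lam2 > lam3 > 0", call. = FALSE)
  if (a1 <= 0) stop("a1 must be positive", call. = FALSE)
  if (a2 < 0 || a3 < 0) stop("a2, a3 must be non-negative", call. = FALSE)
  if (t0 < 0) stop("t0 must be non-negative", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, a3 = a3,
                 lam1 = lam1, lam2 = lam2, lam3 = lam3, t0 = t0),
            class = "feng_params")
}

#' Evaluate the plasma input curve
#'
#' For `t > t0` the curve is
#' `a1 (t - t0) e^{-lam1 (t - t0)} + a2 (e^{-lam2 (t - t0)} - e^{-lam1 (t - t0)})
#'  + a3 (e^{-lam3 (t - t0)} - e^{-lam1 (t - t0)})`, and 0 otherwise.
#'
#' @param params A [feng_params()] object.
#' @param t Non-negative, strictly increasing time grid (min).
#' @return Plasma concentration (kBq/mL) on `t`.
#' @export
feng_input <- function(params, t) {
  stopifnot(inherits(params, "feng_params"))
  if (any(t < 0)) stop("time grid must be non-negative", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  s <- t - params$t0
  out <- numeric(length(t))
  pos <- s > 0
  sp <- s[pos]
  e1 <- exp(-params$lam1 * sp)
  out[pos] <- params$a1 * sp * e1 +
    params$a2 * (exp(-params$lam2 * sp) - e1) +
    params$a3 * (exp(-params$lam3 * sp) - e1)
  out
}
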