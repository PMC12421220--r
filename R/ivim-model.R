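#' Diffusion acquisition protocol
#'
#' An ordered set of b-values defining the measurement axis of a
#' diffusion-weighted acquisition. Working units are ms/um^2 so that the
#' tissue diffusivity (0.4-3 um^2/ms) and the normalised signal (order 1)
#' have similar magnitude, which keeps gradient-descent update steps for the
#' different model parameters comparably sized. Clinical protocols quoted in
#' s/mm^2 are converted on input (1 ms/um^2 = 1000 s/mm^2).
#'
#' @param b_values Numeric vector of nonnegative b-values, in the order the
#'   signals are acquired (predicted signals follow the same order).
#' @param units Either `"ms/um2"` (default, stored as given) or `"s/mm2"`
#'   (divided by 1000 on input).
#' @return An `acquisition_protocol`: list with `b_values` (ms/um^2) and
#'   `n_measurements`.
#' @examples
#' acquisition_protocol(c(0, 10, 20, 30, 50, 80, 100, 200, 400, 800),
#'                      units = "s/mm2")
#' @export
acquisition_protocol <- function(b_values, units = c("ms/um2", "s/mm2")) {
  units <- match.arg(units)
  if (!is.numeric(b_values) || length(b_values) < 1L)
    stop("b_values must be a nonempty numeric vector")
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b_values must be finite and >= 0")
  b <- as.numeric(b_values)
  if (units == "s/mm2") b <- b / 1000
  structure(list(b_values = b, n_measurements = length(b)),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %d b-values (ms/um2): %s\n",
              x$n_measurements, paste(signif(x$b_values, 4), collapse = ", ")))
  invisible(x)
}

#' The 10-b-value IVIM protocol used throughout the package
#'
#' b = 0, 10, 20, 30, 50, 80, 100, 200, 400, 800 s/mm^2 (0-0.8 ms/um^2),
#' a typical clinical IVIM protocol: dense low-b sampling to capture the
#' rapid pseudo-diffusion decay plus high b-values for tissue diffusion.
#'
#' @return An [acquisition_protocol()].
#' @export
default_ivim_protocol <- function() {
  acquisition_protocol(c(0, 10, 20, 30, 50, 80, 100, 200, 400, 800),
                       units = "s/mm2")
}

#' IVIM parameter table
#'
#' Validates and assembles per-voxel intravoxel incoherent motion
#' parameters: tissue diffusion coefficient `Dt` (um^2/ms), pseudo-diffusion
#' coefficient `Dp` (um^2/ms), perfusion fraction `f` (dimensionless, in
#' [0, 1]) and non-diffusion-weighted signal `S0` (a.u.). `Dp > Dt` in
#' physiological regimes; that ordering is reported via the `n_dp_le_dt`
#' attribute as a diagnostic, not enforced.
#'
#' @param Dt,Dp Positive numeric vectors (um^2/ms).
#' @param f Numeric vector in [0, 1].
#' @param S0 Positive numeric vector (a.u.).
#' @return A `data.frame` with columns `Dt, Dp, f, S0` and class
#'   `ivim_params`.
#' @export
ivim_params <- function(Dt, Dp, f, S0) {
  n <- max(length(Dt), length(Dp), length(f), length(S0))
  p <- data.frame(Dt = rep_len(as.numeric(Dt), n),
                  Dp = rep_len(as.numeric(Dp), n),
                  f = rep_len(as.numeric(f), n),
                  S0 = rep_len(as.numeric(S0), n))
  validate_ivim_params(p)
}

validate_ivim_params <- function(p) {
  stopifnot(all(c("Dt", "Dp", "f", "S0") %in% names(p)))
  if (any(p$Dt <= 0) || any(p$Dp <= 0)) stop("Dt and Dp must be > 0")
  if (any(p$f < 0 | p$f > 1)) stop("f must lie in [0, 1]")
  if (any(p$S0 <= 0)) stop("S0 must be > 0")
  attr(p, "n_dp_le_dt") <- sum(p$Dp <= p$Dt)
  class(p) <- unique(c("ivim_params", class(p)))
  p
}

#' Physiological IVIM parameter ranges
#'
#' Default simulation/training ranges: Dt in [0.4, 3] um^2/ms, Dp in
#' [10, 150] um^2/ms, f in [0.1, 0.5], S0 in [0.8, 1.2] a.u. A wider S0
#' range ([0.1, 1]) mirroring in vivo normalised data is available via
#' `preset = "wide_s0"`.
#'
#' @param preset `"default"` or `"wide_s0"`.
#' @return Named list of `c(lo, hi)` per parameter.
#' @export
ivim_param_ranges <- function(preset = c("default", "wide_s0")) {
  preset <- match.arg(preset)
  r <- list(Dt = c(0.4, 3), Dp = c(10, 150), f = c(0.1, 0.5),
            S0 = c(0.8, 1.2))
  if (preset == "wide_s0") r$S0 <- c(0.1, 1)
  r
}

#' IVIM bi-exponential forward model
#'
#' Noise-free diffusion-weighted signal for each voxel and b-value:
#' `A(b) = S0 ( f exp(-b (Dp + Dt)) + (1 - f) exp(-b Dt) )`.
#' The fast pseudo-diffusion compartment (capillary perfusion) decays within
#' the lowest b-values; the tissue compartment dominates thereafter. The
#' output columns follow the protocol's b-value ordering exactly.
#'
#' @param params An [ivim_params()] table (or a single-row list/data.frame
#'   with fields Dt, Dp, f, S0).
#' @param protocol An [acquisition_protocol()].
#' @return N x Nz matrix of strictly positive signals (N voxels, Nz
#'   b-values); a plain vector if `params` has a single row and
#'   `drop = TRUE`.
#' @param drop If `TRUE` (default) a single-voxel result is returned as a
#'   vector.
#' @examples
#' p <- ivim_params(Dt = 1, Dp = 50, f = 0.2, S0 = 1)
#' ivim_signal(p, default_ivim_protocol())
#' @export
ivim_signal <- function(params, protocol, drop = TRUE) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  p <- as.data.frame(params)
  p <- validate_ivim_params(p)
  b <- protocol$b_values
  E_fast <- exp(-outer(p$Dt + p$Dp, b))   # perfusion compartment
  E_slow <- exp(-outer(p$Dt, b))          # tissue compartment
  A <- p$S0 * (p$f * E_fast + (1 - p$f) * E_slow)
  if (drop && nrow(p) == 1L) as.vector(A) else A
}

# Partial derivatives of the forward model with respect to the four
# parameters, used by network backpropagation and gradient-based fitting.
# Returns list of N x Nz matrices dDt, dDp, df, dS0.
ivim_signal_jacobian <- function(p, protocol) {
  b <- protocol$b_values
  E_fast <- exp(-outer(p$Dt + p$Dp, b))
  E_slow <- exp(-outer(p$Dt, b))
  A <- p$S0 * (p$f * E_fast + (1 - p$f) * E_slow)
  bmat <- matrix(b, nrow = length(p$Dt), ncol = length(b), byrow = TRUE)
  list(A = A,
       dDt = -bmat * A,
       dDp = -bmat * (p$S0 * p$f * E_fast),
       df = p$S0 * (E_fast - E_slow),
       dS0 = A / p$S0)
}
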