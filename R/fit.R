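#' Default parameter bounds for conventional fitting
#'
#' The simulation ranges widened by 50% per side (see `widen_ranges`), the
#' same bounds the network output transform uses. The generous widening
#' matters at low SNR: tighter bounds truncate the sampling spread of the
#' estimates at the edge grid levels and bias their mean toward the
#' interior.
#'
#' @param ranges Base ranges (default [ivim_param_ranges()]).
#' @return Named list of `c(lo, hi)` per parameter.
#' @export
default_fit_bounds <- function(ranges = ivim_param_ranges()) {
  widen_ranges(ranges, 0.5)
}

# Lean single-voxel objective with analytic gradient over
# theta = (Dt, Dp, f, S0): plain-vector arithmetic, one evaluation shared
# between optim's fn and gr through a last-theta cache.
make_voxel_objective <- function(M, b, objective, sigma, sigma_scale) {
  s2 <- if (objective == "NLR") (sigma * sigma_scale)^2
  last_theta <- NULL
  last <- NULL
  eval_at <- function(theta) {
    if (!is.null(last_theta) && identical(theta, last_theta)) return(last)
    Dt <- theta[1]; Dp <- theta[2]; f <- theta[3]; S0 <- theta[4]
    E_fast <- exp(-(Dt + Dp) * b)
    E_slow <- exp(-Dt * b)
    A <- S0 * (f * E_fast + (1 - f) * E_slow)
    if (objective == "NLR") {
      Ac <- pmax(A, A_FLOOR)
      x <- M * Ac / s2
      i0e <- i0e_safe(x)
      val <- -sum(log(M / s2) - (M^2 + Ac^2) / (2 * s2) + log(i0e) + x)
      G <- Ac / s2 - (M / s2) * i1e_safe(x) / i0e
    } else {
      r <- A - M
      val <- sum(r^2)
      G <- 2 * r
    }
    grad <- c(sum(G * (-b * A)),
              sum(G * (-b * S0 * f * E_fast)),
              sum(G * (S0 * (E_fast - E_slow))),
              sum(G * (A / S0)))
    last_theta <<- theta
    last <<- list(value = val, grad = grad)
    last
  }
  eval_at
}

fit_voxel_core <- function(M, b, objective, sigma, lower, upper, init,
                           sigma_scale = 1, maxit = 500L) {
  obj <- make_voxel_objective(M, b, objective, sigma, sigma_scale)
  # tight tolerances: the objective has shallow valleys along the Dp-f
  # trade-off and the default stopping rule quits inside them
  res <- tryCatch(
    stats::optim(init, fn = function(th) obj(th)$value,
                 gr = function(th) obj(th)$grad,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 100, pgtol = 1e-12)),
    error = function(e) e)
  if (inherits(res, "error"))
    list(par = init, value = NA_real_, converged = FALSE, iter = 0L,
         message = conditionMessage(res))
  else
    list(par = res$par, value = res$value, converged = res$convergence == 0,
         iter = unname(res$counts[1]), message = res$message %||% "")
}

#' Fit the IVIM model to a single voxel
#'
#' Bounded local optimisation (L-BFGS-B with analytic gradients) of either
#' the negative log Rician likelihood (`"NLR"`, maximum likelihood
#' estimation under Rician noise; requires `sigma`) or the residual sum of
#' squares (`"LSQ"`, least squares). Deterministic given the initial point.
#' Optimiser failure is reported through `converged = FALSE`, never as an
#' exception for ordinary data.
#'
#' @param M Numeric vector of Nz positive magnitudes (Nz >= 4).
#' @param protocol An [acquisition_protocol()] of matching length.
#' @param objective `"NLR"` or `"LSQ"`.
#' @param sigma Noise standard deviation (scalar or [noise_spec()]);
#'   required for `"NLR"`.
#' @param bounds Named list of `c(lo, hi)` per parameter (default
#'   [default_fit_bounds()]).
#' @param init Named numeric or [ivim_params()] row of starting values
#'   inside the bounds; default is the bound midpoints.
#' @param sigma_scale Mis-estimation multiplier on sigma (default 1).
#' @return A `fit_result`: list with `params` (one-row [ivim_params()]),
#'   `objective_value`, `converged`, `n_iterations`, `message`.
#' @export
fit_voxel <- function(M, protocol, objective = c("NLR", "LSQ"),
                      sigma = NULL, bounds = default_fit_bounds(),
                      init = NULL, sigma_scale = 1) {
  objective <- match.arg(objective)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  M <- as.numeric(M)
  if (length(M) != protocol$n_measurements)
    stop("length(M) must match the protocol")
  if (length(M) < 4L) stop("need at least as many measurements as parameters")
  if (objective == "NLR") {
    if (is.null(sigma)) stop("sigma is required for the NLR objective")
    sigma <- resolve_sigma(sigma)
  }
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  if (is.null(init)) {
    init <- (lower + upper) / 2
  } else {
    init <- unlist(as.data.frame(init)[1, c("Dt", "Dp", "f", "S0")])
  }
  if (any(init < lower) || any(init > upper))
    stop("init must lie within the bounds")
  res <- fit_voxel_core(M, protocol$b_values, objective, sigma, lower, upper,
                        init, sigma_scale)
  out <- list(params = ivim_params(res$par[1], res$par[2], res$par[3],
                                   res$par[4]),
              objective_value = res$value, converged = res$converged,
              n_iterations = res$iter, message = res$message)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> Dt=%.4g Dp=%.4g f=%.4g S0=%.4g  obj=%.6g  %s (%d iter)\n",
    x$params$Dt, x$params$Dp, x$params$f, x$params$S0, x$objective_value,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Fit the IVIM model voxel-wise over a batch
#'
#' Vectorised driver over voxels with optional multistart: each voxel is
#' fitted from the bound midpoint plus `multistart - 1` seeded uniform
#' draws within the bounds, keeping the best objective value. Per-voxel
#' optimiser failures are propagated as `converged` flags.
#'
#' @param batch A `signal_batch` (or bare N x Nz matrix with a protocol).
#' @param objective `"NLR"` or `"LSQ"`.
#' @param sigma Required for `"NLR"`.
#' @param bounds Parameter bounds (default [default_fit_bounds()]).
#' @param multistart Number of starts per voxel (default 3).
#' @param seed Seed for the extra starting points.
#' @param sigma_scale Mis-estimation multiplier on sigma.
#' @param protocol Needed only when `batch` is a bare matrix.
#' @return Data frame with one row per voxel: `voxel_id`, the four
#'   parameters, `objective_value`, `converged`, `n_iterations`.
#' @export
fit_volume <- function(batch, objective = c("NLR", "LSQ"), sigma = NULL,
                       bounds = default_fit_bounds(), multistart = 3L,
                       seed = 1L, sigma_scale = 1, protocol = NULL) {
  objective <- match.arg(objective)
  if (inherits(batch, "signal_batch")) {
    M <- batch$M
    protocol <- batch$protocol
  } else {
    M <- as.matrix(batch)
    if (is.null(protocol)) stop("protocol required for a bare matrix")
  }
  empty <- data.frame(voxel_id = integer(), Dt = numeric(), Dp = numeric(),
                      f = numeric(), S0 = numeric(),
                      objective_value = numeric(), converged = logical(),
                      n_iterations = integer())
  if (nrow(M) == 0L) return(empty)
  if (objective == "NLR") {
    if (is.null(sigma)) stop("sigma is required for the NLR objective")
    sigma <- resolve_sigma(sigma)
  }
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  multistart <- as.integer(multistart)
  set.seed(as.integer(seed))
  b <- protocol$b_values
  N <- nrow(M)
  # per-voxel random starts (midpoint first), drawn up front for
  # reproducibility
  n_extra <- max(multistart - 1L, 0L)
  extra <- if (n_extra > 0L)
    array(runif(N * n_extra * 4L), dim = c(4L, n_extra, N))
  par <- matrix(NA_real_, N, 4)
  objv <- numeric(N)
  conv <- logical(N)
  iter <- integer(N)
  for (v in seq_len(N)) {
    starts <- c(list((lower + upper) / 2),
                if (n_extra > 0L)
                  lapply(seq_len(n_extra), function(i)
                    lower + extra[, i, v] * (upper - lower)))
    best <- NULL
    for (init in starts) {
      fr <- fit_voxel_core(M[v, ], b, objective, sigma, lower, upper, init,
                           sigma_scale)
      if (is.null(best) ||
          (is.finite(fr$value) &&
           (!is.finite(best$value) || fr$value < best$value)))
        best <- fr
    }
    par[v, ] <- best$par
    objv[v] <- best$value
    conv[v] <- best$converged
    iter[v] <- best$iter
  }
  data.frame(voxel_id = seq_len(N), Dt = par[, 1], Dp = par[, 2],
             f = par[, 3], S0 = par[, 4], objective_value = objv,
             converged = conv, n_iterations = iter)
}
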