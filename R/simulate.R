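# Child seeds derived from one parent seed, so that e.g. regenerating the
# test split with more repetitions never perturbs the training draw. Kept
# below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(parent_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(parent_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Full factorial IVIM parameter grid
#'
#' Ground-truth parameter combinations for simulation: `n_levels`
#' equidistant values per parameter (endpoints included) crossed over all
#' four IVIM parameters, giving `n_levels^4` combinations. With the default
#' ranges and `n_levels = 10` this is the 10^4-combination simulation grid.
#'
#' @param ranges Named list of `c(lo, hi)` per parameter, as from
#'   [ivim_param_ranges()].
#' @param n_levels Number of equidistant levels per parameter (>= 2).
#' @return An [ivim_params()] table with `n_levels^length(ranges)` rows and a
#'   `combo_id` attribute-free integer column identifying each combination.
#' @export
make_parameter_grid <- function(ranges = ivim_param_ranges(), n_levels = 10L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !(r[1] < r[2]))
      stop(sprintf("invalid range for %s: lo must be < hi", nm))
  }
  levels <- lapply(ranges, function(r) seq(r[1], r[2], length.out = n_levels))
  g <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  names(g) <- names(ranges)
  g$combo_id <- seq_len(nrow(g))
  if (all(c("Dt", "Dp", "f", "S0") %in% names(g))) validate_ivim_params(g)
  else g
}

#' Add Rician noise to noise-free amplitudes
#'
#' Emulates magnitude formation from a single complex image: independent
#' zero-mean Gaussian noise of standard deviation `sigma` is added to the
#' real (signal-carrying) and imaginary channels and the magnitude is taken,
#' `M = sqrt((A + n_R)^2 + n_I^2)`. The result is Rician-distributed with
#' noncentrality `A`; at `A = 0` it is Rayleigh. Bit-reproducible for a
#' fixed seed.
#'
#' @param A Numeric matrix/vector of nonnegative noise-free amplitudes.
#' @param sigma Positive scalar (or [noise_spec()]) Gaussian-component
#'   standard deviation.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Positive magnitudes, same shape as `A`.
#' @export
add_rician_noise <- function(A, sigma, seed = NULL) {
  sigma <- resolve_sigma(sigma)
  if (any(A < 0)) stop("A must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(A)
  M <- sqrt((A + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  if (is.matrix(A)) matrix(M, nrow(A), ncol(A)) else M
}

#' Assemble a voxel batch of magnitude signals
#'
#' Container pairing an N x Nz magnitude matrix with its protocol and,
#' when simulated, the generating truth table and noise level.
#'
#' @param M N x Nz matrix of positive magnitudes.
#' @param protocol An [acquisition_protocol()]; `ncol(M)` must equal its
#'   number of b-values.
#' @param truth Optional [ivim_params()] table, one row per voxel.
#' @param sigma_true Optional [noise_spec()] used in generation.
#' @param seed Optional integer seed recorded for provenance.
#' @return A `signal_batch`.
#' @export
signal_batch <- function(M, protocol, truth = NULL, sigma_true = NULL,
                         seed = NULL) {
  M <- as.matrix(M)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (ncol(M) != protocol$n_measurements)
    stop("ncol(M) must match the protocol's number of b-values")
  if (any(M <= 0)) stop("all magnitudes must be positive")
  if (!is.null(truth) && nrow(truth) != nrow(M))
    stop("truth must have one row per voxel")
  if (!is.null(sigma_true)) sigma_true <- noise_spec(resolve_sigma(sigma_true))
  structure(list(M = M, protocol = protocol, truth = truth,
                 sigma_true = sigma_true, seed = seed),
            class = "signal_batch")
}

#' @export
print.signal_batch <- function(x, ...) {
  cat(sprintf("<signal_batch> %d voxels x %d measurements%s%s\n",
              nrow(x$M), ncol(x$M),
              if (!is.null(x$truth)) ", with ground truth" else "",
              if (!is.null(x$sigma_true))
                sprintf(", sigma = %g", x$sigma_true$sigma) else ""))
  invisible(x)
}

#' Simulate a Rician-distributed IVIM dataset over a parameter grid
#'
#' For each grid combination, `reps_per_combo` independent noisy voxels are
#' generated: the noise-free bi-exponential signal from [ivim_signal()] is
#' corrupted by complex Gaussian noise of standard deviation `sigma` via
#' [add_rician_noise()]. The full design (10 levels per parameter, 20
#' repetitions) yields the 200,000-voxel training set; different SNRs are
#' obtained by varying `sigma` only.
#'
#' @param grid An [ivim_params()] table of ground-truth combinations (e.g.
#'   from [make_parameter_grid()]).
#' @param protocol An [acquisition_protocol()].
#' @param sigma Positive scalar or [noise_spec()].
#' @param reps_per_combo Number of noisy instantiations per combination.
#' @param seed Integer seed for the noise draw.
#' @return A `signal_batch` with `reps_per_combo * nrow(grid)` voxels and the
#'   replicated truth table attached.
#' @export
build_dataset <- function(grid, protocol, sigma, reps_per_combo = 20L,
                          seed = 1L) {
  sigma <- resolve_sigma(sigma)
  reps_per_combo <- as.integer(reps_per_combo)
  if (reps_per_combo < 1L) stop("reps_per_combo must be >= 1")
  grid <- as.data.frame(grid)
  if (is.null(grid$combo_id)) grid$combo_id <- seq_len(nrow(grid))
  truth <- grid[rep(seq_len(nrow(grid)), each = reps_per_combo), , drop = FALSE]
  rownames(truth) <- NULL
  A <- ivim_signal(truth, protocol, drop = FALSE)
  M <- add_rician_noise(A, sigma, seed = seed)
  signal_batch(M, protocol, truth = validate_ivim_params(truth),
               sigma_true = noise_spec(sigma), seed = as.integer(seed))
}

#' Simulate matched training / validation / test splits
#'
#' Study-design convenience wrapper: a factorial grid is simulated at a
#' given SNR into a training set (`reps_train` instantiations per
#' combination), a validation set of `n_val` voxels whose combinations are
#' sampled uniformly from the grid with fresh noise, and a test set
#' generated identically to the training set but with different noise
#' (`reps_test` instantiations). One parent seed spawns independent child
#' seeds per split, so resizing one split leaves the others untouched.
#'
#' @param snr Signal-to-noise ratio at the unit b = 0 signal (`sigma = 1/snr`).
#' @param protocol An [acquisition_protocol()].
#' @param ranges Parameter ranges (default [ivim_param_ranges()]).
#' @param n_levels Grid levels per parameter (default 10).
#' @param reps_train,reps_test Instantiations per combination (defaults 20).
#' @param n_val Validation voxel count (default 1000).
#' @param seed Parent seed.
#' @return List with `train`, `val`, `test` (`signal_batch`es), the `grid`,
#'   and the [noise_spec()] used.
#' @export
simulate_ivim_study <- function(snr, protocol = default_ivim_protocol(),
                                ranges = ivim_param_ranges(),
                                n_levels = 10L, reps_train = 20L,
                                reps_test = 20L, n_val = 1000L, seed = 1L) {
  spec <- snr_to_noise(snr)
  grid <- make_parameter_grid(ranges, n_levels)
  seeds <- derive_seeds(seed, 4L)
  train <- build_dataset(grid, protocol, spec, reps_train, seed = seeds[1])
  set.seed(seeds[2])
  val_rows <- sample.int(nrow(grid), n_val, replace = TRUE)
  val_truth <- grid[val_rows, , drop = FALSE]
  rownames(val_truth) <- NULL
  val_A <- ivim_signal(val_truth, protocol, drop = FALSE)
  val <- signal_batch(add_rician_noise(val_A, spec, seed = seeds[3]),
                      protocol, truth = validate_ivim_params(val_truth),
                      sigma_true = spec, seed = seeds[3])
  test <- build_dataset(grid, protocol, spec, reps_test, seed = seeds[4])
  list(train = train, val = val, test = test, grid = grid, noise = spec)
}
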