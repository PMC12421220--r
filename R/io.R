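sig_col_names <- function(protocol) {
  sprintf("sig_b%g", protocol$b_values)
}

#' Write a signal batch to CSV (plus manifest)
#'
#' Voxel tables are CSV with a fixed column order: `voxel_id`, one signal
#' column per b-value (named `sig_b<value>`, b in ms/um^2), written to
#' `<prefix>_signals.csv`. Ground truth, when present, goes to
#' `<prefix>_truth.csv` with units in the headers (um^2/ms for the
#' diffusivities). A JSON manifest (`<prefix>_manifest.json`) records the
#' protocol, sigma, seed and row count so any output can be traced to the
#' run that produced it.
#'
#' @param batch A `signal_batch`.
#' @param prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_signal_batch <- function(batch, prefix) {
  stopifnot(inherits(batch, "signal_batch"))
  sig <- data.frame(voxel_id = seq_len(nrow(batch$M)))
  sig <- cbind(sig, as.data.frame(batch$M))
  names(sig)[-1] <- sig_col_names(batch$protocol)
  files <- c(signals = paste0(prefix, "_signals.csv"))
  utils::write.csv(sig, files["signals"], row.names = FALSE)
  if (!is.null(batch$truth)) {
    tr <- as.data.frame(batch$truth)
    keep <- intersect(c("Dt", "Dp", "f", "S0", "combo_id"), names(tr))
    tr <- tr[, keep]
    names(tr)[match(c("Dt", "Dp"), names(tr))] <-
      c("Dt_um2_per_ms", "Dp_um2_per_ms")
    tr <- cbind(voxel_id = seq_len(nrow(tr)), tr)
    files["truth"] <- paste0(prefix, "_truth.csv")
    utils::write.csv(tr, files["truth"], row.names = FALSE)
  }
  files["manifest"] <- paste0(prefix, "_manifest.json")
  write_manifest(run_manifest(
    command = "write_signal_batch",
    config = list(n_voxels = nrow(batch$M),
                  b_values_ms_um2 = batch$protocol$b_values,
                  sigma = if (!is.null(batch$sigma_true))
                    batch$sigma_true$sigma else NULL,
                  seed = batch$seed)),
    files["manifest"])
  invisible(files)
}

#' Read a signal batch written by [write_signal_batch()]
#' @param prefix Path prefix used when writing.
#' @return A `signal_batch` (with truth if `<prefix>_truth.csv` exists).
#' @export
read_signal_batch <- function(prefix) {
  man_path <- paste0(prefix, "_manifest.json")
  if (!file.exists(man_path)) stop("missing manifest: ", man_path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  protocol <- acquisition_protocol(man$config$b_values_ms_um2)
  sig <- utils::read.csv(paste0(prefix, "_signals.csv"))
  M <- as.matrix(sig[, -1, drop = FALSE])
  truth <- NULL
  tpath <- paste0(prefix, "_truth.csv")
  if (file.exists(tpath)) {
    tr <- utils::read.csv(tpath)
    names(tr)[match(c("Dt_um2_per_ms", "Dp_um2_per_ms"), names(tr))] <-
      c("Dt", "Dp")
    truth <- validate_ivim_params(tr[, setdiff(names(tr), "voxel_id")])
  }
  sigma <- man$config$sigma
  signal_batch(M, protocol, truth = truth,
               sigma_true = if (!is.null(sigma)) noise_spec(sigma),
               seed = man$config$seed)
}

#' Read b-values from a text file
#'
#' Accepts FSL-style bval files (all values on one whitespace-separated
#' line) or one value per line.
#'
#' @param path Text file of b-values.
#' @param units `"ms/um2"` or `"s/mm2"` (see [acquisition_protocol()]).
#' @return An [acquisition_protocol()].
#' @export
read_bvals <- function(path, units = c("ms/um2", "s/mm2")) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  acquisition_protocol(vals, units = match.arg(units))
}

#' Read a 4D diffusion-weighted NIfTI volume as a signal batch
#'
#' Flattens a 4D magnitude volume (last axis = measurements) into a voxel
#' table, optionally restricted to a mask. An index map is attached so
#' parameter maps can be written back into the original geometry (masked-out
#' voxels become NA).
#'
#' @param path 4D NIfTI file.
#' @param bvals_path Text file of b-values matching the 4th dimension.
#' @param mask Optional 3D NIfTI path or logical array selecting voxels.
#' @param units Units of the b-value file.
#' @return A `signal_batch` with attributes `index_map` (linear indices of
#'   the retained voxels) and `ref_dim` (the 3D volume dimensions).
#' @export
read_dwi_nifti <- function(path, bvals_path, mask = NULL,
                           units = c("ms/um2", "s/mm2")) {
  protocol <- read_bvals(bvals_path, units = match.arg(units))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D volume, got ", length(d), " dimensions")
  if (d[4] != protocol$n_measurements)
    stop(sprintf("volume has %d measurements but protocol has %d b-values",
                 d[4], protocol$n_measurements))
  nvox <- prod(d[1:3])
  M <- matrix(as.numeric(img), nrow = nvox, ncol = d[4])
  keep <- seq_len(nvox)
  if (!is.null(mask)) {
    if (is.character(mask)) mask <- RNifti::readNifti(mask)
    # trailing singleton dimensions may be dropped on disk round-trips
    if (length(mask) != nvox)
      stop("mask dimensions do not match the volume")
    keep <- which(as.logical(as.numeric(mask) != 0))
  }
  batch <- signal_batch(M[keep, , drop = FALSE], protocol)
  attr(batch, "index_map") <- keep
  attr(batch, "ref_dim") <- d[1:3]
  batch
}

#' Write a signal batch as a 4D NIfTI volume
#'
#' Inverse of the volumetric path of [read_dwi_nifti()]: voxels are placed
#' back at `index_map` positions within `ref_dim` (both default to the
#' attributes attached on reading); unfilled voxels are NA.
#'
#' @param batch A `signal_batch`.
#' @param path Output NIfTI path.
#' @param ref_dim 3D dimensions of the target volume.
#' @param index_map Linear voxel indices within the 3D volume.
#' @return `path`, invisibly.
#' @export
write_dwi_nifti <- function(batch, path,
                            ref_dim = attr(batch, "ref_dim"),
                            index_map = attr(batch, "index_map")) {
  stopifnot(inherits(batch, "signal_batch"))
  if (is.null(ref_dim)) stop("ref_dim is required")
  if (is.null(index_map)) index_map <- seq_len(prod(ref_dim))
  vol <- array(NA_real_, dim = c(ref_dim, ncol(batch$M)))
  flat <- matrix(NA_real_, prod(ref_dim), ncol(batch$M))
  flat[index_map, ] <- batch$M
  vol[] <- flat
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Write voxel-wise parameter maps as NIfTI volumes
#'
#' One 3D volume per parameter (`<prefix>_Dt.nii.gz`, ...), with voxels not
#' covered by the index map set to NA. Diffusivity maps are in um^2/ms.
#'
#' @param params Parameter table with columns Dt, Dp, f, S0.
#' @param prefix Output path prefix.
#' @param ref_dim 3D volume dimensions.
#' @param index_map Linear indices of the table's voxels in the volume.
#' @return Named vector of files written, invisibly.
#' @export
write_parameter_maps <- function(params, prefix, ref_dim,
                                 index_map = seq_len(prod(ref_dim))) {
  params <- as.data.frame(params)
  files <- character(0)
  for (p in c("Dt", "Dp", "f", "S0")) {
    vol <- array(NA_real_, dim = ref_dim)
    vol[index_map] <- params[[p]]
    f <- sprintf("%s_%s.nii.gz", prefix, p)
    RNifti::writeNifti(RNifti::asNifti(vol), f)
    files[p] <- f
  }
  invisible(files)
}

#' Run manifest
#'
#' Structured record written alongside every command-line output: the
#' command, a config snapshot (including seeds, sigma and protocol where
#' relevant), a timestamp and the package version.
#'
#' @param command Command or function name.
#' @param config Named list snapshot of the settings used.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(command, config = list()) {
  structure(list(command = command, config = config,
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                 package = "ricianfit",
                 version = as.character(utils::packageVersion("ricianfit"))),
            class = "run_manifest")
}

#' Write a manifest to JSON
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
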