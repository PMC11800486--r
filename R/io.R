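#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file path (.nii or .nii.gz).
#' @return object of class `volume_file`: `data` (numeric array), `affine`
#'   (4x4 voxel-to-world matrix), `path`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such volume: %s", path))
  img <- RNifti::readNifti(path)
  raw <- as.array(img)
  structure(list(data = array(as.numeric(raw), dim = dim(raw)),
                 affine = structure(RNifti::xform(img), class = NULL),
                 path = path),
            class = "volume_file")
}

#' Write a NIfTI volume
#'
#' @param data numeric array (a bare array, or a `susceptibility_map` /
#'   `field_map` / `hpf_phase_image`, whose `values` are taken; the
#'   geometry's voxel size then sets the affine scaling).
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size mm per voxel (scalar or length 3) when `data` is a bare
#'   array.
#' @return invisibly, `path`.
#' @export
write_volume <- function(data, path, voxel_size = 0.5) {
  if (is.list(data) && !is.null(data$values)) {
    voxel_size <- data$geometry$voxel_size
    data <- data$values
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  attr(data, "pixdim") <- voxel_size
  img <- RNifti::asNifti(data, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a complex echo series stored as magnitude/phase NIfTI pairs
#'
#' The on-disk convention stores each complex volume as two NIfTI files:
#' magnitude, and phase in radians.
#'
#' @param magnitude_paths,phase_paths equal-length vectors of NIfTI paths,
#'   one pair per echo.
#' @param echo_times ms, one per echo.
#' @param b0_field Tesla.
#' @param voxel_size mm.
#' @param b0_direction unit 3-vector.
#' @return an `echo_series`.
#' @export
read_echo_series <- function(magnitude_paths, phase_paths, echo_times,
                             b0_field = 3, voxel_size = 0.5,
                             b0_direction = c(0, 0, 1)) {
  if (length(magnitude_paths) != length(phase_paths))
    stop("magnitude and phase path lists differ in length")
  if (length(magnitude_paths) != length(echo_times))
    stop("need one echo time per volume pair")
  echoes <- vector("list", length(echo_times))
  shp <- NULL
  for (e in seq_along(echo_times)) {
    m <- read_volume(magnitude_paths[e]); p <- read_volume(phase_paths[e])
    if (!all(dim(m$data) == dim(p$data)))
      stop(sprintf("shape mismatch between %s and %s",
                   magnitude_paths[e], phase_paths[e]))
    if (is.null(shp)) shp <- dim(m$data)
    else if (!all(dim(m$data) == shp))
      stop(sprintf("echo %d shape differs from echo 1", e))
    echoes[[e]] <- m$data * exp(1i * p$data)
  }
  structure(list(echoes = echoes, echo_times = as.numeric(echo_times),
                 b0_field = b0_field,
                 geometry = grid_geometry(shp, voxel_size, b0_direction)),
            class = "echo_series")
}

#' Write an echo series as magnitude/phase NIfTI pairs
#'
#' @param echoes an `echo_series`.
#' @param prefix output path prefix; files are
#'   `<prefix>_e<k>_mag.nii.gz` / `<prefix>_e<k>_phase.nii.gz`.
#' @return invisibly, a list with `magnitude` and `phase` path vectors.
#' @export
write_echo_series <- function(echoes, prefix) {
  mp <- pp <- character(length(echoes$echoes))
  for (e in seq_along(echoes$echoes)) {
    mp[e] <- sprintf("%s_e%d_mag.nii.gz", prefix, e)
    pp[e] <- sprintf("%s_e%d_phase.nii.gz", prefix, e)
    write_volume(Mod(echoes$echoes[[e]]), mp[e], echoes$geometry$voxel_size)
    write_volume(Arg(echoes$echoes[[e]]), pp[e], echoes$geometry$voxel_size)
  }
  invisible(list(magnitude = mp, phase = pp))
}

#' Load an experiment configuration from YAML
#'
#' Recognised keys mirror [experiment_config()] arguments; `shape`,
#' `voxel_size` and `b0_direction` build the geometry, and an `inversion`
#' block builds the [inversion_config()]. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_per_class", "shape", "voxel_size", "b0_direction", "b0_field",
             "echo_times", "noise_sigma", "m0", "r2star", "filter_radius",
             "inversion", "z_threshold", "coverage_min",
             "annulus_width_voxels", "coverage_floor", "seed", "output_dir")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  geom <- grid_geometry(shape = y$shape %||% c(128L, 128L, 128L),
                        voxel_size = y$voxel_size %||% 0.5,
                        b0_direction = y$b0_direction %||% c(0, 0, 1))
  inv <- if (is.null(y$inversion)) inversion_config("tkd")
         else do.call(inversion_config, y$inversion)
  args <- y[setdiff(names(y), c("shape", "voxel_size", "b0_direction", "inversion"))]
  do.call(experiment_config, c(args, list(geometry = geom, inversion = inv)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
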