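#' Grid geometry for a 3D acquisition volume
#'
#' Describes the voxel lattice on which phantoms, fields and reconstructions
#' live: matrix size, isotropic-or-not voxel size in mm, and the direction of
#' the main magnetic field B0 expressed in the grid frame.
#'
#' World coordinates place the grid centre at the origin: voxel `i` (1-based)
#' along an axis with `n` voxels and spacing `dx` sits at
#' `(i - 1 - (n - 1)/2) * dx` mm.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 16).
#' @param voxel_size numeric length 1 or 3, mm per voxel (default 0.5 mm
#'   isotropic, matching a 0.5 x 0.5 x 0.5 mm^3 gradient-echo protocol).
#' @param b0_direction numeric length 3, direction of B0; normalised to a
#'   unit vector. Default is along the third grid axis (the slab normal).
#' @return an object of class `grid_geometry` with fields `shape`,
#'   `voxel_size`, `b0_direction`.
#' @export
grid_geometry <- function(shape = c(128L, 128L, 128L),
                          voxel_size = 0.5,
                          b0_direction = c(0, 0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 16L))
    stop("shape must be 3 integers, each >= 16")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be positive (length 1 or 3)")
  nb <- sqrt(sum(b0_direction^2))
  if (length(b0_direction) != 3L || nb == 0)
    stop("b0_direction must be a nonzero 3-vector")
  structure(list(shape = shape,
                 voxel_size = as.numeric(voxel_size),
                 b0_direction = as.numeric(b0_direction / nb)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, B0 = (%.3g, %.3g, %.3g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$b0_direction[1], x$b0_direction[2], x$b0_direction[3]))
  invisible(x)
}

# Voxel-centre world coordinates (mm, grid centred at origin) along one axis.
axis_coords <- function(n, dx) (seq_len(n) - 1 - (n - 1) / 2) * dx

#' Voxel-centre coordinate arrays for a geometry
#'
#' @param geometry a [grid_geometry()].
#' @return list of three arrays (`x`, `y`, `z`), each of dim `shape`, holding
#'   the mm world coordinate of every voxel centre along that axis.
#' @keywords internal
voxel_coordinates <- function(geometry) {
  s <- geometry$shape; v <- geometry$voxel_size
  cx <- axis_coords(s[1], v[1])
  cy <- axis_coords(s[2], v[2])
  cz <- axis_coords(s[3], v[3])
  list(x = array(rep(cx, times = s[2] * s[3]), dim = s),
       y = array(rep(rep(cy, each = s[1]), times = s[3]), dim = s),
       z = array(rep(cz, each = s[1] * s[2]), dim = s))
}

# FFT sample frequencies (cycles per mm) for n samples of spacing dx,
# in the order stats::fft uses: 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1.
fft_freq <- function(n, dx = 1) {
  k <- c(seq(0L, floor(n / 2)), seq(-(ceiling(n / 2) - 1L), -1L))
  k / (n * dx)
}

# 3D FFT wrappers; stats::fft is unnormalised, so the inverse divides by N.
fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)
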