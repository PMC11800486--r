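#' Select the echo closest to a target echo time
#'
#' @param echo_times echo times, ms (>= 1).
#' @param target target TE, ms; default 20 ms (the echo conventionally used
#'   for susceptibility-weighted phase).
#' @return 1-based echo index minimising `|TE - target|`; ties break toward
#'   the earlier echo.
#' @export
select_echo <- function(echo_times, target = 20) {
  if (length(echo_times) < 1L) stop("echo_times is empty")
  which.min(abs(echo_times - target))  # which.min takes the first minimum
}

#' 2D circularly symmetric low-pass Hanning kernel
#'
#' `w(k) = 0.5 (1 + cos(pi |k| / R))` for `|k| <= R`, 0 beyond, where `|k|`
#' is the radial distance from the zero-frequency sample in units of k-space
#' voxels of the (unpadded) slice matrix. The weight at the centre is 1.
#'
#' @param slice_shape integer length 2, slice matrix size.
#' @param radius_voxels kernel radius R in k-space voxels (default 128).
#' @return real matrix of dim `slice_shape` in `stats::fft` frequency order.
#' @export
hanning_lowpass_kernel <- function(slice_shape, radius_voxels = 128) {
  if (radius_voxels <= 0) stop("radius_voxels must be > 0")
  # fft-ordered integer sample offsets from DC
  kx <- fft_freq(slice_shape[1], 1) * slice_shape[1]
  ky <- fft_freq(slice_shape[2], 1) * slice_shape[2]
  r <- sqrt(outer(kx^2, ky^2, "+"))
  w <- 0.5 * (1 + cos(pi * r / radius_voxels))
  w[r > radius_voxels] <- 0
  w
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' High-pass-filtered phase reconstruction
#'
#' For each 2D slice of the selected echo: transform to k-space, multiply by
#' the circularly symmetric low-pass Hanning kernel, transform back to get a
#' low-pass complex image, then take the phase of the complex division of the
#' original slice by its low-pass version. The division removes the smooth
#' background phase without explicit unwrapping; the side effect — and the
#' confound this package studies — is that the smooth interior phase of a
#' solid lesion is nulled too, leaving a rim-like residue at its boundary.
#'
#' @param echoes an `echo_series`.
#' @param radius_voxels Hanning kernel radius, k-space voxels (default 128).
#' @param target_te echo-selection target, ms (default 20).
#' @param slice_axis grid axis perpendicular to the 2D filter plane (default
#'   3, the slab normal).
#' @return object of class `hpf_phase_image`: `values` (3D phase array in
#'   `(-pi, pi]` radians), `echo_index`, `radius_voxels`, `valid` (logical
#'   mask, FALSE where the low-pass magnitude underflowed), `geometry`.
#' @export
hpf_phase <- function(echoes, radius_voxels = 128, target_te = 20,
                      slice_axis = 3L) {
  stopifnot(inherits(echoes, "echo_series"))
  idx <- select_echo(echoes$echo_times, target_te)
  vol <- echoes$echoes[[idx]]
  s <- dim(vol)
  perm <- switch(slice_axis, c(2L, 3L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))
  vol_p <- aperm(vol, perm)
  sp <- dim(vol_p)
  w <- hanning_lowpass_kernel(sp[1:2], radius_voxels)
  phase <- array(0, dim = sp)
  valid <- array(TRUE, dim = sp)
  for (z in seq_len(sp[3])) {
    sl <- vol_p[, , z]
    lp <- ifft2(w * fft2(sl))
    eps <- 1e-12 * max(Mod(lp))
    bad <- Mod(lp) <= eps
    ratio <- sl / lp
    ph <- Arg(ratio)
    ph[bad] <- 0
    phase[, , z] <- ph
    valid[, , z] <- !bad
  }
  inv <- order(perm)
  structure(list(values = aperm(phase, inv), echo_index = idx,
                 radius_voxels = radius_voxels,
                 valid = aperm(valid, inv),
                 geometry = echoes$geometry),
            class = "hpf_phase_image")
}
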