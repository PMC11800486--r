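#' @name dipole_forward
#' @title Susceptibility-to-field forward model
#' @description
#' The induced resonance-frequency shift of a susceptibility distribution chi
#' (ppm) in a strong field B0 is, in the Fourier domain,
#' `B(k) = D(k) X(k)` with the unit dipole kernel
#' `D(k) = 1/3 - (k . b0)^2 / |k|^2`. The zero-frequency value is set to 0
#' (zero-mean field convention: the absolute offset is unobservable).
NULL

# Reduced gyromagnetic ratio of the proton, Hz per Tesla.
GAMMA_BAR_HZ_PER_T <- 42.577e6

#' k-space dipole kernel for a grid geometry
#'
#' @param geometry a [grid_geometry()].
#' @return real 3D array in `[-2/3, 1/3]` laid out in `stats::fft` frequency
#'   order, with the zero-frequency sample set to 0.
#' @export
dipole_kernel <- function(geometry) {
  s <- geometry$shape; v <- geometry$voxel_size; b0 <- geometry$b0_direction
  kx <- fft_freq(s[1], v[1]); ky <- fft_freq(s[2], v[2]); kz <- fft_freq(s[3], v[3])
  KX <- array(rep(kx, times = s[2] * s[3]), dim = s)
  KY <- array(rep(rep(ky, each = s[1]), times = s[3]), dim = s)
  KZ <- array(rep(kz, each = s[1] * s[2]), dim = s)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b0[1] + KY * b0[2] + KZ * b0[3]
  d <- 1 / 3 - kb^2 / k2
  d[1, 1, 1] <- 0  # k = 0: zero-mean field convention
  d
}

#' Forward field of a susceptibility map
#'
#' Computes the local field perturbation (ppm of B0) induced by a
#' susceptibility map via FFT convolution with the dipole kernel. Linear in
#' chi; a spatially constant chi maps to a zero field.
#'
#' @param chi a `susceptibility_map`.
#' @param pad logical; zero-pad to twice the grid before convolving to
#'   suppress circular wrap-around (default FALSE; oracle comparisons then
#'   restrict to the inner half-grid).
#' @return object of class `field_map` (fields `values` in ppm, `geometry`).
#' @export
forward_field <- function(chi, pad = FALSE) {
  stopifnot(inherits(chi, "susceptibility_map"))
  g <- chi$geometry
  if (pad) {
    s2 <- 2L * g$shape
    big <- array(0, dim = s2)
    idx <- lapply(g$shape, seq_len)
    big[idx[[1]], idx[[2]], idx[[3]]] <- chi$values
    g2 <- grid_geometry(s2, g$voxel_size, g$b0_direction)
    d <- dipole_kernel(g2)
    f <- Re(ifft3(d * fft3(big)))[idx[[1]], idx[[2]], idx[[3]]]
  } else {
    d <- dipole_kernel(g)
    f <- Re(ifft3(d * fft3(chi$values)))
  }
  structure(list(values = f, geometry = g), class = "field_map")
}

#' Closed-form field of a uniformly magnetized sphere
#'
#' Lorentz-corrected field of a sphere of radius `a` and susceptibility
#' contrast `delta_chi` (ppm): zero inside, and
#' `(delta_chi / 3) (a / r)^3 (3 cos^2 theta - 1)` outside, with `theta`
#' measured from the B0 axis. A solid sphere's external field is exactly a
#' dipole — the physical root of the rim-appearance confound on filtered
#' phase images.
#'
#' @param radius sphere radius, mm (> 0).
#' @param delta_chi susceptibility contrast, ppm.
#' @param points n x 3 matrix of mm coordinates relative to the sphere
#'   centre.
#' @param b0_direction unit 3-vector, default `c(0, 0, 1)`.
#' @return numeric vector of field values, ppm. Points with `r <= radius`
#'   (including r = 0) return the interior value 0.
#' @export
analytic_sphere_field <- function(radius, delta_chi, points,
                                  b0_direction = c(0, 0, 1)) {
  if (radius <= 0) stop("radius must be > 0")
  points <- matrix(as.numeric(points), ncol = 3)
  b0 <- b0_direction / sqrt(sum(b0_direction^2))
  r <- sqrt(rowSums(points^2))
  ct2 <- ifelse(r > 0, (points %*% b0)[, 1]^2 / r^2, 0)
  out <- ifelse(r > radius,
                (delta_chi / 3) * (radius / r)^3 * (3 * ct2 - 1),
                0)
  as.numeric(out)
}

#' Closed-form field of a uniform spherical shell
#'
#' Superposition of two solid spheres (outer minus inner): zero in the
#' cavity, and outside the shell the field of a solid sphere with matched
#' total moment `delta_chi (a_out^3 - a_in^3)`. Hence a shell and a solid
#' sphere of equal moment are indistinguishable from their external fields
#' alone.
#'
#' @inheritParams analytic_sphere_field
#' @param inner_radius,outer_radius shell radii, mm, `0 < inner < outer`.
#' @return numeric vector of field values, ppm.
#' @export
analytic_shell_field <- function(inner_radius, outer_radius, delta_chi,
                                 points, b0_direction = c(0, 0, 1)) {
  if (!(inner_radius > 0 && outer_radius > inner_radius))
    stop("need 0 < inner_radius < outer_radius")
  analytic_sphere_field(outer_radius, delta_chi, points, b0_direction) -
    analytic_sphere_field(inner_radius, delta_chi, points, b0_direction)
}

#' Synthesize a multi-echo gradient-echo acquisition
#'
#' Per-voxel complex signal at echo time TE (seconds internally; the
#' interface uses ms):
#' `m0 exp(-R2* TE) exp(i 2 pi gamma_bar B0 field_ppm 1e-6 TE)`,
#' plus i.i.d. complex Gaussian noise of standard deviation
#' `noise_sigma * max(m0)` per real/imaginary channel.
#'
#' @param chi a `susceptibility_map` (the field is computed internally via
#'   [forward_field()]), or a `field_map` to use a precomputed field.
#' @param m0 proton-density / steady-state magnitude grid, or a scalar.
#' @param r2star R2* relaxation-rate grid in 1/s, or a scalar.
#' @param echo_times strictly increasing echo times, ms. Default is the
#'   8-echo train 3.4, 9.0, ..., 42.6 ms (TE1 = 3.4 ms, dTE = 5.6 ms).
#' @param b0_field main field strength, Tesla (default 3).
#' @param noise_sigma complex-noise SD as a fraction of max(m0); 0 disables.
#' @param seed integer seed for the noise.
#' @param pad passed to [forward_field()] when `chi` is a susceptibility map.
#' @return object of class `echo_series`: list with `echoes` (list of complex
#'   3D arrays), `echo_times` (ms), `b0_field`, and the `geometry`.
#' @export
synthesize_gre <- function(chi, m0 = 1, r2star = 15,
                           echo_times = default_echo_times(),
                           b0_field = 3, noise_sigma = 0, seed = 1L,
                           pad = FALSE) {
  if (is.unsorted(echo_times, strictly = TRUE)) stop("echo_times must be strictly increasing")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  fieldmap <- if (inherits(chi, "field_map")) chi else forward_field(chi, pad = pad)
  g <- fieldmap$geometry
  if (length(m0) == 1L) m0 <- array(m0, dim = g$shape)
  if (length(r2star) == 1L) r2star <- array(r2star, dim = g$shape)
  omega <- 2 * pi * GAMMA_BAR_HZ_PER_T * b0_field * fieldmap$values * 1e-6  # rad/s
  sd_noise <- noise_sigma * max(m0)
  set.seed(seed)
  echoes <- vector("list", length(echo_times))
  for (e in seq_along(echo_times)) {
    te <- echo_times[e] * 1e-3
    sig <- m0 * exp(-r2star * te) * exp(1i * omega * te)
    if (sd_noise > 0)
      sig <- sig + complex(real = stats::rnorm(length(sig), 0, sd_noise),
                           imaginary = stats::rnorm(length(sig), 0, sd_noise))
    echoes[[e]] <- array(sig, dim = g$shape)
  }
  structure(list(echoes = echoes, echo_times = as.numeric(echo_times),
                 b0_field = b0_field, geometry = g),
            class = "echo_series")
}

#' Default 8-echo gradient-echo train (ms)
#'
#' First TE 3.4 ms, echo spacing 5.6 ms, 8 echoes.
#' @param n_echoes number of echoes.
#' @param te1 first echo time, ms.
#' @param dte echo spacing, ms.
#' @return numeric vector of echo times in ms.
#' @export
default_echo_times <- function(n_echoes = 8L, te1 = 3.4, dte = 5.6)
  te1 + dte * (seq_len(n_echoes) - 1)
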