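#' Estimate the total field from a multi-echo series
#'
#' Per voxel, the echo phases are temporally unwrapped (each echo's principal
#' phase is shifted by the multiple of 2*pi closest to the prediction of a
#' running magnitude-weighted slope estimate, seeded by the first-echo phase)
#' and a magnitude-weighted linear fit of phase versus TE with a free
#' intercept yields the off-resonance slope, converted to ppm of B0.
#' Valid while `|phase(TE1)| < pi`; beyond that the first-echo seed itself
#' aliases.
#'
#' @param echoes an `echo_series` with >= 2 echoes.
#' @param mask_threshold voxels whose mean magnitude falls at or below this
#'   fraction of the maximum mean magnitude are masked out with weight 0
#'   (default 0, i.e. only identically zero-signal voxels are dropped).
#' @return object of class `total_field_estimate`: `field` (ppm array),
#'   `weights` (nonnegative array: mean signal magnitude, 0 outside mask),
#'   `mask` (logical array), `geometry`.
#' @export
estimate_field <- function(echoes, mask_threshold = 0) {
  stopifnot(inherits(echoes, "echo_series"))
  ne <- length(echoes$echoes)
  if (ne < 2L) stop("need at least 2 echoes to fit a field")
  te <- echoes$echo_times * 1e-3  # s
  g <- echoes$geometry

  mags <- lapply(echoes$echoes, Mod)
  mean_mag <- Reduce(`+`, mags) / ne
  mask <- mean_mag > mask_threshold * max(mean_mag)

  # temporally unwrapped phase per echo, accumulated WLS statistics
  unwrapped <- vector("list", ne)
  unwrapped[[1]] <- Arg(echoes$echoes[[1]])
  slope <- unwrapped[[1]] / te[1]          # running rad/s estimate
  sw <- mags[[1]]; swx <- sw * te[1]; swy <- sw * unwrapped[[1]]
  swxx <- sw * te[1]^2; swxy <- swx * unwrapped[[1]]
  for (e in 2:ne) {
    pred <- slope * te[e]
    p <- Arg(echoes$echoes[[e]])
    p <- p + 2 * pi * round((pred - p) / (2 * pi))
    unwrapped[[e]] <- p
    w <- mags[[e]]
    sw <- sw + w; swx <- swx + w * te[e]; swy <- swy + w * p
    swxx <- swxx + w * te[e]^2; swxy <- swxy + w * te[e] * p
    # refresh the running slope from the fit so far (guarded denominator)
    den <- sw * swxx - swx^2
    ok <- den > 0
    slope[ok] <- ((sw * swxy - swx * swy)[ok]) / den[ok]
  }
  den <- sw * swxx - swx^2
  slope_fit <- array(0, dim = g$shape)
  ok <- den > 0 & mask
  slope_fit[ok] <- ((sw * swxy - swx * swy)[ok]) / den[ok]

  field <- slope_fit / (2 * pi * GAMMA_BAR_HZ_PER_T * echoes$b0_field * 1e-6)
  weights <- mean_mag
  weights[!mask] <- 0
  structure(list(field = field, weights = weights, mask = mask, geometry = g),
            class = "total_field_estimate")
}

as_field_array <- function(field) {
  if (inherits(field, "total_field_estimate")) field$field
  else if (inherits(field, "field_map")) field$values
  else field
}

#' Thresholded k-space division (TKD) dipole inversion
#'
#' `X(k) = F(k) / D(k)` where `|D| >= threshold`, and
#' `F(k) sign(D) / threshold` inside the zero cone of the kernel. The
#' simplest dipole deconvolution; linear in the field.
#'
#' @param field a `total_field_estimate`, `field_map`, or bare ppm array.
#' @param geometry a [grid_geometry()] (taken from `field` when it carries
#'   one).
#' @param threshold kernel magnitude floor, in `(0, 2/3]` (default 0.2).
#' @return object of class `susceptibility_map` (ppm).
#' @export
tkd_inversion <- function(field, geometry = NULL, threshold = 0.2) {
  if (threshold <= 0 || threshold > 2 / 3) stop("threshold must be in (0, 2/3]")
  if (is.null(geometry)) geometry <- field$geometry
  f <- as_field_array(field)
  d <- dipole_kernel(geometry)
  inv <- ifelse(abs(d) >= threshold, 1 / d, sign(d) / threshold)
  inv[1, 1, 1] <- 0  # DC unobservable
  chi <- Re(ifft3(inv * fft3(f)))
  structure(list(values = chi, geometry = geometry), class = "susceptibility_map")
}

#' Inversion configuration
#'
#' @param method `"tkd"` or `"tikhonov_tfi"`.
#' @param tkd_threshold TKD kernel floor, `(0, 2/3]`.
#' @param lambda gradient (Tikhonov) regularization weight, >= 0.
#' @param max_iterations conjugate-gradient iteration cap, >= 1.
#' @param tolerance relative-residual stopping tolerance.
#' @param preconditioner_weight diagonal right-preconditioner value applied
#'   outside the reliability mask (expected susceptibility dynamic range of
#'   the masked-out region relative to tissue).
#' @return list of class `inversion_config`.
#' @export
inversion_config <- function(method = c("tkd", "tikhonov_tfi"),
                             tkd_threshold = 0.2, lambda = 1e-3,
                             max_iterations = 50L, tolerance = 1e-6,
                             preconditioner_weight = 30) {
  method <- match.arg(method)
  if (tkd_threshold <= 0 || tkd_threshold > 2 / 3) stop("tkd_threshold in (0, 2/3]")
  if (lambda < 0) stop("lambda must be >= 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(method = method, tkd_threshold = tkd_threshold,
                 lambda = lambda, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 preconditioner_weight = preconditioner_weight),
            class = "inversion_config")
}

# forward differences with periodic boundary, one axis
shift_fwd <- function(x, axis) {
  n <- dim(x)[axis]
  idx <- c(seq(2L, n), 1L)
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
}
shift_bwd <- function(x, axis) {
  n <- dim(x)[axis]
  idx <- c(n, seq_len(n - 1L))
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
}
# grad^T grad (periodic Laplacian, negated): sum_axis (2x - shift_fwd - shift_bwd)
gtg <- function(x) {
  6 * x - shift_fwd(x, 1) - shift_bwd(x, 1) -
          shift_fwd(x, 2) - shift_bwd(x, 2) -
          shift_fwd(x, 3) - shift_bwd(x, 3)
}

#' Regularized total-field dipole inversion
#'
#' Minimises `|| W (d (*) chi - f) ||^2 + lambda || grad chi ||^2` by
#' conjugate gradients on the normal equations, where `(*)` is FFT
#' convolution with the dipole kernel, `W` the reliability weights
#' (normalised to unit maximum), and the gradient uses forward differences
#' with periodic boundaries. A diagonal right-preconditioner boosts the
#' expected dynamic range outside the reliability mask. This is a linear
#' stand-in for nonlinear preconditioned total-field inversion solvers: the
#' property it preserves — and the one the rim analysis needs — is dipole
#' deconvolution of the unprocessed total field.
#'
#' @param field a `total_field_estimate` (its weights are used; a bare
#'   `field_map`/array gets unit weights).
#' @param config an [inversion_config()].
#' @param geometry required when `field` carries no geometry.
#' @return `susceptibility_map` with attribute `convergence`: list with
#'   `iterations`, `residuals` (relative residual per iteration),
#'   `converged`, `diverged`.
#' @export
tikhonov_tfi_inversion <- function(field, config = inversion_config(method = "tikhonov_tfi"),
                                   geometry = NULL) {
  if (is.null(geometry)) geometry <- field$geometry
  f <- as_field_array(field)
  w <- if (inherits(field, "total_field_estimate")) field$weights else array(1, dim(f))
  wmax <- max(w)
  if (wmax <= 0) stop("all reliability weights are zero")
  w2 <- (w / wmax)^2
  d <- dipole_kernel(geometry)
  conv_d <- function(x) Re(ifft3(d * fft3(x)))
  # right preconditioner: expected dynamic range, larger outside the mask
  mask <- if (inherits(field, "total_field_estimate")) field$mask else array(TRUE, dim(f))
  prec <- array(1, dim(f)); prec[!mask] <- config$preconditioner_weight
  # solve (P A P) y = P b, chi = P y  with A = C W^2 C + lambda L
  A <- function(y) {
    x <- prec * y
    prec * (conv_d(w2 * conv_d(x)) + config$lambda * gtg(x))
  }
  b <- prec * conv_d(w2 * f)
  y <- array(0, dim(f))
  r <- b; p <- r
  rs <- sum(r * r); b2 <- sqrt(sum(b * b))
  residuals <- numeric(0); n_bad <- 0L; diverged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    Ap <- A(p)
    alpha <- rs / sum(p * Ap)
    y <- y + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    rel <- sqrt(rs_new) / b2
    residuals <- c(residuals, rel)
    if (rel < config$tolerance) break
    n_bad <- if (length(residuals) > 1L && rel > residuals[length(residuals) - 1L]) n_bad + 1L else 0L
    if (n_bad >= 10L) { diverged <- TRUE; warning("CG residual increased for 10 consecutive iterations; returning partial result"); break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  chi <- prec * y
  out <- structure(list(values = chi, geometry = geometry), class = "susceptibility_map")
  attr(out, "convergence") <- list(iterations = it, residuals = residuals,
                                   converged = length(residuals) > 0 && residuals[length(residuals)] < config$tolerance,
                                   diverged = diverged)
  out
}
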