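test_that("dipole kernel hits its closed-form limits and range", {
  g <- small_geom(32)
  d <- dipole_kernel(g)
  expect_equal(d[1, 1, 1], 0)                    # DC nulled
  expect_equal(d[1, 1, 2], -2 / 3)               # k along B0
  expect_equal(d[2, 1, 1], 1 / 3)                # k orthogonal to B0
  expect_equal(d[2, 2, 2], 0, tolerance = 1e-12) # (1,1,1): cos^2 = 1/3, magic angle
  expect_true(all(d >= -2 / 3 - 1e-12 & d <= 1 / 3 + 1e-12))
})

test_that("forward field of a constant map is zero and the operator is linear", {
  g <- small_geom(32)
  const <- structure(list(values = array(0.3, g$shape), geometry = g),
                     class = "susceptibility_map")
  expect_lt(max(abs(forward_field(const)$values)), 1e-12)

  set.seed(1)
  x1 <- structure(list(values = array(rnorm(32^3), g$shape), geometry = g),
                  class = "susceptibility_map")
  x2 <- structure(list(values = array(rnorm(32^3), g$shape), geometry = g),
                  class = "susceptibility_map")
  lhs <- forward_field(structure(list(values = 2 * x1$values - 3 * x2$values,
                                      geometry = g), class = "susceptibility_map"))
  rhs <- 2 * forward_field(x1)$values - 3 * forward_field(x2)$values
  expect_lt(max(abs(lhs$values - rhs)), 1e-10)
})

test_that("analytic sphere field evaluates the closed form", {
  # interior (including the centre) is zero
  expect_equal(analytic_sphere_field(2, 0.12, rbind(c(0, 0, 0), c(0.5, 0.5, 0))),
               c(0, 0))
  # on-axis point r = 2a: (chi/3)(1/8)(2)
  expect_equal(analytic_sphere_field(2, 0.12, cbind(0, 0, 4)), 0.12 / 3 / 8 * 2)
  # equatorial point r = 2a: -(chi/3)(1/8)
  expect_equal(analytic_sphere_field(2, 0.12, cbind(4, 0, 0)), -0.12 / 3 / 8)
})

test_that("shell field is the two-sphere superposition with matched-moment identity", {
  set.seed(2)
  pts <- matrix(rnorm(300, sd = 8), ncol = 3)
  r <- sqrt(rowSums(pts^2))
  shell <- analytic_shell_field(3, 4, 0.1, pts)
  # cavity is field-free
  expect_true(all(shell[r < 3] == 0))
  # superposition identity
  expect_equal(shell,
               analytic_sphere_field(4, 0.1, pts) - analytic_sphere_field(3, 0.1, pts),
               tolerance = 1e-15)
  # externally the shell equals a solid sphere of matched total moment
  ext <- r > 4
  chi_solid <- 0.1 * (4^3 - 3^3) / 4^3
  expect_equal(shell[ext], analytic_sphere_field(4, chi_solid, pts[ext, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("FFT forward field matches the analytic sphere away from the interface", {
  ph <- solid_phantom(radius = 4, chi = 0.1, n = 64)
  f <- forward_field(build_susceptibility_map(ph))
  co <- qsmrim:::voxel_coordinates(ph$geometry)
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  fa <- analytic_sphere_field(4, 0.1, pts)
  r <- sqrt(rowSums(pts^2))
  inner <- abs(pts[, 1]) < 8 & abs(pts[, 2]) < 8 & abs(pts[, 3]) < 8
  away <- r > 4 + 1 | r < 4 - 1          # outside a 2-voxel interface band
  sel <- inner & away
  peak <- max(abs(fa[r > 4]))
  expect_lt(max(abs(as.vector(f$values)[sel] - fa[sel])), 0.05 * peak)
})

test_that("multi-echo synthesis follows the signal equation", {
  g <- small_geom(16)  # sub-minimum shape guard is on grid_geometry only
  expect_error(grid_geometry(c(8, 8, 8)))
  g <- small_geom(16)
  field <- structure(list(values = array(0.1, g$shape), geometry = g),
                     class = "field_map")
  e <- synthesize_gre(field, echo_times = c(3.4, 20.2), noise_sigma = 0)
  # phase at TE = 20.2 ms for 0.1 ppm at 3 T: ~1.621 rad
  expect_equal(Arg(e$echoes[[2]][1, 1, 1]), expected_phase(0.1, 20.2),
               tolerance = 1e-9)
  expect_equal(expected_phase(0.1, 20.2), 1.621, tolerance = 1e-3)
  # zero field, no noise: zero phase at all echoes
  zf <- structure(list(values = array(0, g$shape), geometry = g), class = "field_map")
  e0 <- synthesize_gre(zf, echo_times = default_echo_times(), noise_sigma = 0)
  expect_true(all(vapply(e0$echoes, function(s) max(abs(Arg(s))), numeric(1)) == 0))
  # magnitude decays monotonically in TE when R2* > 0
  mags <- vapply(e0$echoes, function(s) mean(Mod(s)), numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("the default echo train is 8 echoes from 3.4 ms in 5.6 ms steps", {
  expect_equal(default_echo_times(),
               c(3.4, 9.0, 14.6, 20.2, 25.8, 31.4, 37.0, 42.6))
})

test_that("matched-moment solid and shell FFT fields agree outside the lesion", {
  g <- small_geom(64)
  shell <- build_susceptibility_map(
    rim_phantom(radius = 3, core_chi = 0, rim_chi = 0.1, thickness = 1, n = 64))
  chi_solid <- 0.1 * (4^3 - 3^3) / 4^3
  solid <- build_susceptibility_map(solid_phantom(radius = 4, chi = chi_solid, n = 64))
  fs <- forward_field(shell)$values
  fo <- forward_field(solid)$values
  r <- radius_grid(g)
  ext <- r > 5 & r < 12
  peak <- max(abs(fo[r > 4]))
  expect_lt(max(abs(fs[ext] - fo[ext])), 0.05 * peak)
})
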