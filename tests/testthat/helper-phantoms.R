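# Shared fixture builders. Grids are kept small (32-64 voxels) so the unit
# suite stays fast; resolution-sensitive checks use the full study grid in
# the acceptance tests.

small_geom <- function(n = 48L, voxel = 0.5) grid_geometry(rep(n, 3L), voxel)

solid_phantom <- function(radius = 4, chi = 0.05, n = 48L, voxel = 0.5) {
  phantom_spec(small_geom(n, voxel),
               list(lesion_spec(c(0, 0, 0), radius, core_chi = chi)))
}

rim_phantom <- function(radius = 4, core_chi = 0.05, rim_chi = 0.1,
                        thickness = 1, coverage = 1, n = 48L, voxel = 0.5) {
  phantom_spec(small_geom(n, voxel),
               list(lesion_spec(c(0, 0, 0), radius, core_chi = core_chi,
                                rim_chi = rim_chi, rim_thickness = thickness,
                                rim_coverage = coverage)))
}

# voxel-centre radii (mm) from the grid centre, as a 3D array
radius_grid <- function(geometry) {
  co <- qsmrim:::voxel_coordinates(geometry)
  sqrt(co$x^2 + co$y^2 + co$z^2)
}

# phase accrued by a field of f ppm at TE ms in B0 Tesla (the signal-model
# arithmetic, restated independently of the implementation)
expected_phase <- function(f_ppm, te_ms, b0 = 3)
  2 * pi * 42.577e6 * b0 * f_ppm * 1e-6 * te_ms * 1e-3
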