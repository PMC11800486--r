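# Builds a 3D fixture with a disc lesion in the central slice, a constant
# core level, an annulus offset in chosen sectors, and Gaussian background.
make_fixture <- function(n = 48, radius = 8, core = 0, annulus_delta = 0,
                         half_only = FALSE, sigma = 1, seed = 1) {
  set.seed(seed)
  img <- array(rnorm(n^3, 0, sigma), dim = rep(n, 3))
  cx <- (n + 1) / 2
  ix <- slice.index(array(0, rep(n, 3)), 1) - cx
  iy <- slice.index(array(0, rep(n, 3)), 2) - cx
  iz <- slice.index(array(0, rep(n, 3)), 3) - cx
  r2d <- sqrt(ix^2 + iy^2)
  mask <- r2d <= radius & abs(iz) <= 3
  img[mask] <- core
  ann <- r2d > radius & r2d <= radius + 2 & abs(iz) <= 3
  if (half_only) ann <- ann & ix >= 0
  img[ann] <- core + annulus_delta
  bg <- r2d > radius + 6 & r2d <= radius + 14
  list(img = img, mask = mask, bg = bg)
}

test_that("a constant image scores zero contrast and zero coverage", {
  n <- 32
  img <- array(1.5, rep(n, 3))
  fx <- make_fixture(n = n, radius = 6)
  sc <- rim_score(img, fx$mask, fx$bg)
  expect_equal(sc$z_contrast, 0)
  expect_equal(sc$angular_coverage, 0)
  expect_false(sc$reliable)   # no background spread to calibrate against
})

test_that("a uniformly elevated annulus scores its z offset and full coverage", {
  fx <- make_fixture(annulus_delta = 5, sigma = 1)
  sc <- rim_score(fx$img, fx$mask, fx$bg)
  expect_equal(sc$z_contrast, 5, tolerance = 0.15)
  expect_equal(sc$angular_coverage, 1)
  expect_true(sc$reliable)
})

test_that("a half-elevated annulus reports about half angular coverage", {
  fx <- make_fixture(annulus_delta = 5, half_only = TRUE)
  sc <- rim_score(fx$img, fx$mask, fx$bg, n_sectors = 12)
  expect_lte(abs(sc$angular_coverage - 0.5), 1 / 12 + 1e-9)
})

test_that("too-small lesions are flagged unreliable and their call withheld", {
  fx <- make_fixture(radius = 1.5)
  sc <- rim_score(fx$img, fx$mask, fx$bg, annulus_width_voxels = 2)
  expect_false(sc$reliable)
  expect_true(is.na(classify_rim(sc, "qsm")$call))
})

test_that("classification applies the modality sign convention", {
  mk <- function(z, cov) structure(list(lesion_id = 1L, z_contrast = z,
                                        angular_coverage = cov, noise_sigma = 1,
                                        reliable = TRUE), class = "rim_score")
  expect_equal(classify_rim(mk(0, 0), "qsm")$call, "rim-")
  expect_equal(classify_rim(mk(0, 0), "phase")$call, "rim-")
  expect_equal(classify_rim(mk(4, 0.8), "qsm")$call, "rim+")
  expect_equal(classify_rim(mk(4, 0.8), "phase")$call, "rim-")   # wrong sign
  expect_equal(classify_rim(mk(-4, 0.8), "phase")$call, "rim+")
  expect_equal(classify_rim(mk(4, 0.1), "qsm")$call, "rim-")     # coverage gate
  # thresholds are tunable
  expect_equal(classify_rim(mk(1.7, 0.8), "qsm", z_threshold = 1.5)$call, "rim+")
})

test_that("raising the annulus cannot revoke a QSM rim-positive call", {
  fx <- make_fixture(annulus_delta = 3)
  sc1 <- rim_score(fx$img, fx$mask, fx$bg)
  img2 <- fx$img
  ann3d <- qsmrim:::dilate_disc2d
  # add a constant to every boundary voxel (reconstruct the annulus in 3D)
  n <- dim(fx$img)[1]; cx <- (n + 1) / 2
  ix <- slice.index(fx$img, 1) - cx; iy <- slice.index(fx$img, 2) - cx
  iz <- slice.index(fx$img, 3) - cx
  ann <- sqrt(ix^2 + iy^2) > 8 & sqrt(ix^2 + iy^2) <= 10 & abs(iz) <= 3
  img2[ann] <- img2[ann] + 2
  sc2 <- rim_score(img2, fx$mask, fx$bg)
  expect_gt(sc2$z_contrast, sc1$z_contrast)
  c1 <- classify_rim(sc1, "qsm")$call
  c2 <- classify_rim(sc2, "qsm")$call
  expect_false(c1 == "rim+" && c2 == "rim-")
})

test_that("rim scores are stable under a quarter-turn of the slice plane", {
  fx <- make_fixture(annulus_delta = 5, half_only = TRUE)
  rot <- function(a) aperm(a[dim(a)[1]:1, , , drop = FALSE], c(2, 1, 3))
  s1 <- rim_score(fx$img, fx$mask, fx$bg)
  s2 <- rim_score(rot(fx$img), rot(fx$mask), rot(fx$bg))
  expect_equal(s1$z_contrast, s2$z_contrast, tolerance = 1e-6)
  expect_lte(abs(s1$angular_coverage - s2$angular_coverage), 1 / 12 + 1e-9)
})

test_that("edge-band scoring reads the rim tissue inside the lesion boundary", {
  # lesion mask covering core + rim; rim occupies the outer 2-voxel shell
  n <- 48
  img <- array(rnorm(n^3, 0, 0.005), rep(n, 3))
  cx <- (n + 1) / 2
  ix <- slice.index(img, 1) - cx; iy <- slice.index(img, 2) - cx
  iz <- slice.index(img, 3) - cx
  r2d <- sqrt(ix^2 + iy^2)
  mask <- r2d <= 10 & abs(iz) <= 4
  img[r2d <= 8 & abs(iz) <= 4] <- 0.05                      # demyelinated core
  img[r2d > 8 & r2d <= 10 & abs(iz) <= 4] <- 0.15           # iron rim
  bg <- r2d > 16 & r2d <= 22
  sc <- rim_score(img, mask, bg, band = "edge")
  expect_gt(sc$z_contrast, 2)
  expect_equal(sc$angular_coverage, 1)
  expect_equal(classify_rim(sc, "qsm")$call, "rim+")
  # without the rim the edge band matches the core: no call
  img2 <- img; img2[r2d > 8 & r2d <= 10 & abs(iz) <= 4] <- 0.05
  sc2 <- rim_score(img2, mask, bg, band = "edge")
  expect_lt(abs(sc2$z_contrast), 1)
})
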