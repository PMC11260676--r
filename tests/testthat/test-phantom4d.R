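test_that("reference anatomy rasterizes a water body with the target", {
  cfg <- phantom_config()
  anat <- build_reference_anatomy(cfg)
  expect_s3_class(anat$density, "volume_grid")
  expect_true(all(anat$density$values %in% c(0, 1)))
  # sphere target radius 10 mm on a 2 mm grid: volume within 5% of 4.19 cc
  tmask <- rasterize_primitive(cfg$target, anat$density)
  expect_equal(volume_cc(tmask), 4 / 3 * pi * 10^3 / 1000, tolerance = 0.05)
  # degenerate config: no OARs is valid
  cfg0 <- phantom_config(oars = list())
  expect_length(build_reference_anatomy(cfg0)$structures, 1L)
})

test_that("structures breaking the body or motion-core bounds are rejected", {
  ctr <- c(56, 56, 56)
  expect_error(
    phantom_config(target = structure_primitive("CTV", "sphere", "target",
                                                ctr, radius = 60)),
    "outside the body")
  expect_error(
    phantom_config(oars = list(
      structure_primitive("O", "sphere", "oar", ctr + c(0, -40, 0),
                          radius = 8))),
    "motion core")
})

test_that("analytic displacement is periodic, zero at phase 0, symmetric", {
  m <- motion_model("respiratory", center = c(0, 0, 0))
  pt <- c(1, 2, 3)
  expect_equal(analytic_displacement(m, pt, 0), matrix(0, 1, 3))
  # (1 - cos(pi)) / 2 = 1: full amplitude at mid-cycle inside the core
  expect_equal(as.vector(analytic_displacement(m, pt, 0.5)), c(0, 2, 8))
  expect_equal(analytic_displacement(m, pt, 0.25),
               analytic_displacement(m, pt, 0.75))
  for (phi in c(0.1, 0.3, 0.62))
    expect_equal(analytic_displacement(m, pt, phi),
                 analytic_displacement(m, pt, phi + 1))
  # envelope tapers to zero beyond r_outer
  far <- c(0, 0, m$r_outer + 5)
  expect_equal(as.vector(analytic_displacement(m, far, 0.5)), c(0, 0, 0))
})

test_that("cardiac displacement is radial about the cardiac centre", {
  m <- motion_model("cardiac", center = c(0, 0, 0))
  # point at the reference radius moves by the full amplitude at mid-cycle
  u <- as.vector(analytic_displacement(m, c(m$r0, 0, 0), 0.5))
  expect_equal(u, c(2.5, 0, 0))
  # displacement is parallel to the radial direction
  p <- c(6, 8, 0)
  u <- as.vector(analytic_displacement(m, p, 0.3))
  expect_equal(u[1] / p[1], u[2] / p[2])
  expect_equal(u[3], 0)
})

test_that("sampled DVFs respect the amplitude bound and reference identity", {
  g <- water_grid(16, spacing = 4)
  m <- motion_model("respiratory", center = c(30, 30, 30),
                    r_core = 12, r_outer = 25)
  expect_true(all(sample_dvf(m, g, 0)$vectors == 0))
  m0 <- motion_model("respiratory", amplitude_mm = c(0, 0, 0),
                     center = c(30, 30, 30), r_core = 12, r_outer = 25)
  for (k in c(1, 5, 9))
    expect_true(all(sample_dvf(m0, g, k)$vectors == 0))
  dvf <- sample_dvf(m, g, 5)
  mag <- sqrt(rowSums(matrix(dvf$vectors, ncol = 3)^2))
  expect_lte(max(mag), sqrt(sum(m$amplitude_mm^2)) + 1e-12)
  expect_error(sample_dvf(m, g, 10), "out of range")
})

test_that("phase set has 10 phases with exact translated target masks", {
  cfg <- small_config(amp_si = 6)
  ps <- generate_phase_set(cfg, "respiratory")
  expect_length(ps$densities, 10L)
  expect_length(ps$dvfs, 10L)
  expect_length(ps$masks, 10L)
  ref <- ps$masks[[1]]$CTV
  # phase 5 (mid-cycle): target centroid shifted by the full SI amplitude
  c0 <- mask_centroid(ref)
  c5 <- mask_centroid(ps$masks[[6]]$CTV)
  expect_equal(c5 - c0, c(0, 0, 6), tolerance = 0.2)
})

test_that("rigid translation conserves the target voxel count to 2%", {
  # a 10-mm target (5 voxels) keeps its rasterized volume stable across the
  # sub-voxel phase shifts; smaller targets are below this guarantee
  ps <- generate_phase_set(phantom_config(), "respiratory")
  n0 <- sum(ps$masks[[1]]$CTV$values)
  for (k in 2:10)
    expect_lte(abs(sum(ps$masks[[k]]$CTV$values) - n0) / n0, 0.02)
})

test_that("zero motion degenerates every phase to the reference", {
  cfg <- small_config(amp_si = 0, amp_resp = c(0, 0, 0))
  ps <- generate_phase_set(cfg, "respiratory")
  for (k in 2:10) {
    expect_identical(ps$masks[[k]]$CTV$values, ps$masks[[1]]$CTV$values)
    expect_true(all(ps$dvfs[[k]]$vectors == 0))
    expect_identical(ps$densities[[k]]$values, ps$densities[[1]]$values)
  }
})

test_that("AIP is the voxelwise mean of the phase densities", {
  cfg <- small_config(amp_si = 0, amp_resp = c(0, 0, 0))
  ps <- generate_phase_set(cfg, "respiratory")
  aip <- make_aip(ps)
  expect_equal(aip$values, ps$densities[[1]]$values)
  # two-value toy: 5 phases at 0 and 5 at 1 average to 0.5
  g0 <- water_grid(4, value = 0); g1 <- water_grid(4, value = 1)
  toy <- list(densities = c(rep(list(g0), 5), rep(list(g1), 5)))
  expect_true(all(make_aip(toy)$values == 0.5))
  # mismatched frames are rejected
  bad <- list(densities = list(g1, water_grid(5)))
  expect_error(make_aip(bad), "frame")
})
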