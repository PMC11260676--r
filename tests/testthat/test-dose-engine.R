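test_that("range-energy model matches its power law and inverts", {
  beam <- beam_model()
  expect_equal(range_from_energy(100, beam), 76.282107, tolerance = 1e-6)
  expect_gt(range_from_energy(230, beam), range_from_energy(70, beam))
  for (e in seq(70, 230, by = 10))
    expect_equal(energy_from_range(range_from_energy(e, beam), beam), e,
                 tolerance = 1e-6)
  expect_error(range_from_energy(60, beam), "energy outside")
  expect_error(range_from_energy(240, beam), "energy outside")
})

test_that("lateral sigma hits the machine anchors and decreases in energy", {
  beam <- beam_model()
  expect_identical(sigma_at_energy(70, beam), 7.2)
  expect_identical(sigma_at_energy(230, beam), 2.6)
  expect_equal(sigma_at_energy(150, beam), 4.9)
  e <- seq(70, 230, by = 5)
  expect_true(all(diff(sigma_at_energy(e, beam)) < 0))
})

test_that("Bragg curve peaks at the range with a sharp distal falloff", {
  beam <- beam_model()
  for (e in c(70, 120, 180, 230)) {
    r <- range_from_energy(e, beam)
    d <- seq(0, r + 20, by = 0.05)
    idd <- bragg_idd(d, e, beam)
    expect_true(all(idd >= 0))
    peak <- max(idd)
    expect_lte(abs(d[which.max(idd)] - r), 0.025)
    expect_lt(idd[1], peak)                      # entrance below the peak
    expect_lt(bragg_idd(r + 10, e, beam), 0.01 * peak)
    sp <- bragg_peak_sigma(e, beam)
    expect_identical(bragg_idd(r + 3 * sp + 0.1, e, beam), 0)
  }
})

test_that("radiological depth integrates density along the ray", {
  water <- water_grid(40, spacing = 2)   # 80 mm cube of water
  entry <- c(1, 40, 40)
  expect_equal(radiological_depth(water, entry, c(1, 0, 0), c(51, 40, 40)),
               50, tolerance = 0.5)
  expect_equal(radiological_depth(water, entry, c(1, 0, 0), entry), 0)
  expect_error(
    radiological_depth(water, entry, c(1, 0, 0), c(-10, 40, 40)),
    "behind")
  # 20-mm slab of density 0.3 reduces the WEPL by 14 mm
  slab <- water
  ax <- grid_axes(slab)
  slab$values[ax$x >= 20 & ax$x < 40, , ] <- 0.3
  full <- radiological_depth(slab, entry, c(1, 0, 0), c(61, 40, 40))
  expect_equal(full, 60 - 14, tolerance = 0.7)
})

test_that("spot dose is linear in MU with an exact lateral Gaussian", {
  # constant sigma = 4 mm (flat anchors, no depth broadening) makes the
  # lateral ratio at a 4-mm offset exactly exp(-1/2)
  beam <- beam_model(sigma_anchor_lo = c(70, 4.000001),
                     sigma_anchor_hi = c(230, 4), sigma_depth_k = 0)
  water <- water_grid(30)
  iso <- c(28, 28, 28)   # a voxel centre, so an exactly on-axis voxel exists
  d1 <- spot_dose(list(x = 0, y = 0, mu = 1), 0, 120, water, water, beam,
                  iso = iso)
  d2 <- spot_dose(list(x = 0, y = 0, mu = 2), 0, 120, water, water, beam,
                  iso = iso)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  expect_true(all(d1$values >= 0))
  # hottest voxel is on-axis; 2 voxels away in z is a 4 mm = 1 sigma offset
  m <- arrayInd(which.max(d1$values), dim(d1$values))
  ratio <- d1$values[m[1], m[2], m[3] + 2] / d1$values[m[1], m[2], m[3]]
  expect_equal(ratio, exp(-0.5), tolerance = 1e-6)
  # beyond the lateral cutoff the contribution vanishes
  expect_identical(d1$values[m[1], m[2], min(m[3] + 15, 30)], 0)
})

test_that("plan dose is additive and order-independent over spots", {
  water <- water_grid(24)
  beam <- beam_small()
  mk <- function(spots) {
    structure(list(fields = list(list(gantry_angle = 90,
                                      layers = list(list(energy = 80,
                                                         spots = spots)))),
                   prescription = prescription(), normalization_factor = 1,
                   iso = c(23, 23, 23)),
              class = "pbs_plan")
  }
  s1 <- data.frame(x = c(-5, 0), y = c(0, 3), mu = c(1, 2))
  s2 <- data.frame(x = 5, y = -2, mu = 0.5)
  both <- rbind(s1, s2)
  d_all <- plan_dose(mk(both), water, water, beam)
  d_sum <- plan_dose(mk(s1), water, water, beam)$values +
    plan_dose(mk(s2), water, water, beam)$values
  expect_equal(d_all$values, d_sum, tolerance = 1e-12)
  d_perm <- plan_dose(mk(both[c(3, 1, 2), ]), water, water, beam)
  expect_equal(d_perm$values, d_all$values, tolerance = 1e-12)
  # normalization factor scales the dose field
  p2 <- mk(both); p2$normalization_factor <- 1.7
  expect_equal(plan_dose(p2, water, water, beam)$values,
               1.7 * d_all$values, tolerance = 1e-12)
})

test_that("single-spot depth-dose peaks near the model range in water", {
  water <- water_grid(40)   # 80 mm cube
  beam <- beam_small()
  iso <- c(39, 39, 39)
  e <- energy_from_range(50, beam)   # peak 50 mm into the cube
  d <- spot_dose(list(x = 0, y = 0, mu = 1), 90, e, water, water, beam,
                 iso = iso)
  # gantry 90: beam travels along +x from the x = 0 face
  prof <- apply(d$values, 1, max)
  peak_x <- grid_axes(water)$x[which.max(prof)]
  expect_lte(abs(peak_x - 50), 2.5)
})
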