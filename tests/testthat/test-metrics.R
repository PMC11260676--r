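test_that("DVH curve is a monotone survival function of the voxel doses", {
  toy <- toy_dose_mask(dose_in = 25)
  c1 <- cumulative_dvh(toy$dose, toy$mask)
  expect_equal(c1$volume[1], 1)
  expect_true(all(c1$volume[c1$dose <= 25] == 1))
  expect_true(all(c1$volume[c1$dose > 25] == 0))
  set.seed(9)
  for (i in 1:20) {
    dm <- make_dose_mask(runif(50, 0, 30))
    cv <- cumulative_dvh(dm$dose, dm$mask)
    expect_true(all(diff(cv$volume) <= 0))
  }
  expect_error(cumulative_dvh(toy$dose, make_dose_mask(1)$mask), "frame")
})

test_that("Dx and Vx follow the continuous DVH convention", {
  dm <- make_dose_mask(c(20, 24, 25, 26))
  expect_equal(dose_at_volume(dm$dose, dm$mask, 50), 25)
  expect_equal(dose_at_volume(dm$dose, dm$mask, 100), 20)   # D100 = Dmin
  expect_equal(dose_at_volume(dm$dose, dm$mask, 0.001), 26) # -> Dmax
  expect_equal(volume_at_dose(dm$dose, dm$mask, 25), 50)
  expect_equal(volume_at_dose(dm$dose, dm$mask, 25, interpolate = FALSE), 50)
  expect_equal(volume_at_dose(dm$dose, dm$mask, 0), 100)
  # cc variant is the relative volume times the structure volume
  expect_equal(volume_at_dose(dm$dose, dm$mask, 25, unit = "cc"),
               0.5 * 4 * 8 / 1000)
  # uniform dose: all Dx equal, V at that dose = 100%
  un <- make_dose_mask(rep(25, 10))
  for (x in c(1, 50, 95, 100))
    expect_equal(dose_at_volume(un$dose, un$mask, x), 25)
  expect_equal(volume_at_dose(un$dose, un$mask, 25), 100)
})

test_that("Dx matches an independent sort oracle and scales with dose", {
  set.seed(31)
  for (i in 1:30) {
    vals <- round(runif(40, 0, 30), 2)
    dm <- make_dose_mask(vals)
    for (x in c(2, 50, 95, 98)) {
      expect_equal(dose_at_volume(dm$dose, dm$mask, x), oracle_dx(vals, x),
                   tolerance = 1e-10)
    }
    # D-ordering invariant
    dx <- vapply(c(99, 98, 95, 50, 2, 1), function(x)
      dose_at_volume(dm$dose, dm$mask, x), numeric(1))
    expect_true(all(diff(dx) >= -1e-12))
    # scale equivariance
    dm2 <- dm; dm2$dose$values <- 3 * dm$dose$values
    expect_equal(dose_at_volume(dm2$dose, dm2$mask, 50),
                 3 * dose_at_volume(dm$dose, dm$mask, 50))
    expect_equal(volume_at_dose(dm2$dose, dm2$mask, 3 * 10),
                 volume_at_dose(dm$dose, dm$mask, 10))
  }
})

test_that("conformity index follows the Paddick form", {
  toy <- toy_dose_mask(dose_in = 25)
  expect_equal(conformity_index(toy$dose, toy$mask, 25), 1)
  # worked case: overlap 90, target 100, isodose 120 -> 0.675
  g <- water_grid(10)
  itv <- g; itv$values[] <- 0; itv$values[1:100] <- 1
  dose <- g; dose$values[] <- 0
  dose$values[11:100] <- 25       # 90 covered target voxels
  dose$values[101:130] <- 25      # 30 hot voxels outside
  expect_equal(conformity_index(dose, itv, 25), 90^2 / (100 * 120))
  cold <- g; cold$values[] <- 0
  expect_true(is.na(conformity_index(cold, itv, 25)))
  set.seed(4)
  for (i in 1:20) {
    dm <- make_dose_mask(runif(60, 0, 30))
    ci <- conformity_index(dm$dose, dm$mask, 20)
    if (!is.na(ci)) expect_lte(ci, 1)
  }
})

test_that("homogeneity index is (D2 - D98) / Dmean", {
  toy <- toy_dose_mask(dose_in = 25)
  expect_equal(homogeneity_index(toy$dose, toy$mask), 0)
  # D2 = 26, D98 = 24, Dmean = 25 -> 0.08
  vals <- c(rep(26, 2), rep(2384 / 95, 95), 24, rep(20, 2))
  dm <- make_dose_mask(vals)
  expect_equal(dose_at_volume(dm$dose, dm$mask, 2), 26)
  expect_equal(dose_at_volume(dm$dose, dm$mask, 98), 24)
  expect_equal(homogeneity_index(dm$dose, dm$mask), 0.08, tolerance = 1e-10)
  set.seed(5)
  for (i in 1:20) {
    dm <- make_dose_mask(runif(50, 1, 30))
    expect_gte(homogeneity_index(dm$dose, dm$mask), 0)
  }
})

test_that("gradient indices are nested isodose-volume ratios", {
  toy <- toy_dose_mask(dose_in = 25)
  gi <- gradient_indexes(toy$dose, 25)
  expect_equal(unname(gi), c(1, 1, 1))
  # worked case: V12.5Gy = 500 cc, V25Gy = 125 cc -> GI = 4
  g <- volume_grid(array(0, dim = c(50, 50, 32)), spacing = c(2, 2, 2))
  g$values[seq_len(15625)] <- 25
  g$values[15625 + seq_len(46875)] <- 13
  expect_equal(volume_at_dose(g, NULL, 25, unit = "cc"), 125)
  expect_equal(volume_at_dose(g, NULL, 12.5, unit = "cc"), 500)
  expect_equal(unname(gradient_indexes(g, 25)["GI"]), 4.0)
  # radial falloff: GI_low >= GI >= GI_high >= 1
  rg <- water_grid(24)
  ax <- grid_axes(rg)
  ctr <- c(23, 23, 23)
  r2 <- outer(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, "+"),
              (ax$z - ctr[3])^2, "+")
  rad <- rg; rad$values <- 28 * exp(-r2 / (2 * 8^2))
  gir <- gradient_indexes(rad, 25)
  expect_gte(gir["GI_low"], gir["GI"])
  expect_gte(gir["GI"], gir["GI_high"])
  expect_gte(gir["GI_high"], 1)
  zero <- rg; zero$values[] <- 0
  expect_true(all(is.na(gradient_indexes(zero, 25))))
})

test_that("metric report carries the full target panel with sane ordering", {
  subj <- small_subject("respiratory")
  dose <- static_3d(subj$plan, subj$aip, subj$beam)
  rep <- metrics_report(dose, subj$structures, target = "ITV")
  expect_setequal(rep$metric[rep$structure == "ITV"],
                  c("V25", "D99", "D98", "D95", "D50", "D2", "D1",
                    "Dmax", "Dmin", "Dmean", "CI", "HI", "GI", "GI_high",
                    "GI_low"))
  v <- function(m) rep$value[rep$metric == m & rep$structure == "ITV"]
  expect_true(v("D99") <= v("D98") && v("D98") <= v("D95") &&
              v("D95") <= v("D50") && v("D50") <= v("D2") &&
              v("D2") <= v("D1") && v("D1") <= v("Dmax"))
  expect_true(v("Dmin") <= v("Dmean") && v("Dmean") <= v("Dmax"))
  expect_true(v("CI") <= 1 && v("CI") >= 0)
  # zero dose: all D metrics 0, CI/HI/GI flagged undefined
  zdose <- dose; zdose$values[] <- 0
  zrep <- metrics_report(zdose, subj$structures, target = "ITV")
  zv <- function(m) zrep$value[zrep$metric == m & zrep$structure == "ITV"]
  for (m in c("D99", "D95", "D50", "Dmax", "Dmean")) expect_equal(zv(m), 0)
  for (m in c("CI", "HI", "GI", "GI_high", "GI_low"))
    expect_true(is.na(zv(m)))
  # OAR rows appear when requested
  rep2 <- metrics_report(dose, subj$structures, target = "ITV",
                         oars = "CTV", oar_vx_gy = 10)
  expect_true(all(c("D50", "D5", "Dmax", "V10_cc") %in%
                  rep2$metric[rep2$structure == "CTV"]))
})
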