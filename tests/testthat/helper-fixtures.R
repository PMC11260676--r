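# Shared fixtures, all built in code. Expensive objects are memoized per
# test run so several test files can reuse one computation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# uniform water cube, n^3 voxels at `spacing` mm
water_grid <- function(n = 20, spacing = 2, value = 1) {
  volume_grid(array(value, dim = c(n, n, n)), spacing = rep(spacing, 3))
}

# beam model with an extended energy range so small desk-scale phantoms
# (shallow targets) are plannable in tests
beam_small <- function(...) beam_model(energy_range_mev = c(30, 230), ...)

# small moving phantom: 30^3 grid (60 mm), 26-mm water body, 6-mm target,
# SI translation `amp_si` mm; single structure keeps dose tests fast
small_config <- function(amp_si = 6, amp_resp = c(0, 0, amp_si)) {
  shape <- c(31, 31, 31); spacing <- c(2, 2, 2)
  ctr <- (shape - 1) / 2 * spacing
  phantom_config(
    grid_shape = shape, spacing = spacing,
    body = structure_primitive("BODY", "sphere", "body", ctr, radius = 26),
    target = structure_primitive("CTV", "sphere", "target", ctr, radius = 6),
    oars = list(),
    respiratory = motion_model("respiratory", amplitude_mm = amp_resp,
                               center = ctr, r_core = 13, r_outer = 25),
    cardiac = motion_model("cardiac", amplitude_mm = 2.5,
                           center = ctr + c(0, -4, 0), r0 = 10,
                           r_core = 13, r_outer = 25),
    seed = 1L)
}

# planned + normalized small subject for one motion mode (memoized)
small_subject <- function(mode = "respiratory", amp_si = 6) {
  fixture(paste0("small_subject_", mode, "_", amp_si), function() {
    cfg <- small_config(amp_si = amp_si)
    beam <- beam_small()
    ps <- generate_phase_set(cfg, mode)
    aip <- make_aip(ps)
    ss <- build_structure_set(ps)
    plan <- make_plan(ss$masks$ITV, aip, beam, gantry_angles = c(0, 180),
                      spot_spacing = 5, layer_step = 5)
    plan <- optimize_weights(plan, aip, ss$masks$ITV, beam, n_iter = 15)
    raw <- static_3d(plan, aip, beam)
    plan$normalization_factor <-
      normalize_to_prescription(raw, ss$masks$ITV)$scale
    list(config = cfg, beam = beam, phase_set = ps, aip = aip,
         structures = ss, plan = plan)
  })
}

# default-phantom planned static run (the acceptance t1/t2 construction)
default_static_run <- function() {
  fixture("default_static_run", function() {
    cfg <- phantom_config()
    ps <- generate_phase_set(cfg, "respiratory")
    aip <- make_aip(ps)
    ss <- build_structure_set(ps)
    beam <- beam_model()
    plan <- make_plan(ss$masks$ITV, aip, beam)
    plan <- optimize_weights(plan, aip, ss$masks$ITV, beam)
    raw <- static_3d(plan, aip, beam)
    nr <- normalize_to_prescription(raw, ss$masks$ITV)
    plan$normalization_factor <- nr$scale
    list(config = cfg, beam = beam, phase_set = ps, aip = aip,
         structures = ss, plan = plan, dose = nr$dose)
  })
}

# random abstract plan (for timing / partition tests; not meant for dosimetry)
random_plan <- function(seed, n_spots_total = 60, n_fields = 2,
                        xy_range = 12) {
  set.seed(seed)
  layers_per_field <- sample(2:3, n_fields, replace = TRUE)
  n_layers <- sum(layers_per_field)
  counts <- as.vector(stats::rmultinom(1, n_spots_total - n_layers,
                                       rep(1, n_layers))) + 1L
  li <- 0L
  fields <- lapply(seq_len(n_fields), function(fi) {
    energies <- sort(stats::runif(layers_per_field[fi], 75, 220),
                     decreasing = TRUE)
    layers <- lapply(energies, function(e) {
      li <<- li + 1L
      n <- counts[li]
      list(energy = e,
           spots = data.frame(x = stats::runif(n, -xy_range, xy_range),
                              y = stats::runif(n, -xy_range, xy_range),
                              mu = stats::runif(n, 0.02, 4)))
    })
    list(gantry_angle = stats::runif(1, 0, 360), layers = layers)
  })
  structure(list(fields = fields, prescription = prescription(),
                 normalization_factor = 1, iso = c(0, 0, 0)),
            class = "pbs_plan")
}

# independent event-by-event clock replay: vectorized per layer, written
# without reusing the package's timeline loop
oracle_spot_phases <- function(plan, beam, period_s, n_phases,
                               interfield_gap_s = beam$interfield_gap_s) {
  t <- 0
  phases <- integer(0)
  for (fi in seq_along(plan$fields)) {
    if (fi > 1) t <- t + interfield_gap_s
    fld <- plan$fields[[fi]]
    for (li in seq_along(fld$layers)) {
      if (li > 1) t <- t + beam$layer_switch_s
      sp <- fld$layers[[li]]$spots
      n <- nrow(sp)
      if (n == 0) next
      drill <- sp$mu / beam$mu_rate
      hop <- c(0, sqrt(diff(sp$x)^2 + diff(sp$y)^2) / beam$scan_speed)
      starts <- t + cumsum(hop) + cumsum(c(0, drill[-n]))
      mids <- starts + drill / 2
      cyc <- mids / period_s
      frac <- cyc - floor(cyc)
      phases <- c(phases, pmin(floor(frac * n_phases), n_phases - 1))
      t <- starts[n] + drill[n]
    }
  }
  as.integer(phases)
}

# uniform-dose-in-mask toy on a water grid
toy_dose_mask <- function(n = 12, dose_in = 25, radius_vox = 4) {
  g <- water_grid(n)
  ctr <- (n - 1) / 2 * 2
  mask <- rasterize_primitive(
    structure_primitive("T", "sphere", "target", rep(ctr, 3),
                        radius = radius_vox * 2), g)
  dose <- g
  dose$values <- mask$values * dose_in
  list(dose = dose, mask = mask)
}

# independent sort-based oracle for Dx: explicit loop over the descending
# sorted doses with hand-written linear interpolation (no shared code with
# the implementation)
oracle_dx <- function(doses, x) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  v <- x / 100
  us <- unique(s)
  fs <- vapply(us, function(u) sum(s >= u) / n, numeric(1))
  if (v <= fs[1]) return(us[1])
  for (i in seq_len(length(us) - 1)) {
    if (v <= fs[i + 1]) {
      return(us[i] + (v - fs[i]) / (fs[i + 1] - fs[i]) * (us[i + 1] - us[i]))
    }
  }
  us[length(us)]
}

make_dose_mask <- function(values) {
  n <- length(values)
  side <- ceiling(n^(1 / 3))
  g <- water_grid(side)
  dose <- g; dose$values[] <- 0; dose$values[seq_len(n)] <- values
  mask <- g; mask$values[] <- 0; mask$values[seq_len(n)] <- 1
  list(dose = dose, mask = mask)
}

mask_centroid <- function(mask) {
  ax <- grid_axes(mask)
  d <- dim(mask$values)
  idx <- which(mask$values > 0)
  i <- (idx - 1) %% d[1] + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  c(mean(ax$x[i]), mean(ax$y[j]), mean(ax$z[k]))
}
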