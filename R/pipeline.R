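#' Jittered phantom configuration for one synthetic subject
#'
#' Derives a per-subject phantom from the default geometry by seeded jitter
#' of the target position (axial, +/- 3 mm), target radius (9-11 mm) and
#' OAR offsets, emulating anatomical variation across a synthetic cohort.
#' All randomness is controlled by `seed`.
#'
#' @param seed integer subject seed.
#' @param heterogeneity passed to [phantom_config()].
#' @return a [phantom_config()].
#' @export
subject_phantom_config <- function(seed = 1L, heterogeneity = FALSE) {
  set.seed(seed)
  shape <- c(57, 57, 57); spacing <- c(2, 2, 2); origin <- c(0, 0, 0)
  ctr <- origin + (shape - 1) / 2 * spacing
  tctr <- ctr + c(stats::runif(1, -3, 3), stats::runif(1, -3, 3), 0)
  trad <- stats::runif(1, 9, 11)
  target <- structure_primitive("CTV", "sphere", "target", tctr,
                                radius = trad)
  th <- stats::runif(1, 0, 2 * pi)
  oars <- list(
    structure_primitive("OAR_A", "sphere", "oar",
                        tctr + c(0, -(trad + stats::runif(1, 8, 10)), 0),
                        radius = 8),
    structure_primitive("OAR_B", "sphere", "oar",
                        tctr + (trad + stats::runif(1, 5, 7)) *
                          c(cos(th), -abs(sin(th)) / 2, 0),
                        radius = 5))
  phantom_config(grid_shape = shape, spacing = spacing, origin = origin,
                 target = target, oars = oars,
                 respiratory = motion_model("respiratory", center = tctr),
                 cardiac = motion_model("cardiac",
                                        center = tctr + c(0, -12, 0)),
                 heterogeneity = heterogeneity, seed = seed)
}

# wide one-row data.frame of target metrics from a metrics_report
.report_wide <- function(report, structure_name) {
  r <- report[report$structure == structure_name, ]
  out <- as.data.frame(as.list(stats::setNames(r$value, r$metric)))
  out
}

#' End-to-end run for one subject and one motion mode
#'
#' Phantom generation, ITV/IRV contouring, plan construction and weight
#' optimization on the AIP, prescription normalization, delivery-timeline
#' simulation, and reconstruction of the 3D static, 4D accumulated and 4D
#' dynamic doses with their metric reports (static metrics on the ITV, 4D
#' metrics on the CTV, mirroring the evaluation frames of the workflow).
#'
#' @param config a [phantom_config()].
#' @param mode "respiratory" or "cardiac".
#' @param beam a [beam_model()].
#' @param rx a [prescription()].
#' @param n_iter optimizer iterations.
#' @param plan optional pre-built, pre-normalized plan to reuse.
#' @return list with `phase_set`, `aip`, `structures`, `plan`, `timeline`,
#'   `doses` (a `dose4d_result`), and `reports` (named list of
#'   `metrics_report`s: static, accumulated, dynamic).
#' @export
run_subject <- function(config, mode = c("respiratory", "cardiac"),
                        beam = beam_model(), rx = prescription(),
                        n_iter = 40, plan = NULL) {
  mode <- match.arg(mode)
  ps <- generate_phase_set(config, mode)
  aip <- make_aip(ps)
  ss <- build_structure_set(ps)
  itv <- ss$masks$ITV
  if (is.null(plan)) {
    plan <- make_plan(itv, aip, beam, rx)
    plan <- optimize_weights(plan, aip, itv, beam, n_iter = n_iter)
    validate_plan(plan)
    raw <- static_3d(plan, aip, beam)
    plan$normalization_factor <- normalize_to_prescription(raw, itv, rx)$scale
  }
  timeline <- simulate_timeline(plan, beam)
  doses <- reconstruct_doses(plan, ps, aip, beam, timeline)
  oar_names <- names(ss$roles)[ss$roles == "OAR"]
  reports <- list(
    static = metrics_report(doses$static3d, ss, rx, target = "ITV",
                            oars = paste0("IRV_", oar_names)),
    accumulated = metrics_report(doses$accumulated4d, ss, rx, target = "CTV",
                                 oars = oar_names),
    dynamic = metrics_report(doses$dynamic4d, ss, rx, target = "CTV",
                             oars = oar_names))
  list(phase_set = ps, aip = aip, structures = ss, plan = plan,
       timeline = timeline, doses = doses, reports = reports)
}

#' Cohort simulation across seeds
#'
#' Runs [run_subject()] for `n` seed-varied synthetic subjects in one or
#' both motion modes and assembles per-arm target metric tables plus the
#' paired comparison tables (3D static vs 4D dynamic, and 4D accumulated vs
#' 4D dynamic for interplay).
#'
#' @param n number of subjects.
#' @param seed base seed; subject s uses `seed * 1000 + s`.
#' @param modes motion modes to run.
#' @param beam,rx,n_iter passed to [run_subject()].
#' @return list per mode, each with `metrics` (list of data.frames: static,
#'   accumulated, dynamic; one row per subject) and `comparisons` (list of
#'   [cohort_compare()] tables: static_vs_dynamic, accumulated_vs_dynamic).
#' @export
run_cohort <- function(n = 12, seed = 1L,
                       modes = c("respiratory", "cardiac"),
                       beam = beam_model(), rx = prescription(),
                       n_iter = 40) {
  out <- list()
  for (mode in modes) {
    st <- list(); ac <- list(); dy <- list()
    for (s in seq_len(n)) {
      cfg <- subject_phantom_config(seed * 1000L + s)
      res <- run_subject(cfg, mode, beam, rx, n_iter = n_iter)
      st[[s]] <- .report_wide(res$reports$static, "ITV")
      ac[[s]] <- .report_wide(res$reports$accumulated, "CTV")
      dy[[s]] <- .report_wide(res$reports$dynamic, "CTV")
    }
    metrics <- list(static = do.call(rbind, st),
                    accumulated = do.call(rbind, ac),
                    dynamic = do.call(rbind, dy))
    comparisons <- if (n >= 2) list(
      static_vs_dynamic = cohort_compare(metrics$static, metrics$dynamic,
                                         "3D static", "4D dynamic"),
      accumulated_vs_dynamic = cohort_compare(metrics$accumulated,
                                              metrics$dynamic,
                                              "4D accumulated", "4D dynamic"))
    else list()
    out[[mode]] <- list(metrics = metrics, comparisons = comparisons)
  }
  out
}

#' Config-driven pipeline run with file outputs
#'
#' Runs one subject in the requested motion modes and writes the declared
#' artifacts under `outdir`: phantom volumes (NIfTI), the plan (JSON), the
#' timeline with phase assignments (CSV), the three dose volumes per mode
#' (NIfTI), the metric reports (CSV), and a JSON manifest with the seed and
#' parameters. Deterministic for a fixed seed.
#'
#' @param seed subject seed.
#' @param outdir output directory (created if missing).
#' @param modes motion modes.
#' @param beam,rx,n_iter passed to [run_subject()].
#' @return path of the manifest file, invisibly.
#' @export
run_pipeline <- function(seed = 1L, outdir,
                         modes = c("respiratory", "cardiac"),
                         beam = beam_model(), rx = prescription(),
                         n_iter = 40) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- subject_phantom_config(seed)
  written <- character(0)
  wv <- function(vol, name) {
    p <- file.path(outdir, name)
    write_volume(vol, p)
    written <<- c(written, name)
    p
  }
  for (mode in modes) {
    res <- run_subject(cfg, mode, beam, rx, n_iter = n_iter)
    wv(res$aip, paste0(mode, "_aip.nii.gz"))
    wv(res$structures$masks$ITV, paste0(mode, "_itv.nii.gz"))
    wv(res$doses$static3d, paste0(mode, "_dose_static3d.nii.gz"))
    wv(res$doses$accumulated4d, paste0(mode, "_dose_accumulated4d.nii.gz"))
    wv(res$doses$dynamic4d, paste0(mode, "_dose_dynamic4d.nii.gz"))
    plan_to_json(res$plan, file.path(outdir, paste0(mode, "_plan.json")))
    timeline_table(res$timeline,
                   path = file.path(outdir, paste0(mode, "_timeline.csv")))
    for (nm in names(res$reports))
      utils::write.csv(res$reports[[nm]],
                       file.path(outdir, paste0(mode, "_metrics_", nm, ".csv")),
                       row.names = FALSE)
    written <- c(written, paste0(mode, "_plan.json"),
                 paste0(mode, "_timeline.csv"),
                 paste0(mode, "_metrics_", names(res$reports), ".csv"))
  }
  manifest <- list(package = "proton4d",
                   version = as.character(utils::packageVersion("proton4d")),
                   seed = seed, modes = modes,
                   prescription = rx[c("dose_gy", "coverage_percent",
                                       "fractions", "rbe")],
                   timing = beam[c("mu_rate", "scan_speed", "layer_switch_s",
                                   "interfield_gap_s")],
                   files = written)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
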