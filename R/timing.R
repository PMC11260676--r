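#' Simulate the spot-by-spot delivery timeline
#'
#' Advances one continuous clock through the plan in delivery order: spot
#' drilling takes `mu / mu_rate` seconds, moving between consecutive spots
#' of one layer takes distance / `scan_speed`, switching energy layers costs
#' `layer_switch_s`, and consecutive fields are separated by
#' `interfield_gap_s`. The clock starts at 0 at the first spot's start, so
#' delivery commences at the 0% motion phase.
#'
#' @param plan a `pbs_plan` (spots already in serpentine delivery order).
#' @param beam a [beam_model()] carrying the timing constants.
#' @param interfield_gap_s override for the inter-field gap (seconds).
#' @return object of class `spot_timeline`: data.frame `entries` with
#'   columns field, layer, spot, x, y, mu, energy, t_start, t_end; plus
#'   `total_time_s` and per-field start times `field_start_s`.
#' @export
simulate_timeline <- function(plan, beam = beam_model(),
                              interfield_gap_s = beam$interfield_gap_s) {
  t <- 0
  rows <- list()
  field_start <- numeric(length(plan$fields))
  for (fi in seq_along(plan$fields)) {
    if (fi > 1) t <- t + interfield_gap_s
    field_start[fi] <- t
    fld <- plan$fields[[fi]]
    for (li in seq_along(fld$layers)) {
      if (li > 1) t <- t + beam$layer_switch_s
      lay <- fld$layers[[li]]
      sp <- lay$spots
      n <- nrow(sp)
      if (n == 0) next
      t_start <- numeric(n); t_end <- numeric(n)
      for (si in seq_len(n)) {
        if (si > 1) {
          dist <- sqrt((sp$x[si] - sp$x[si - 1])^2 +
                       (sp$y[si] - sp$y[si - 1])^2)
          t <- t + dist / beam$scan_speed
        }
        t_start[si] <- t
        t <- t + sp$mu[si] / beam$mu_rate
        t_end[si] <- t
      }
      rows[[length(rows) + 1L]] <-
        data.frame(field = fi, layer = li, spot = seq_len(n),
                   x = sp$x, y = sp$y, mu = sp$mu, energy = lay$energy,
                   t_start = t_start, t_end = t_end)
    }
  }
  entries <- do.call(rbind, rows)
  structure(list(entries = entries, total_time_s = t,
                 field_start_s = field_start),
            class = "spot_timeline")
}

#' Motion phase index at a time point
#'
#' `floor(((t / period) mod 1) * n_phases)`, i.e. the cycle is divided into
#' `n_phases` equal bins starting at the 0% phase at t = 0.
#'
#' @param t time in seconds (vectorized, >= 0).
#' @param period_s motion period in seconds.
#' @param n_phases number of phases.
#' @return integer phase indices in `[0, n_phases)`.
#' @export
phase_of_time <- function(t, period_s, n_phases) {
  stopifnot(period_s > 0, n_phases >= 1)
  pmin(as.integer(floor(((t / period_s) %% 1) * n_phases)),
       as.integer(n_phases) - 1L)
}

#' Split a plan into per-phase sub-plans
#'
#' Assigns every spot to the motion phase of its drilling-interval midpoint
#' and returns one sub-plan per phase (possibly with empty layers). The spot
#' multiset and the total MU are conserved exactly.
#'
#' @param plan a `pbs_plan`.
#' @param timeline the [simulate_timeline()] result for this plan.
#' @param period_s motion period in seconds.
#' @param n_phases number of phases.
#' @param reset_each_field if `TRUE`, each field's clock is referenced to
#'   its own start (every field commences at the 0% phase); default keeps
#'   one continuous clock for the whole plan.
#' @return list of `n_phases` sub-plans; each is a `pbs_plan` with an extra
#'   `phase_index` element.
#' @export
split_into_subplans <- function(plan, timeline, period_s, n_phases = 10L,
                                reset_each_field = FALSE) {
  e <- timeline$entries
  if (is.null(e) || nrow(e) != n_spots(plan))
    stop("timeline does not cover the plan's spots")
  tmid <- (e$t_start + e$t_end) / 2
  if (reset_each_field) tmid <- tmid - timeline$field_start_s[e$field]
  phase <- phase_of_time(tmid, period_s, n_phases)
  row <- 0L
  # per-spot phase labels, walked in the same order the timeline was built
  subplans <- lapply(seq_len(n_phases) - 1L, function(k) {
    sp <- plan
    sp$phase_index <- k
    sp
  })
  for (fi in seq_along(plan$fields)) {
    for (li in seq_along(plan$fields[[fi]]$layers)) {
      spots <- plan$fields[[fi]]$layers[[li]]$spots
      n <- nrow(spots)
      if (n == 0) next
      ph <- phase[row + seq_len(n)]
      row <- row + n
      for (k in seq_len(n_phases) - 1L) {
        subplans[[k + 1L]]$fields[[fi]]$layers[[li]]$spots <-
          spots[ph == k, , drop = FALSE]
      }
    }
  }
  subplans
}

#' Export a timeline with phase assignments as a data.frame / CSV
#'
#' @param timeline a `spot_timeline`.
#' @param periods named numeric vector of motion periods (seconds) to bin
#'   against (default respiratory 4 s and cardiac 0.8 s).
#' @param n_phases number of phases per cycle.
#' @param path optional CSV output path.
#' @return data.frame with one row per spot and one phase column per period.
#' @export
timeline_table <- function(timeline, periods = c(resp = 4, cardiac = 0.8),
                           n_phases = 10L, path = NULL) {
  e <- timeline$entries
  tmid <- (e$t_start + e$t_end) / 2
  for (nm in names(periods))
    e[[paste0("phase_", nm)]] <- phase_of_time(tmid, periods[[nm]], n_phases)
  if (!is.null(path)) utils::write.csv(e, path, row.names = FALSE)
  e
}
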