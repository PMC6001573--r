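#' Normalise a densitometry band to a housekeeping band
#'
#' @param raw_band raw band intensity.
#' @param housekeeping_band housekeeping (e.g. GAPDH) band intensity (> 0).
#' @return `raw_band / housekeeping_band`.
#' @export
normalize_to_housekeeping <- function(raw_band, housekeeping_band) {
  if (any(!is.finite(housekeeping_band)) || any(housekeeping_band <= 0))
    stop_glia("housekeeping level must be positive", "invalid_spec")
  raw_band / housekeeping_band
}

#' Per-interval degradation and release deltas of a washout time course
#'
#' Between adjacent measured time points, the decrease of the internal
#' level is the material that left the intracellular pool. The supernatant
#' increase over the same interval is the released part, in its own
#' (ELISA) units. When a `calibration` factor is supplied (internal units
#' per supernatant unit), release is converted to internal-equivalent
#' units and subtracted, so `delta_digested` isolates true degradation;
#' without calibration `delta_digested` is the plain internal delta and
#' release is reported separately. Negative deltas (apparent gain under
#' noise) are preserved and flagged, never clipped.
#'
#' @param tc data frame with `time_h`, `internal_level` and optionally
#'   `supernatant_level`, one row per time point in time order.
#' @param calibration optional factor converting supernatant units to
#'   internal units.
#' @return A `degradation_summary` data frame: one row per interval with
#'   `t_start_h`, `t_end_h`, `delta_internal`, `delta_released` (supernatant
#'   units), `delta_released_internal` (internal units; NA without
#'   calibration), `delta_digested`, cumulative columns and a
#'   `negative_delta` flag.
#' @export
degradation_deltas <- function(tc, calibration = NULL) {
  if (!all(c("time_h", "internal_level") %in% names(tc)))
    stop_glia("time course needs 'time_h' and 'internal_level'",
              "invalid_spec")
  if (nrow(tc) < 2L)
    stop_glia("need at least two time points", "invalid_spec")
  if (any(diff(tc$time_h) <= 0))
    stop_glia("time points must be strictly increasing", "invalid_spec")
  ni <- nrow(tc) - 1L
  d_int <- tc$internal_level[-nrow(tc)] - tc$internal_level[-1]
  d_rel <- if ("supernatant_level" %in% names(tc))
    tc$supernatant_level[-1] - tc$supernatant_level[-nrow(tc)]
  else rep(NA_real_, ni)
  d_rel_int <- if (!is.null(calibration)) d_rel * calibration
               else rep(NA_real_, ni)
  d_dig <- if (!is.null(calibration)) d_int - d_rel_int else d_int
  out <- data.frame(interval = seq_len(ni),
                    t_start_h = tc$time_h[-nrow(tc)],
                    t_end_h = tc$time_h[-1],
                    delta_internal = d_int,
                    delta_released = d_rel,
                    delta_released_internal = d_rel_int,
                    delta_digested = d_dig,
                    cumulative_digested = cumsum(d_dig),
                    cumulative_released = cumsum(d_rel),
                    negative_delta = d_dig < 0 |
                      (!is.na(d_rel) & d_rel < 0))
  class(out) <- c("degradation_summary", "data.frame")
  out
}

#' Compare per-interval degradation between two conditions
#'
#' Deltas are computed per replicate and then compared across replicates
#' (never deltas of replicate averages), preserving the within-replicate
#' pairing of the parallel-experiment design.
#'
#' @param treated,control numeric matrices of per-replicate deltas, one
#'   row per interval and one column per replicate (e.g. built by applying
#'   [degradation_deltas()] to each replicate).
#' @param design test passed to [compare_groups()] (default unpaired t).
#' @return Data frame with one row per interval: group means, mean
#'   difference (treated - control) and, when both arms have >= 2
#'   replicates, the test statistic and p value; with a single replicate a
#'   warning is raised and only the descriptive columns are filled.
#' @export
compare_conditions <- function(treated, control, design = "unpaired") {
  treated <- as.matrix(treated); control <- as.matrix(control)
  if (nrow(treated) != nrow(control))
    stop_glia("conditions have different numbers of intervals",
              "invalid_spec")
  can_test <- ncol(treated) >= 2L && ncol(control) >= 2L
  if (!can_test)
    warning("fewer than 2 replicates per condition: descriptive output only")
  out <- do.call(rbind, lapply(seq_len(nrow(treated)), function(i) {
    ti <- treated[i, ]; ci <- control[i, ]
    row <- data.frame(interval = i, mean_treated = mean(ti),
                      mean_control = mean(ci),
                      difference = mean(ti) - mean(ci),
                      statistic = NA_real_, p_value = NA_real_)
    if (can_test) {
      cmp <- compare_groups(list(treated = ti, control = ci),
                            design = design)
      row$statistic <- cmp$statistic
      row$p_value <- cmp$p_value
    }
    row
  }))
  out
}

#' Split a long kinetics table into per-replicate time courses
#'
#' @param df data frame with columns `condition`, `replicate`, `time_h`,
#'   `internal_level` and optionally `supernatant_level`.
#' @return Nested list: per condition, a list of per-replicate data frames
#'   ordered by time.
#' @export
kinetics_by_replicate <- function(df) {
  need <- c("condition", "replicate", "time_h", "internal_level")
  if (!all(need %in% names(df)))
    stop_glia(paste("kinetics table needs columns:",
                    paste(need, collapse = ", ")), "invalid_spec")
  lapply(split(df, df$condition), function(d)
    lapply(split(d, d$replicate), function(r) r[order(r$time_h), ]))
}
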