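#' Mean cell-body speed of a track
#'
#' Mean Euclidean centroid displacement between consecutive frames divided
#' by the frame interval, in um/min. Only consecutive frame pairs (frame
#' difference of 1) contribute.
#'
#' @param track a `cell_track` from [track_cells()].
#' @return Speed in um/min.
#' @export
compute_cell_speed <- function(track) {
  px <- attr(track, "pixel_size_um"); dt <- attr(track, "frame_interval_s")
  if (is.null(px) || is.null(dt))
    stop_glia("track lacks pixel size / frame interval metadata",
              "invalid_track")
  if (nrow(track) < 2L)
    stop_glia("cell speed is undefined for tracks shorter than 2 frames",
              "undefined_metric")
  tr <- track[order(track$frame), ]
  consec <- diff(tr$frame) == 1L
  if (!any(consec))
    stop_glia("no consecutive frame pairs in track", "undefined_metric")
  steps <- sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)[consec] * px
  mean(steps) / (dt / 60)
}

#' Membrane-change statistic dA/p of a track
#'
#' For each consecutive frame pair, `dA = |A(t+1) - A(t)|` in um^2 divided
#' by the mean of the two frames' perimeters in um, giving a length (um)
#' that tracks membrane extension/retraction activity. The absolute value
#' is used so extension and retraction both count.
#'
#' @param track a `cell_track` from [track_cells()].
#' @return A list with `series` (per-pair dA/p, um) and `mean`.
#' @export
compute_membrane_change <- function(track) {
  px <- attr(track, "pixel_size_um")
  if (nrow(track) < 2L)
    stop_glia("dA/p is undefined for tracks shorter than 2 frames",
              "undefined_metric")
  tr <- track[order(track$frame), ]
  consec <- diff(tr$frame) == 1L
  a <- tr$area_px2 * px^2
  p <- tr$perimeter_px * px
  if (any(p <= 0))
    stop_glia("zero perimeter in track", "invalid_shape")
  dap <- (abs(diff(a)) / ((p[-1] + p[-length(p)]) / 2))[consec]
  list(series = dap, mean = mean(dap))
}

#' Morphing speed of a track
#'
#' Number of roundish/polarized state changes per hour of observation.
#' With `debounce = d > 1`, a new state must persist for at least `d`
#' frames before it counts as a transition (runs shorter than `d` are
#' assigned to the preceding accepted state); `d = 1` is the raw count.
#'
#' @param track a `cell_track` with a `state` column.
#' @param debounce minimum persistence in frames.
#' @return A list with `transitions` (integer count) and
#'   `per_hour` (transitions divided by observed duration in hours).
#' @export
compute_morphing_speed <- function(track, debounce = 1L) {
  dt <- attr(track, "frame_interval_s")
  tr <- track[order(track$frame), ]
  states <- tr$state
  if (any(is.na(states)))
    stop_glia("track has unclassified frames", "invalid_track")
  seq_states <- states
  if (debounce > 1L) {
    # a state only counts once it has persisted >= debounce frames;
    # shorter excursions are absorbed into the surrounding state
    r <- rle(states)
    vals <- r$values[r$lengths >= debounce]
    if (length(vals) == 0L) vals <- states[1]
    seq_states <- rle(vals)$values       # collapse repeats after absorption
  }
  n_trans <- if (length(seq_states) > 1L)
    sum(seq_states[-1] != seq_states[-length(seq_states)]) else 0L
  duration_h <- (max(tr$frame) - min(tr$frame)) * dt / 3600
  list(transitions = as.integer(n_trans),
       per_hour = if (duration_h > 0) n_trans / duration_h else NA_real_)
}

#' Per-cell motility metrics for a set of tracks
#'
#' @param tracks list of `cell_track` objects from [track_cells()].
#' @param debounce passed to [compute_morphing_speed()].
#' @return Data frame: `cell_id`, `n_frames`, `cell_speed_um_min`,
#'   `mean_dA_over_p_um`, `transitions`, `morphing_speed_per_h`.
#' @export
motility_metrics <- function(tracks, debounce = 1L) {
  if (length(tracks) == 0L)
    stop_glia("no tracks to summarise", "invalid_track")
  do.call(rbind, lapply(tracks, function(tr) {
    ms <- compute_morphing_speed(tr, debounce = debounce)
    data.frame(cell_id = tr$cell_id[1], n_frames = nrow(tr),
               cell_speed_um_min = compute_cell_speed(tr),
               mean_dA_over_p_um = compute_membrane_change(tr)$mean,
               transitions = ms$transitions,
               morphing_speed_per_h = ms$per_hour)
  }))
}

#' Summarise per-cell metrics into a group table
#'
#' @param metrics data frame from [motility_metrics()].
#' @return A list with `per_cell` (the input) and `summary` (one row per
#'   metric: mean, SD, n). Two-group comparisons are delegated to
#'   [compare_groups()].
#' @export
summarize_movie <- function(metrics) {
  cols <- c("cell_speed_um_min", "mean_dA_over_p_um",
            "morphing_speed_per_h")
  summary <- do.call(rbind, lapply(cols, function(cl)
    data.frame(metric = cl, mean = mean(metrics[[cl]]),
               sd = if (nrow(metrics) > 1L) sd(metrics[[cl]]) else 0,
               n = nrow(metrics))))
  list(per_cell = metrics, summary = summary)
}

#' Run the full motility pipeline on a movie
#'
#' Segments every frame, extracts shape features, links tracks and computes
#' the three motility statistics (cell speed, mean dA/p, morphing speed).
#'
#' @param movie a [time_lapse_movie()].
#' @param params a [seg_params()].
#' @param max_step_um,min_track_len passed to [track_cells()].
#' @param debounce passed to [compute_morphing_speed()].
#' @param resample_to_1min if TRUE and the movie was acquired faster than 1
#'   frame/min, analyse every k-th frame so the analysis cadence is 1
#'   frame/min.
#' @return A list with `tracks`, `per_cell` metrics and the group `summary`.
#' @export
analyze_motility <- function(movie, params = seg_params(), max_step_um = 10,
                             min_track_len = 2, debounce = 1L,
                             resample_to_1min = FALSE) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (resample_to_1min && movie$frame_interval_s < 60) {
    k <- round(60 / movie$frame_interval_s)
    if (k > 1L) movie <- thin_frames(movie, k)
  }
  features <- vector("list", length(movie$frames))
  for (f in seq_along(movie$frames)) {
    lab <- withCallingHandlers(
      segment_frame(movie$frames[[f]], params),
      warning = function(w) invokeRestart("muffleWarning"))
    features[[f]] <- shape_features(lab, movie$pixel_size_um,
                                    frame_index = f)
  }
  tracks <- track_cells(features, movie$pixel_size_um,
                        movie$frame_interval_s, max_step_um = max_step_um,
                        min_track_len = min_track_len)
  metrics <- motility_metrics(tracks, debounce = debounce)
  c(list(tracks = tracks), summarize_movie(metrics))
}
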