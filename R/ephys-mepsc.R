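#' Estimate baseline noise SD of a current trace
#'
#' If no segments are given, the trace is cut into windows and the
#' lowest-variance half (variance at or below the median) is taken as
#' event-free baseline; the SD reported is the median of those windows'
#' SDs, each computed after subtracting the window mean. Requires at least
#' 100 ms of usable baseline.
#'
#' @param trace a [current_trace()].
#' @param segments optional list of index ranges `c(from, to)` declaring
#'   event-free stretches; overrides the automatic selection.
#' @param window_ms window size for the automatic selection.
#' @return An object of class `noise_estimate`: list with `sd_pA` and
#'   `segments` (list of index ranges used).
#' @export
estimate_noise_sd <- function(trace, segments = NULL, window_ms = 50) {
  stopifnot(inherits(trace, "current_trace"))
  fs <- trace$sampling_hz
  x <- trace$samples
  if (is.null(segments)) {
    w <- max(2L, round(window_ms / 1000 * fs))
    n_win <- floor(length(x) / w)
    if (n_win * w < round(0.1 * fs))
      stop_glia("less than 100 ms of trace available for noise estimation",
                "insufficient_baseline")
    m <- matrix(x[seq_len(n_win * w)], nrow = w)
    v <- apply(m, 2, var)
    keep <- which(v <= median(v))
    segments <- lapply(keep, function(k) c((k - 1L) * w + 1L, k * w))
    sds <- sqrt(v[keep])
    sd_pA <- median(sds)
  } else {
    total <- sum(vapply(segments, function(s) s[2] - s[1] + 1L, numeric(1)))
    if (total < round(0.1 * fs))
      stop_glia("less than 100 ms of declared baseline", "insufficient_baseline")
    vals <- unlist(lapply(segments, function(s) {
      seg <- x[s[1]:s[2]]
      seg - mean(seg)
    }))
    sd_pA <- sd(vals)
  }
  structure(list(sd_pA = unname(sd_pA), segments = segments),
            class = "noise_estimate")
}

#' Detect miniature EPSCs with noise-scaled thresholds
#'
#' Candidate deflections are found on the baseline-subtracted trace
#' (rolling-median baseline) as contiguous stretches exceeding the
#' amplitude threshold `k * SD`; each candidate window is extended to the
#' surrounding zero crossings and must additionally pass the area
#' threshold `k * SD * width_ms` (in pA*ms) when `combine = "and"` (the
#' default conservative rule; `"or"` accepts either threshold). Candidates
#' closer than the refractory window are merged so one event is not
#' counted twice, while events riding on a previous event's decay are
#' split at the valley between above-threshold peaks (peaks must be
#' separated by the refractory window and by a valley at least 2 SD below
#' both). Events are inward (negative) deflections and are reported as
#' positive magnitudes.
#'
#' @param trace a [current_trace()].
#' @param noise a [estimate_noise_sd()] result, or NULL to estimate it
#'   from the trace.
#' @param k threshold multiplier (the conventional range is 3-4).
#' @param baseline_window_ms rolling-median baseline window.
#' @param width_ms nominal event width for the area threshold.
#' @param refractory_ms merge window between candidates.
#' @param combine `"and"` (amplitude AND area) or `"or"`.
#' @param amp_smooth_ms light boxcar applied only when reading off the
#'   peak amplitude, emulating the usual 1 kHz analysis bandwidth.
#' @return An `event_list` data frame (`onset_s`, `peak_time_s`,
#'   `amplitude_pA`, `area_pA_ms`) with attributes `duration_s`, `k` and
#'   `noise_sd_pA`.
#' @export
detect_mepscs <- function(trace, noise = NULL, k = 3.5,
                          baseline_window_ms = 200, width_ms = 10,
                          refractory_ms = 5, combine = c("and", "or"),
                          amp_smooth_ms = 0.5) {
  stopifnot(inherits(trace, "current_trace"))
  combine <- match.arg(combine)
  if (k < 1) stop_glia("'k' must be >= 1", "invalid_spec")
  fs <- trace$sampling_hz
  x <- trace$samples
  if (length(x) == 0L)
    stop_glia("empty trace", "invalid_trace")
  empty <- data.frame(onset_s = numeric(0), peak_time_s = numeric(0),
                      amplitude_pA = numeric(0), area_pA_ms = numeric(0))
  duration_s <- length(x) / fs
  if (is.null(noise)) noise <- estimate_noise_sd(trace)
  sd_n <- noise$sd_pA
  bw <- round(baseline_window_ms / 1000 * fs)
  if (bw %% 2 == 0) bw <- bw + 1L
  baseline <- if (length(x) > bw) runmed(x, bw, endrule = "median")
              else rep(median(x), length(x))
  d <- -(x - baseline)                  # positive = inward deflection
  thr_amp <- k * sd_n
  thr_area <- k * sd_n * width_ms
  above <- d > thr_amp
  if (!any(above)) {
    out <- empty
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # merge runs separated by less than the refractory window
    gap <- round(refractory_ms / 1000 * fs)
    if (nrow(runs) > 1L) {
      keep <- c(TRUE, runs[-1, 1] - runs[-nrow(runs), 2] > gap)
      grp <- cumsum(keep)
      runs <- cbind(tapply(runs[, 1], grp, min), tapply(runs[, 2], grp, max))
    }
    max_ext <- round(0.05 * fs)         # never extend beyond 50 ms
    sw <- max(1L, round(amp_smooth_ms / 1000 * fs))
    boxcar <- function(v) {
      if (amp_smooth_ms <= 0 || length(v) < 2L * sw + 2L) return(v)
      out <- as.numeric(stats::filter(c(rep(v[1], sw), v,
                                        rep(v[length(v)], sw)),
                                      rep(1 / (2 * sw + 1), 2 * sw + 1),
                                      sides = 2))
      out[(sw + 1L):(sw + length(v))]
    }
    gap_n <- max(1L, round(refractory_ms / 1000 * fs))
    rows <- vector("list", nrow(runs))
    for (q in seq_len(nrow(runs))) {
      a <- runs[q, 1]; b <- runs[q, 2]
      while (a > 1L && d[a - 1L] > 0 && runs[q, 1] - a < max_ext) a <- a - 1L
      while (b < length(d) && d[b + 1L] > 0 && b - runs[q, 2] < max_ext)
        b <- b + 1L
      win <- d[a:b]
      w <- boxcar(win)
      amp <- max(w)
      area <- sum(win) / fs * 1000      # pA*ms
      ok <- if (combine == "and") amp >= thr_amp && area >= thr_area
            else amp >= thr_amp || area >= thr_area
      if (!ok) next
      # split riding events: local maxima above threshold, separated by
      # at least the refractory window and by a valley at least 2 SD
      # below both flanking peaks
      n_w <- length(w)
      pk <- which(w >= thr_amp &
                    w > c(-Inf, w[-n_w]) & w >= c(w[-1], -Inf))
      if (length(pk) == 0L) pk <- which.max(w)
      acc <- pk[1]
      if (length(pk) > 1L) {
        for (p in pk[-1]) {
          lastp <- acc[length(acc)]
          if (p - lastp < gap_n) next
          valley <- min(w[lastp:p])
          if (valley <= min(w[lastp], w[p]) - 2 * sd_n)
            acc <- c(acc, p)
        }
      }
      # sub-window boundaries at the deepest valley between kept peaks
      bounds <- c(1L, vapply(seq_along(acc)[-1], function(m) {
        seg <- acc[m - 1L]:acc[m]
        seg[which.min(w[seg])]
      }, integer(1)), n_w)
      rows[[q]] <- do.call(rbind, lapply(seq_along(acc), function(m) {
        lo <- bounds[m]; hi <- bounds[m + 1L]
        data.frame(onset_s = (a + lo - 2) / fs,
                   peak_time_s = (a + acc[m] - 2) / fs,
                   amplitude_pA = w[acc[m]],
                   area_pA_ms = sum(win[lo:hi]) / fs * 1000)
      }))
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  }
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, duration_s = duration_s, k = k, noise_sd_pA = sd_n,
            class = c("event_list", "data.frame"))
}

#' Summary statistics of a detected-event list
#'
#' @param events an `event_list` from [detect_mepscs()] (or any data frame
#'   with `amplitude_pA`).
#' @param duration_s recording duration; defaults to the event list's
#'   attribute.
#' @return A list with `n`, `frequency_hz`, `amplitude_mean_pA`,
#'   `amplitude_sem_pA`, and `amplitude_defined` (FALSE when no events
#'   were detected, in which case the amplitude fields are NA).
#' @export
summarize_mepscs <- function(events, duration_s = attr(events, "duration_s")) {
  if (is.null(duration_s) || duration_s <= 0)
    stop_glia("positive recording duration required", "invalid_spec")
  n <- nrow(events)
  if (n == 0L)
    return(list(n = 0L, frequency_hz = 0, amplitude_mean_pA = NA_real_,
                amplitude_sem_pA = NA_real_, amplitude_defined = FALSE))
  list(n = n, frequency_hz = n / duration_s,
       amplitude_mean_pA = mean(events$amplitude_pA),
       amplitude_sem_pA = if (n > 1L) sd(events$amplitude_pA) / sqrt(n)
                          else NA_real_,
       amplitude_defined = TRUE)
}
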