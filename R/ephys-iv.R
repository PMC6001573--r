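#' I/V curve container
#'
#' @param v_mV strictly increasing step voltages.
#' @param i_pA one measured current per voltage.
#' @param window description of the measurement window.
#' @return An object of class `iv_curve` (a data frame).
#' @export
iv_curve <- function(v_mV, i_pA, window = "last two-thirds of step") {
  if (length(v_mV) != length(i_pA))
    stop_glia("voltages and currents differ in length", "invalid_curve")
  if (any(diff(v_mV) <= 0))
    stop_glia("voltages must be strictly increasing", "invalid_curve")
  structure(data.frame(v_mV = v_mV, i_pA = i_pA),
            window = window, class = c("iv_curve", "data.frame"))
}

#' Measure step currents of a sweep set into an I/V curve
#'
#' For each voltage step the current is averaged over the final two-thirds
#' of the step duration, excluding the first third so capacitive transients
#' do not contaminate the estimate.
#'
#' @param sweeps a `sweep_set` (see [generate_sweepset()]), i.e. a list
#'   with a `voltage_step_protocol` and one [current_trace()] per step.
#' @param window_fraction fraction of the step, taken from the end, over
#'   which to average (default 2/3).
#' @return An [iv_curve()].
#' @export
measure_step_currents <- function(sweeps, window_fraction = 2 / 3) {
  stopifnot(inherits(sweeps, "sweep_set") || is.list(sweeps))
  vs <- protocol_steps(sweeps$protocol)
  if (length(sweeps$traces) != length(vs))
    stop_glia(sprintf("protocol has %d steps but %d traces supplied",
                      length(vs), length(sweeps$traces)),
              "protocol_mismatch")
  dur_s <- sweeps$protocol$step_duration_ms / 1000
  i_meas <- vapply(seq_along(vs), function(k) {
    tr <- sweeps$traces[[k]]
    n_step <- round(dur_s * tr$sampling_hz)
    if (length(tr$samples) < n_step)
      stop_glia("trace shorter than the protocol step duration",
                "protocol_mismatch")
    t_k <- (seq_len(n_step) - 1) / tr$sampling_hz
    mean(tr$samples[seq_len(n_step)][t_k >= dur_s * (1 - window_fraction)])
  }, numeric(1))
  ord <- order(vs)
  iv_curve(vs[ord], i_meas[ord],
           window = sprintf("last %.3g of %g ms step", window_fraction,
                            sweeps$protocol$step_duration_ms))
}

#' Pointwise difference of two I/V curves
#'
#' `after - before`, the curve of the conductance added between the two
#' recordings (e.g. before vs after agonist application). The voltage
#' grids must match exactly.
#'
#' @param after,before [iv_curve()] objects on identical voltage grids.
#' @return An [iv_curve()].
#' @export
difference_curve <- function(after, before) {
  stopifnot(inherits(after, "iv_curve"), inherits(before, "iv_curve"))
  if (nrow(after) != nrow(before) ||
      any(abs(after$v_mV - before$v_mV) > 1e-9))
    stop_glia("I/V curves are on different voltage grids", "grid_mismatch")
  iv_curve(after$v_mV, after$i_pA - before$i_pA,
           window = attr(after, "window"))
}

#' Reversal potential of an I/V curve
#'
#' Locates the sign change of the current and linearly interpolates the
#' zero crossing between the two bracketing grid points. If several
#' crossings exist the one nearest 0 mV is returned and the result is
#' flagged ambiguous (attribute `ambiguous`, plus a warning). A curve with
#' no sign change raises a `no_reversal` error rather than silently
#' returning a value.
#'
#' @param curve an [iv_curve()].
#' @return Reversal potential in mV (attribute `ambiguous` = TRUE if
#'   several crossings were present).
#' @export
estimate_reversal_potential <- function(curve) {
  stopifnot(inherits(curve, "iv_curve"))
  v <- curve$v_mV; i <- curve$i_pA
  exact <- which(i == 0)
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0)
  e_rev <- c(v[exact],
             vapply(cross, function(k)
               v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k]),
               numeric(1)))
  if (length(e_rev) == 0L)
    stop_glia("current does not change sign: no reversal in tested range",
              "no_reversal")
  ambiguous <- length(e_rev) > 1L
  if (ambiguous)
    warning(sprintf("%d sign changes found; reporting the one nearest 0 mV",
                    length(e_rev)))
  out <- e_rev[which.min(abs(e_rev))]
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Series-resistance stability check
#'
#' A recording is discarded when the series resistance deviates from its
#' initial value by more than `threshold_fraction` (default 25%) at any
#' point during the experiment.
#'
#' @param rs_MOhm series-resistance readings in megaohms, in time order.
#' @param threshold_fraction maximum tolerated |Rs(t) - Rs(0)| / Rs(0).
#' @return A list with `pass` (logical; FALSE = discard) and
#'   `max_change_fraction`.
#' @export
check_rs_stability <- function(rs_MOhm, threshold_fraction = 0.25) {
  if (length(rs_MOhm) < 2L)
    stop_glia("need at least two Rs readings", "invalid_qc")
  if (any(!is.finite(rs_MOhm)) || any(rs_MOhm <= 0))
    stop_glia("series resistance must be positive", "invalid_qc")
  change <- max(abs(rs_MOhm - rs_MOhm[1])) / rs_MOhm[1]
  list(pass = change <= threshold_fraction, max_change_fraction = change)
}

#' Rolling-mean time course of holding current
#'
#' Convenience view of the holding-current amplitude over time during an
#' application experiment (no target values attached).
#'
#' @param trace a [current_trace()].
#' @param window_s rolling-mean window in seconds.
#' @return Data frame with `time_s` and `i_pA`.
#' @export
holding_current_timecourse <- function(trace, window_s = 1) {
  stopifnot(inherits(trace, "current_trace"))
  n <- length(trace$samples)
  w <- max(1L, round(window_s * trace$sampling_hz))
  cs <- cumsum(c(0, trace$samples))
  starts <- seq(1L, n - w + 1L, by = w)
  data.frame(time_s = (starts - 1 + w / 2) / trace$sampling_hz,
             i_pA = (cs[starts + w] - cs[starts]) / w)
}
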