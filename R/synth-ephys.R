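#' Voltage-step protocol
#'
#' Defaults are the microglia step protocol: holding -20 mV, steps from
#' -140 to +60 mV in 20 mV increments, 250 ms per step, 5 s between steps.
#'
#' @param holding_mV holding potential between steps (mV); use -70 for the
#'   neuronal recordings.
#' @param step_start_mV,step_stop_mV,step_increment_mV step grid (mV); the
#'   increment must divide the span exactly.
#' @param step_duration_ms duration of each step (> 0).
#' @param inter_step_interval_s interval between steps (s).
#' @return An object of class `voltage_step_protocol`.
#' @export
voltage_step_protocol <- function(holding_mV = -20, step_start_mV = -140,
                                  step_stop_mV = 60, step_increment_mV = 20,
                                  step_duration_ms = 250,
                                  inter_step_interval_s = 5) {
  check_number(step_duration_ms, "step_duration_ms", min = 0,
               strict_min = TRUE)
  check_number(step_increment_mV, "step_increment_mV", min = 0,
               strict_min = TRUE)
  span <- step_stop_mV - step_start_mV
  if (span <= 0 || abs(span / step_increment_mV -
                         round(span / step_increment_mV)) > 1e-9)
    stop_glia("step increment must divide (stop - start)", "invalid_spec")
  structure(list(holding_mV = holding_mV, step_start_mV = step_start_mV,
                 step_stop_mV = step_stop_mV,
                 step_increment_mV = step_increment_mV,
                 step_duration_ms = step_duration_ms,
                 inter_step_interval_s = inter_step_interval_s),
            class = "voltage_step_protocol")
}

#' Step voltages of a protocol
#' @param protocol a [voltage_step_protocol()].
#' @return Numeric vector of step command voltages (mV), increasing.
#' @export
protocol_steps <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_step_protocol"))
  seq(protocol$step_start_mV, protocol$step_stop_mV,
      by = protocol$step_increment_mV)
}

#' Single current trace
#'
#' @param samples current samples in pA.
#' @param sampling_hz sampling rate (> 0).
#' @param command_mV optional command-voltage value or series.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_hz, command_mV = NULL) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop_glia("trace samples must be finite numbers", "invalid_trace")
  check_number(sampling_hz, "sampling_hz", min = 0, strict_min = TRUE)
  structure(list(samples = as.numeric(samples), sampling_hz = sampling_hz,
                 command_mV = command_mV),
            class = "current_trace")
}

#' Specification for a synthetic voltage-step recording
#'
#' The membrane model is two linear conductances plus a capacitive
#' transient: the steady-state current at step voltage V is
#' `g_leak (V - E_leak) + g_add r(V) (V - E_add)` (pA, with conductances in
#' nS and voltages in mV), where `r(V) = rect_gain` for V > E_add under
#' `rectification = "outward"` and 1 otherwise. Each step carries a
#' capacitive transient `cap_gain (V - holding) exp(-t/tau)`.
#'
#' @param protocol a [voltage_step_protocol()].
#' @param leak_conductance_nS,leak_reversal_mV leak conductance and reversal.
#' @param added_conductance_nS,added_reversal_mV added (e.g. ligand-gated)
#'   conductance and its reversal; defaults emulate an outward slightly
#'   rectifying conductance reversing at +15 mV.
#' @param rectification `"none"` or `"outward"`.
#' @param rect_gain conductance gain above `added_reversal_mV` when
#'   `rectification = "outward"`.
#' @param capacitance_tau_ms transient decay time constant (> 0).
#' @param cap_gain_pA_per_mV transient amplitude per mV of step (from
#'   holding); 0 disables the transient.
#' @param noise_sd_pA white current noise SD.
#' @param sampling_hz digitisation rate (default 10 kHz).
#' @param seed integer seed.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(protocol = voltage_step_protocol(),
                       leak_conductance_nS = 2, leak_reversal_mV = -40,
                       added_conductance_nS = 0, added_reversal_mV = 15,
                       rectification = c("none", "outward"), rect_gain = 1.5,
                       capacitance_tau_ms = 5, cap_gain_pA_per_mV = 3,
                       noise_sd_pA = 0, sampling_hz = 10000, seed = 1L) {
  rectification <- match.arg(rectification)
  stopifnot(inherits(protocol, "voltage_step_protocol"))
  check_number(leak_conductance_nS, "leak_conductance_nS", min = 0)
  check_number(added_conductance_nS, "added_conductance_nS", min = 0)
  check_number(capacitance_tau_ms, "capacitance_tau_ms", min = 0,
               strict_min = TRUE)
  check_number(noise_sd_pA, "noise_sd_pA", min = 0)
  check_number(sampling_hz, "sampling_hz", min = 0, strict_min = TRUE)
  structure(list(protocol = protocol,
                 leak_conductance_nS = leak_conductance_nS,
                 leak_reversal_mV = leak_reversal_mV,
                 added_conductance_nS = added_conductance_nS,
                 added_reversal_mV = added_reversal_mV,
                 rectification = rectification, rect_gain = rect_gain,
                 capacitance_tau_ms = capacitance_tau_ms,
                 cap_gain_pA_per_mV = cap_gain_pA_per_mV,
                 noise_sd_pA = noise_sd_pA, sampling_hz = sampling_hz,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Noise-free steady-state current of a sweep spec
#' @param spec a [sweep_spec()].
#' @param v_mV step voltage(s) in mV.
#' @return Steady-state current(s) in pA.
#' @export
steady_state_current <- function(spec, v_mV) {
  stopifnot(inherits(spec, "sweep_spec"))
  gain <- ifelse(spec$rectification == "outward" &
                   v_mV > spec$added_reversal_mV, spec$rect_gain, 1)
  spec$leak_conductance_nS * (v_mV - spec$leak_reversal_mV) +
    spec$added_conductance_nS * gain * (v_mV - spec$added_reversal_mV)
}

#' Generate a synthetic voltage-step sweep set
#'
#' One current trace per step voltage; samples are taken at
#' `t_k = (k - 1) / sampling_hz` from step onset.
#'
#' @param spec a [sweep_spec()].
#' @param label optional condition label (e.g. `"baseline"`).
#' @return An object of class `sweep_set`: list with `protocol`, `traces`
#'   (one [current_trace()] per step, in step order) and `label`.
#' @export
generate_sweepset <- function(spec, label = "baseline") {
  stopifnot(inherits(spec, "sweep_spec"))
  with_seed(spec$seed, {
    vs <- protocol_steps(spec$protocol)
    n <- round(spec$protocol$step_duration_ms / 1000 * spec$sampling_hz)
    tt <- (seq_len(n) - 1) / spec$sampling_hz
    traces <- lapply(vs, function(v) {
      i <- steady_state_current(spec, v) +
        spec$cap_gain_pA_per_mV * (v - spec$protocol$holding_mV) *
          exp(-tt / (spec$capacitance_tau_ms / 1000))
      if (spec$noise_sd_pA > 0) i <- i + rnorm(n, sd = spec$noise_sd_pA)
      current_trace(i, spec$sampling_hz, command_mV = v)
    })
    structure(list(protocol = spec$protocol, traces = traces, label = label),
              class = "sweep_set")
  })
}

#' Specification for a synthetic mEPSC recording
#'
#' Miniature events are biexponential inward transients at Poisson times on
#' Gaussian noise; overlapping events sum linearly. Defaults emulate the
#' baseline condition of the neuronal recordings: ~5.5 Hz events of ~20 pA
#' mean amplitude, digitised at 10 kHz.
#'
#' @param duration_s recording length (s).
#' @param sampling_hz digitisation rate (>= 1000).
#' @param event_rate_hz Poisson event rate (>= 0).
#' @param amplitude_mean_pA,amplitude_cv lognormal peak-amplitude mean and
#'   coefficient of variation (cv 0 = fixed amplitude).
#' @param tau_rise_ms,tau_decay_ms biexponential time constants
#'   (rise < decay).
#' @param noise_sd_pA Gaussian baseline noise SD.
#' @param seed integer seed.
#' @return An object of class `mepsc_spec`.
#' @export
mepsc_spec <- function(duration_s = 120, sampling_hz = 10000,
                       event_rate_hz = 5.5, amplitude_mean_pA = 20.45,
                       amplitude_cv = 0.3, tau_rise_ms = 0.5,
                       tau_decay_ms = 5, noise_sd_pA = 2, seed = 1L) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(sampling_hz, "sampling_hz", min = 1000)
  check_number(event_rate_hz, "event_rate_hz", min = 0)
  check_number(amplitude_mean_pA, "amplitude_mean_pA", min = 0,
               strict_min = TRUE)
  check_number(amplitude_cv, "amplitude_cv", min = 0)
  if (tau_rise_ms >= tau_decay_ms)
    stop_glia("tau_rise must be smaller than tau_decay", "invalid_spec")
  check_number(noise_sd_pA, "noise_sd_pA", min = 0)
  structure(list(duration_s = duration_s, sampling_hz = sampling_hz,
                 event_rate_hz = event_rate_hz,
                 amplitude_mean_pA = amplitude_mean_pA,
                 amplitude_cv = amplitude_cv, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, noise_sd_pA = noise_sd_pA,
                 seed = as.integer(seed)),
            class = "mepsc_spec")
}

# biexponential kernel with unit peak; t in seconds
biexp_kernel <- function(t, tau_rise_s, tau_decay_s) {
  tpk <- tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
  pk <- exp(-tpk / tau_decay_s) - exp(-tpk / tau_rise_s)
  (exp(-t / tau_decay_s) - exp(-t / tau_rise_s)) / pk
}

#' Generate a synthetic mEPSC trace with planted events
#'
#' @param spec a [mepsc_spec()].
#' @return A list with `trace` (a [current_trace()]; events are negative
#'   deflections, the standard inward-current convention at -70 mV) and
#'   `events` (data frame of planted ground truth: `onset_s`,
#'   `amplitude_pA` as positive magnitudes).
#' @export
generate_mepsc_trace <- function(spec) {
  stopifnot(inherits(spec, "mepsc_spec"))
  with_seed(spec$seed, {
    fs <- spec$sampling_hz
    n <- round(spec$duration_s * fs)
    x <- numeric(n)
    n_ev <- rpois(1, spec$event_rate_hz * spec$duration_s)
    onsets <- sort(runif(n_ev, 0, spec$duration_s))
    if (spec$amplitude_cv > 0) {
      sdlog <- sqrt(log(1 + spec$amplitude_cv^2))
      amps <- rlnorm(n_ev, log(spec$amplitude_mean_pA) - sdlog^2 / 2, sdlog)
    } else {
      amps <- rep(spec$amplitude_mean_pA, n_ev)
    }
    if (n_ev > 0) {
      klen <- min(n, round(10 * spec$tau_decay_ms / 1000 * fs))
      kt <- (seq_len(klen) - 1) / fs
      kernel <- biexp_kernel(kt, spec$tau_rise_ms / 1000,
                             spec$tau_decay_ms / 1000)
      for (e in seq_len(n_ev)) {
        i0 <- floor(onsets[e] * fs) + 1L
        i1 <- min(n, i0 + klen - 1L)
        if (i0 <= n)
          x[i0:i1] <- x[i0:i1] - amps[e] * kernel[seq_len(i1 - i0 + 1L)]
      }
    }
    if (spec$noise_sd_pA > 0) x <- x + rnorm(n, sd = spec$noise_sd_pA)
    list(trace = current_trace(x, fs),
         events = data.frame(onset_s = onsets, amplitude_pA = amps))
  })
}
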