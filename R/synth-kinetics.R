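#' Specification for a synthetic uptake/degradation/release time course
#'
#' First-order per-interval accounting of internalised material: over each
#' interval between consecutive measured time points a fixed fraction of the
#' current internal pool is digested and a fixed fraction is released to the
#' supernatant. Defaults emulate a 3-h uptake pulse followed by washout
#' measurements after 5, 9 and 21 h.
#'
#' @param initial_internal_level internal level at the first time point
#'   (arbitrary housekeeping-normalised densitometry units).
#' @param digestion_fraction_per_interval fraction of the internal pool
#'   digested per interval, in \[0, 1\].
#' @param release_fraction_per_interval fraction released per interval;
#'   digestion + release must be <= 1.
#' @param interval_times_h strictly increasing measurement times (h).
#' @param noise_cv multiplicative measurement noise CV (lognormal, mean 1).
#' @param seed integer seed.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(initial_internal_level = 1,
                          digestion_fraction_per_interval = 0.4,
                          release_fraction_per_interval = 0.1,
                          interval_times_h = c(3, 8, 12, 24),
                          noise_cv = 0.1, seed = 1L) {
  check_number(initial_internal_level, "initial_internal_level", min = 0)
  check_number(digestion_fraction_per_interval,
               "digestion_fraction_per_interval", min = 0, max = 1)
  check_number(release_fraction_per_interval,
               "release_fraction_per_interval", min = 0, max = 1)
  if (digestion_fraction_per_interval + release_fraction_per_interval > 1)
    stop_glia("digestion + release fractions must be <= 1 per interval",
              "invalid_spec")
  if (length(interval_times_h) < 2L || any(diff(interval_times_h) <= 0))
    stop_glia("'interval_times_h' must be >= 2 strictly increasing times",
              "invalid_spec")
  check_number(noise_cv, "noise_cv", min = 0)
  structure(list(initial_internal_level = initial_internal_level,
                 digestion_fraction_per_interval =
                   digestion_fraction_per_interval,
                 release_fraction_per_interval =
                   release_fraction_per_interval,
                 interval_times_h = interval_times_h, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "kinetics_spec")
}

# mean-1 multiplicative lognormal noise
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, -sdlog^2 / 2, sdlog)
}

#' Generate a synthetic degradation/release time course
#'
#' The noise-free process conserves mass: initial internal level = final
#' internal + cumulative digested + cumulative released. Measurement noise
#' is applied multiplicatively to the observed levels only, never to the
#' underlying pool.
#'
#' @param spec a [kinetics_spec()].
#' @return A list with `table` (data frame: `time_h`, `internal_level`,
#'   `supernatant_level`; supernatant in the same internal-equivalent units,
#'   i.e. calibration factor 1) and `truth` (noise-free levels plus the
#'   planted per-interval digested and released amounts).
#' @export
generate_degradation_timecourse <- function(spec) {
  stopifnot(inherits(spec, "kinetics_spec"))
  with_seed(spec$seed, {
    times <- spec$interval_times_h
    np <- length(times)
    internal <- numeric(np); sup <- numeric(np)
    digested <- numeric(np - 1L); released <- numeric(np - 1L)
    internal[1] <- spec$initial_internal_level; sup[1] <- 0
    for (k in seq_len(np - 1L)) {
      digested[k] <- internal[k] * spec$digestion_fraction_per_interval
      released[k] <- internal[k] * spec$release_fraction_per_interval
      internal[k + 1L] <- internal[k] - digested[k] - released[k]
      sup[k + 1L] <- sup[k] + released[k]
    }
    tab <- data.frame(
      time_h = times,
      internal_level = internal * lnorm_noise(np, spec$noise_cv),
      supernatant_level = sup * lnorm_noise(np, spec$noise_cv))
    list(table = tab,
         truth = list(internal = internal, supernatant = sup,
                      digested = digested, released = released))
  })
}

#' Specification for a synthetic assay matrix
#'
#' Features-by-samples matrix of nonnegative intensities: per-feature
#' lognormal baseline times a per-condition multiplicative effect times
#' mean-1 lognormal noise. The expression flavour additionally marks a
#' fraction of entries as too close to background.
#'
#' @param n_features number of features (rows).
#' @param conditions named list of per-condition effects; each element is a
#'   positive scalar or a positive length-`n_features` vector. Defaults
#'   emulate a four-treatment design with two replicates.
#' @param n_replicates replicates per condition (>= 2).
#' @param noise_cv multiplicative noise CV.
#' @param flag_fraction probability that an entry is flagged
#'   below-background (expression flavour only).
#' @param seed integer seed.
#' @return An object of class `assay_spec`.
#' @export
assay_spec <- function(n_features = 40,
                       conditions = list(ctrl = 1, ngf = 1, abeta = 1,
                                         abeta_ngf = 1),
                       n_replicates = 2, noise_cv = 0.1, flag_fraction = 0,
                       seed = 1L) {
  check_number(n_features, "n_features", min = 1)
  check_number(n_replicates, "n_replicates", min = 2)
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(flag_fraction, "flag_fraction", min = 0, max = 1)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop_glia("'conditions' must be a named list", "invalid_spec")
  for (nm in names(conditions)) {
    eff <- conditions[[nm]]
    if (!is.numeric(eff) || any(eff <= 0) ||
        !(length(eff) %in% c(1L, n_features)))
      stop_glia(sprintf("condition '%s' effects must be positive scalars or length n_features", nm),
                "invalid_spec")
  }
  structure(list(n_features = as.integer(n_features),
                 conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, flag_fraction = flag_fraction,
                 seed = as.integer(seed)),
            class = "assay_spec")
}

#' Generate a synthetic assay matrix with planted condition effects
#'
#' @param spec an [assay_spec()].
#' @param flavor `"cytokine"` (no flags) or `"expression"` (carries a 0/1
#'   well-above-background flag matrix; 1 = well above background).
#' @return An [assay_table()] whose `truth` attribute records the baseline
#'   and per-condition effect vectors.
#' @export
generate_assay_matrix <- function(spec, flavor = c("cytokine", "expression")) {
  stopifnot(inherits(spec, "assay_spec"))
  flavor <- match.arg(flavor)
  with_seed(spec$seed, {
    nf <- spec$n_features
    conds <- names(spec$conditions)
    baseline <- rlnorm(nf, log(100), 1)
    effects <- lapply(spec$conditions, function(e) rep(e, length.out = nf))
    samples <- data.frame(
      sample = paste(rep(conds, each = spec$n_replicates),
                     rep(seq_len(spec$n_replicates), length(conds)),
                     sep = "_r"),
      condition = rep(conds, each = spec$n_replicates),
      replicate = rep(seq_len(spec$n_replicates), length(conds)),
      stringsAsFactors = FALSE)
    ns <- nrow(samples)
    values <- matrix(NA_real_, nf, ns,
                     dimnames = list(paste0("feature_", seq_len(nf)),
                                     samples$sample))
    for (s in seq_len(ns))
      values[, s] <- baseline * effects[[samples$condition[s]]] *
        lnorm_noise(nf, spec$noise_cv)
    flags <- NULL
    if (flavor == "expression") {
      flags <- matrix(1L, nf, ns, dimnames = dimnames(values))
      if (spec$flag_fraction > 0)
        flags[matrix(runif(nf * ns) < spec$flag_fraction, nf, ns)] <- 0L
    }
    tab <- assay_table(values, samples, flags = flags)
    attr(tab, "truth") <- list(baseline = baseline, effects = effects)
    tab
  })
}

#' Stated-world cytokine panel
#'
#' Convenience [assay_spec()] reproducing the qualitative structure of the
#' inflammation-array experiment: four treatments (control, NGF, amyloid,
#' amyloid + NGF) with two replicates, in which a subset of inflammatory
#' features is raised several-fold by amyloid, mildly lowered by NGF, and
#' returned to baseline when NGF accompanies amyloid.
#'
#' @param n_features number of features (default 40, a typical antibody
#'   array size).
#' @param inflammatory_fraction fraction of features responsive to amyloid.
#' @param abeta_fold fold-increase of inflammatory features under amyloid.
#' @param ngf_fold fold-change of inflammatory features under NGF alone.
#' @param noise_cv multiplicative noise CV.
#' @param seed integer seed.
#' @return An [assay_spec()].
#' @export
cytokine_panel_spec <- function(n_features = 40, inflammatory_fraction = 0.3,
                                abeta_fold = 3, ngf_fold = 0.7,
                                noise_cv = 0.15, seed = 1L) {
  n_inf <- max(1L, round(n_features * inflammatory_fraction))
  eff <- function(fold) c(rep(fold, n_inf), rep(1, n_features - n_inf))
  assay_spec(n_features = n_features,
             conditions = list(ctrl = rep(1, n_features),
                               ngf = eff(ngf_fold),
                               abeta = eff(abeta_fold),
                               abeta_ngf = rep(1, n_features)),
             n_replicates = 2, noise_cv = noise_cv, flag_fraction = 0,
             seed = seed)
}
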