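# Independent oracles used across the suite. These deliberately re-derive
# quantities with brute force / closed forms, not by calling the pipeline
# code they check.

# per-cell motility metrics recomputed directly from generator ground truth
oracle_motility <- function(truth, pixel_size_um, frame_interval_s) {
  do.call(rbind, lapply(split(truth, truth$cell_id), function(d) {
    d <- d[order(d$frame), ]
    n <- nrow(d)
    steps <- sqrt(diff(d$x_px)^2 + diff(d$y_px)^2) * pixel_size_um
    dA <- abs(diff(d$area_px2)) * pixel_size_um^2
    pbar <- (d$perimeter_px[-1] + d$perimeter_px[-n]) / 2 * pixel_size_um
    data.frame(cell_id = d$cell_id[1],
               x0 = d$x_px[1], y0 = d$y_px[1],
               speed_um_min = mean(steps) / (frame_interval_s / 60),
               dap_um = mean(dA / pbar),
               transitions = sum(d$state[-1] != d$state[-n]))
  }))
}

# one-to-one greedy matching of detected events to planted onsets
match_events <- function(planted_onsets, detected_onsets, tol_s = 0.010) {
  matched <- logical(length(planted_onsets))
  used <- logical(length(detected_onsets))
  for (i in order(planted_onsets)) {
    d <- abs(detected_onsets - planted_onsets[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1L && is.finite(d[j]) && d[j] <= tol_s) {
      matched[i] <- TRUE
      used[j] <- TRUE
    }
  }
  matched
}

# optimal assignment by exhaustive permutation (fine for n <= 6): returns
# the permutation of columns minimising total distance
hungarian_oracle <- function(cost) {
  n <- nrow(cost)
  stopifnot(n <= 6, ncol(cost) == n)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  best
}

# rasterized disk oracle: pixels with centre within r of (cy, cx), 0-based
disk_oracle_count <- function(cy, cx, r, nr, nc) {
  g <- expand.grid(i = seq_len(nr) - 1, j = seq_len(nc) - 1)
  sum((g$i - cy)^2 + (g$j - cx)^2 <= r^2)
}

# small movie spec used by several motility tests
tiny_movie_spec <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 3, duration_frames = 12, frame_interval_s = 60,
         pixel_size_um = 0.5, image_shape = c(240L, 240L),
         translocation_speed_um_min = 1, membrane_change_rate = 0.2,
         morph_transition_prob = 0.05, noise_level = 0, seed = 1L),
    list(...))
  do.call(movie_spec, args)
}
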