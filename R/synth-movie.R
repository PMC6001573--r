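#' Specification for a synthetic microglia time-lapse movie
#'
#' Describes the stated acquisition world: bright ramified cells on a dark
#' background, imaged at a fixed frame interval with known pixel size.
#' Defaults emulate a 1-hour acquisition at 1 frame / 30 s through a 40x
#' objective with a cohort of 29 cells per experiment.
#'
#' @param n_cells number of cells planted in the field.
#' @param duration_frames number of frames (>= 2).
#' @param frame_interval_s seconds between frames.
#' @param pixel_size_um microns per pixel.
#' @param image_shape integer vector `(rows, cols)` in pixels.
#' @param translocation_speed_um_min planted cell-body speed, um/min. The
#'   walk is diffusive (fresh direction each frame) so cells do not drift
#'   out of the field; the planted *step length* per frame is exact.
#' @param membrane_change_rate target mean dA/p per frame pair, in um.
#'   Realised by stochastic soma-radius fluctuation, calibrated closed-loop
#'   on the true masks to within a few percent of the target.
#' @param morph_transition_prob per-frame probability of switching between
#'   the roundish and polarized shape states.
#' @param noise_level additive Gaussian intensity noise SD as a fraction of
#'   the foreground intensity (foreground = 1, background = 0).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return An object of class `movie_spec`.
#' @export
movie_spec <- function(n_cells = 29, duration_frames = 120,
                       frame_interval_s = 30, pixel_size_um = 0.4,
                       image_shape = c(768L, 768L),
                       translocation_speed_um_min = 0.5,
                       membrane_change_rate = 0.15,
                       morph_transition_prob = 0.01,
                       noise_level = 0.1, seed = 1L) {
  check_number(n_cells, "n_cells", min = 1)
  check_number(duration_frames, "duration_frames", min = 2)
  check_number(frame_interval_s, "frame_interval_s", min = 0, strict_min = TRUE)
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  check_number(translocation_speed_um_min, "translocation_speed_um_min", min = 0)
  check_number(membrane_change_rate, "membrane_change_rate", min = 0)
  check_number(morph_transition_prob, "morph_transition_prob", min = 0, max = 1)
  check_number(noise_level, "noise_level", min = 0)
  if (length(image_shape) != 2L || any(image_shape < 16))
    stop_glia("'image_shape' must be two pixel dimensions >= 16", "invalid_spec")
  structure(list(n_cells = as.integer(n_cells),
                 duration_frames = as.integer(duration_frames),
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 image_shape = as.integer(image_shape),
                 translocation_speed_um_min = translocation_speed_um_min,
                 membrane_change_rate = membrane_change_rate,
                 morph_transition_prob = morph_transition_prob,
                 noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "movie_spec")
}

#' Time-lapse movie container
#'
#' @param frames list of numeric matrices, one per time point, equal shape.
#' @param pixel_size_um microns per pixel (> 0).
#' @param frame_interval_s seconds between frames (> 0).
#' @return An object of class `time_lapse_movie`.
#' @export
time_lapse_movie <- function(frames, pixel_size_um, frame_interval_s) {
  if (!is.list(frames) || length(frames) < 2L)
    stop_glia("a movie needs at least 2 frames", "invalid_movie")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_glia("all frames must have the same shape", "invalid_movie")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  check_number(frame_interval_s, "frame_interval_s", min = 0, strict_min = TRUE)
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "time_lapse_movie")
}

#' @export
print.time_lapse_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("time_lapse_movie: %d frames of %dx%d px, %.3g um/px, %g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              x$frame_interval_s))
  invisible(x)
}

# ---- rendering ------------------------------------------------------------

# pixels (1-based i,j) covered by a disk of radius r centred at 0-based (cy, cx)
disk_pixels <- function(cy, cx, r, nr, nc) {
  i0 <- max(1L, floor(cy - r) + 1L); i1 <- min(nr, ceiling(cy + r) + 1L)
  j0 <- max(1L, floor(cx - r) + 1L); j1 <- min(nc, ceiling(cx + r) + 1L)
  if (i0 > i1 || j0 > j1) return(cbind(i = integer(0), j = integer(0)))
  ii <- i0:i1; jj <- j0:j1
  g <- expand.grid(i = ii, j = jj)
  keep <- (g$i - 1 - cy)^2 + (g$j - 1 - cx)^2 <= r^2
  cbind(i = g$i[keep], j = g$j[keep])
}

# rasterize one cell: soma disk + tapered branches; returns logical crop
# mask plus the 0-based (row, col) offset of the crop within the frame
render_cell <- function(cy, cx, r_soma, branches, nr, nc, reach) {
  pad <- 2L
  i0 <- max(1L, floor(cy - reach) + 1L - pad)
  i1 <- min(nr, ceiling(cy + reach) + 1L + pad)
  j0 <- max(1L, floor(cx - reach) + 1L - pad)
  j1 <- min(nc, ceiling(cx + reach) + 1L + pad)
  cnr <- i1 - i0 + 1L; cnc <- j1 - j0 + 1L
  m <- matrix(FALSE, cnr, cnc)
  off <- c(i0 - 1L, j0 - 1L)           # 0-based offset of crop
  ly <- cy - off[1]; lx <- cx - off[2] # centre in crop coords (0-based)
  px <- disk_pixels(ly, lx, r_soma, cnr, cnc)
  m[px] <- TRUE
  if (!is.null(branches) && nrow(branches) > 0) {
    for (b in seq_len(nrow(branches))) {
      ang <- branches$angle[b]; len <- branches$length[b]
      dy <- sin(ang); dx <- cos(ang)
      for (t in seq(0, len, by = 0.5)) {
        w <- 2.2 - 1.3 * t / len
        py <- ly + (r_soma - 1 + t) * dy
        pxx <- lx + (r_soma - 1 + t) * dx
        px <- disk_pixels(py, pxx, w, cnr, cnc)
        m[px] <- TRUE
      }
    }
  }
  list(mask = m, offset = off)
}

draw_branch_set <- function(state) {
  n <- if (state == "polarized") sample(2:4, 1L) else sample(0:1, 1L)
  if (n == 0L)
    return(data.frame(angle = numeric(0), length = numeric(0)))
  base <- runif(1, 0, 2 * pi)
  jit <- if (n > 1L) runif(n, -0.25, 0.25) else runif(n, -pi, pi)
  data.frame(angle = base + (seq_len(n) - 1L) * 2 * pi / n + jit,
             length = runif(n, 10, 16))
}

# Draw everything random up front; rendering is then deterministic so the
# membrane-rate calibration loop can re-render without consuming RNG.
plan_movie <- function(spec) {
  nf <- spec$duration_frames
  step_px <- spec$translocation_speed_um_min * spec$frame_interval_s / 60 /
    spec$pixel_size_um
  r0 <- runif(spec$n_cells, 7, 9)
  reach <- max(r0) + 16 + 3
  # each cell random-walks inside its own territory so cells can never
  # overlap regardless of duration; the planted step length stays exact
  confine_r <- max(12, 3 * step_px)
  margin <- reach + confine_r
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  if (2 * margin >= min(nr, nc))
    stop_glia("image too small to place cells without overlap", "sizing_error")
  min_sep <- 2 * margin + 2
  centers <- matrix(NA_real_, spec$n_cells, 2)  # (y, x), 0-based
  tries <- 0L
  for (k in seq_len(spec$n_cells)) {
    repeat {
      tries <- tries + 1L
      if (tries > 500L * spec$n_cells)
        stop_glia("image too small to place cells without overlap",
                  "sizing_error")
      cand <- c(runif(1, margin, nr - 1 - margin),
                runif(1, margin, nc - 1 - margin))
      if (k == 1L) { centers[k, ] <- cand; break }
      dd <- sqrt(rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                            matrix(cand, k - 1L, 2, byrow = TRUE))^2))
      if (all(dd >= min_sep)) { centers[k, ] <- cand; break }
    }
  }
  cells <- vector("list", spec$n_cells)
  for (k in seq_len(spec$n_cells)) {
    pos <- matrix(NA_real_, nf, 2)
    pos[1, ] <- centers[k, ]
    for (t in seq_len(nf - 1L)) {
      for (try in 1:50) {
        th <- runif(1, 0, 2 * pi)
        cand <- pos[t, ] + step_px * c(sin(th), cos(th))
        if (sqrt(sum((cand - centers[k, ])^2)) <= confine_r) break
        cand <- pos[t, ]          # degenerate fallback: stay put
      }
      pos[t + 1L, ] <- cand
    }
    state <- character(nf)
    state[1] <- sample(c("roundish", "polarized"), 1L)
    flips <- runif(nf - 1L) < spec$morph_transition_prob
    for (t in seq_len(nf - 1L))
      state[t + 1L] <- if (flips[t])
        setdiff(c("roundish", "polarized"), state[t]) else state[t]
    n_seg <- 1L + sum(flips)
    segs <- cumsum(c(TRUE, flips))          # segment id per frame
    configs <- vector("list", n_seg)
    for (s in seq_len(n_seg))
      configs[[s]] <- draw_branch_set(state[match(s, segs)])
    cells[[k]] <- list(r0 = r0[k], pos = pos, state = state, segs = segs,
                       configs = configs, e_raw = runif(nf, -1, 1),
                       transitions = sum(flips))
  }
  list(cells = cells, reach = reach)
}

render_plan <- function(plan, spec, a) {
  nf <- spec$duration_frames
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ncell <- length(plan$cells)
  masks <- vector("list", ncell)
  truth <- vector("list", ncell)
  for (k in seq_len(ncell)) {
    cl <- plan$cells[[k]]
    per_frame <- vector("list", nf)
    rows <- data.frame(cell_id = k, frame = seq_len(nf), x_px = NA_real_,
                       y_px = NA_real_, area_px2 = NA_integer_,
                       perimeter_px = NA_integer_,
                       n_branches = NA_integer_,
                       state = cl$state, stringsAsFactors = FALSE)
    for (t in seq_len(nf)) {
      r_t <- max(4, cl$r0 + a * cl$e_raw[t])
      br <- cl$configs[[cl$segs[t]]]
      rc <- render_cell(cl$pos[t, 1], cl$pos[t, 2], r_t, br, nr, nc,
                        plan$reach)
      mm <- mask_metrics(rc$mask, rc$offset)
      rows$x_px[t] <- mm$x_px; rows$y_px[t] <- mm$y_px
      rows$area_px2[t] <- mm$area_px2
      rows$perimeter_px[t] <- mm$perimeter_px
      rows$n_branches[t] <- nrow(br)
      per_frame[[t]] <- rc
    }
    masks[[k]] <- per_frame
    truth[[k]] <- rows
  }
  list(masks = masks, truth = do.call(rbind, truth))
}

realized_dap <- function(truth, spec) {
  um <- spec$pixel_size_um
  vals <- vapply(split(truth, truth$cell_id), function(d) {
    d <- d[order(d$frame), ]
    dA <- abs(diff(d$area_px2)) * um^2
    p <- (d$perimeter_px[-1] + d$perimeter_px[-nrow(d)]) / 2 * um
    mean(dA / p)
  }, numeric(1))
  mean(vals)
}

#' Generate a synthetic microglia movie with planted ground truth
#'
#' Renders `n_cells` bright cells (soma disk plus 0-4 tapered branches) on a
#' dark background. The polarized state is rendered with >= 2 branches and
#' the roundish state with <= 1, so shape-state ground truth is unambiguous.
#' Membrane dynamics are implemented as stochastic soma-radius fluctuation,
#' calibrated in a closed loop so the realised mean dA/p on the true masks
#' matches `membrane_change_rate`; radius fluctuation is radially symmetric,
#' which keeps the planted centroid speed decoupled from membrane activity.
#'
#' @param spec a [movie_spec()].
#' @return A list with components `movie` ([time_lapse_movie()]), `truth`
#'   (data frame: cell_id, frame, x_px, y_px, area_px2, perimeter_px,
#'   n_branches, state), and `transitions` (data frame: cell_id,
#'   transitions). Ground-truth areas/perimeters/centroids are computed on
#'   the exact rendered masks with the same estimators the pipeline uses.
#' @export
generate_cell_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  with_seed(spec$seed, {
    plan <- plan_movie(spec)
    target <- spec$membrane_change_rate
    # mean|dr| of U(-a,a) pairs is 2a/3 and dA/p of a disk under the
    # edge-count perimeter is ~(2*pi/8)|dr|, so a ~ 1.9 target / px size
    a <- if (target > 0) 1.9 * target / spec$pixel_size_um else 0
    rendered <- render_plan(plan, spec, a)
    if (target > 0) {
      for (it in 1:3) {
        realized <- realized_dap(rendered$truth, spec)
        if (realized <= 0 || abs(realized - target) / target < 0.03) break
        a <- a * target / realized
        rendered <- render_plan(plan, spec, a)
      }
    }
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    frames <- vector("list", spec$duration_frames)
    for (t in seq_len(spec$duration_frames)) {
      f <- matrix(0, nr, nc)
      for (k in seq_along(rendered$masks)) {
        rc <- rendered$masks[[k]][[t]]
        w <- which(rc$mask, arr.ind = TRUE)
        f[cbind(w[, 1] + rc$offset[1], w[, 2] + rc$offset[2])] <- 1
      }
      if (spec$noise_level > 0)
        f <- f + matrix(rnorm(nr * nc, sd = spec$noise_level), nr, nc)
      frames[[t]] <- f
    }
    transitions <- data.frame(
      cell_id = seq_along(plan$cells),
      transitions = vapply(plan$cells, `[[`, numeric(1), "transitions"))
    list(movie = time_lapse_movie(frames, spec$pixel_size_um,
                                  spec$frame_interval_s),
         truth = rendered$truth,
         transitions = transitions,
         membrane_scale_px = a,
         spec = spec)
  })
}

#' Keep every k-th frame of a movie
#'
#' Reproduces a coarser analysis cadence from a finer acquisition (for
#' example analysing at 1 frame/min a movie acquired at 1 frame/30 s with
#' `keep_every = 2`). The frame interval is rescaled accordingly.
#'
#' @param movie a [time_lapse_movie()].
#' @param keep_every positive integer stride.
#' @return A [time_lapse_movie()].
#' @export
thin_frames <- function(movie, keep_every = 2L) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  check_number(keep_every, "keep_every", min = 1)
  idx <- seq(1L, length(movie$frames), by = as.integer(keep_every))
  time_lapse_movie(movie$frames[idx], movie$pixel_size_um,
                   movie$frame_interval_s * keep_every)
}
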