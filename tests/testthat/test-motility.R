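# build a bare cell_track from vectors, as track_cells would
make_track <- function(x_px, y_px, area_px2 = NULL, perimeter_px = NULL,
                       state = NULL, pixel_size_um = 1,
                       frame_interval_s = 60, frame = seq_along(x_px)) {
  n <- length(x_px)
  df <- data.frame(frame = frame, x_px = x_px, y_px = y_px,
                   area_px2 = if (is.null(area_px2)) rep(100, n) else area_px2,
                   perimeter_px = if (is.null(perimeter_px)) rep(40, n)
                                  else perimeter_px,
                   state = if (is.null(state)) rep("roundish", n) else state,
                   cell_id = 1L)
  attr(df, "pixel_size_um") <- pixel_size_um
  attr(df, "frame_interval_s") <- frame_interval_s
  class(df) <- c("cell_track", "data.frame")
  df
}

test_that("cell speed follows unit arithmetic and a random-walk oracle", {
  # static track
  expect_equal(compute_cell_speed(make_track(rep(5, 10), rep(5, 10))), 0)
  # 2 px/frame at 1 um/px and 60 s interval -> 2 um/min
  expect_equal(compute_cell_speed(make_track(2 * (0:9), rep(0, 10))), 2)
  # planted random walk vs brute-force mean step length
  set.seed(42)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  tr <- make_track(x, y, pixel_size_um = 0.5, frame_interval_s = 30)
  oracle <- mean(sqrt(diff(x)^2 + diff(y)^2)) * 0.5 / (30 / 60)
  expect_equal(compute_cell_speed(tr), oracle, tolerance = 1e-9)
  expect_error(compute_cell_speed(make_track(1, 1)),
               class = "undefined_metric")
})

test_that("dA/p uses absolute area change over the mean perimeter", {
  # identical consecutive masks -> all zero
  z <- compute_membrane_change(make_track(rep(0, 5), rep(0, 5)))
  expect_equal(z$series, rep(0, 4))
  # hand arithmetic: 100 -> 120 px^2, perimeters 40 and 44 px, 1 um/px
  tr <- make_track(c(0, 0), c(0, 0), area_px2 = c(100, 120),
                   perimeter_px = c(40, 44))
  expect_equal(compute_membrane_change(tr)$mean, 20 / 42)
  # symmetric grow/shrink oscillation gives a constant series
  tr2 <- make_track(rep(0, 6), rep(0, 6),
                    area_px2 = rep(c(100, 120), 3),
                    perimeter_px = rep(c(40, 44), 3))
  expect_equal(length(unique(round(compute_membrane_change(tr2)$series, 12))),
               1L)
  expect_error(
    compute_membrane_change(make_track(c(0, 0), c(0, 0),
                                       perimeter_px = c(0, 40))),
    class = "invalid_shape")
})

test_that("dA/p and speed scale linearly with pixel size", {
  set.seed(7)
  x <- cumsum(rnorm(20)); y <- cumsum(rnorm(20))
  a <- 100 + cumsum(rnorm(20, sd = 4)); p <- rep(40, 20)
  t1 <- make_track(x, y, a, p, pixel_size_um = 0.5)
  t2 <- make_track(x, y, a, p, pixel_size_um = 1.0)
  expect_equal(compute_cell_speed(t2), 2 * compute_cell_speed(t1))
  expect_equal(compute_membrane_change(t2)$mean,
               2 * compute_membrane_change(t1)$mean)
})

test_that("morphing speed counts state changes per hour", {
  # constant state
  tr <- make_track(rep(0, 60), rep(0, 60), state = rep("roundish", 60))
  expect_equal(compute_morphing_speed(tr)$per_hour, 0)
  # R,P,R over one hour of frames -> 2 transitions/h
  st <- c(rep("roundish", 20), rep("polarized", 20), rep("roundish", 21))
  tr2 <- make_track(rep(0, 61), rep(0, 61), state = st)
  ms <- compute_morphing_speed(tr2)
  expect_equal(ms$transitions, 2L)
  expect_equal(ms$per_hour, 2)
  # random planted sequence vs brute-force scan
  set.seed(5)
  st3 <- sample(c("roundish", "polarized"), 80, replace = TRUE)
  tr3 <- make_track(rep(0, 80), rep(0, 80), state = st3)
  expect_equal(compute_morphing_speed(tr3)$transitions,
               sum(st3[-1] != st3[-80]))
  # per-hour rate is invariant to frame-interval relabelling
  tr4 <- make_track(rep(0, 61), rep(0, 61), state = st,
                    frame_interval_s = 30)
  expect_equal(compute_morphing_speed(tr4)$transitions, 2L)
  expect_equal(compute_morphing_speed(tr4)$per_hour, 4)  # same count, 0.5 h
  # debounce absorbs one-frame flickers
  st5 <- c(rep("roundish", 10), "polarized", rep("roundish", 10))
  tr5 <- make_track(rep(0, 21), rep(0, 21), state = st5)
  expect_equal(compute_morphing_speed(tr5)$transitions, 2L)
  expect_equal(compute_morphing_speed(tr5, debounce = 2)$transitions, 0L)
})

test_that("segmentation matches the raster oracle on synthetic disks", {
  # uniform frame -> empty labelling with a warning
  expect_warning(lab0 <- segment_frame(matrix(0.5, 64, 64)),
                 "no object")
  expect_equal(attr(lab0, "n"), 0L)
  # one bright disk: pixel count equals the rasterised disk oracle
  img <- matrix(0, 80, 80)
  img[(row(img) - 1 - 40)^2 + (col(img) - 1 - 40)^2 <= 100] <- 1
  lab <- segment_frame(img, seg_params(smooth_sigma = 0, threshold = "fixed",
                                       threshold_value = 0.5))
  expect_equal(attr(lab, "n"), 1L)
  expect_equal(sum(lab == 1L), disk_oracle_count(40, 40, 10, 80, 80))
  # two disjoint disks -> two masks
  img2 <- matrix(0, 80, 80)
  img2[(row(img2) - 1 - 20)^2 + (col(img2) - 1 - 20)^2 <= 64] <- 1
  img2[(row(img2) - 1 - 58)^2 + (col(img2) - 1 - 58)^2 <= 64] <- 1
  lab2 <- segment_frame(img2, seg_params(smooth_sigma = 0,
                                         threshold = "fixed",
                                         threshold_value = 0.5))
  expect_equal(attr(lab2, "n"), 2L)
  expect_equal(length(masks_from_labels(lab2)), 2L)
})

test_that("morphology classification follows the two-ramification rule", {
  mk_disk <- function(n, cy, cx, r) {
    m <- matrix(FALSE, n, n)
    m[(row(m) - 1 - cy)^2 + (col(m) - 1 - cx)^2 <= r^2] <- TRUE
    m
  }
  add_branch <- function(m, cy, cx, angle, len, width = 1.6) {
    for (t in seq(0, len, by = 0.5)) {
      py <- cy + t * sin(angle); px <- cx + t * cos(angle)
      m[(row(m) - 1 - py)^2 + (col(m) - 1 - px)^2 <= width^2] <- TRUE
    }
    m
  }
  # perfect disk -> roundish, 0 ramifications
  d <- classify_morphology(mk_disk(50, 25, 25, 9))
  expect_equal(d$n_ramifications, 0L)
  expect_equal(d$state, "roundish")
  # one long protrusion -> still roundish (boundary rule: >= 2 needed)
  m1 <- add_branch(mk_disk(60, 30, 30, 9), 30, 30, 0, 22)
  c1 <- classify_morphology(m1)
  expect_equal(c1$n_ramifications, 1L)
  expect_equal(c1$state, "roundish")
  # three branches -> polarized with 3 ramifications
  m3 <- mk_disk(80, 40, 40, 9)
  for (ang in c(0.3, 2.4, 4.4)) m3 <- add_branch(m3, 40, 40, ang, 24)
  c3 <- classify_morphology(m3)
  expect_equal(c3$n_ramifications, 3L)
  expect_equal(c3$state, "polarized")
  expect_error(classify_morphology(mk_disk(20, 10, 10, 1.5)),
               class = "invalid_shape")
})

test_that("tracking links planted cells and ends on disappearance", {
  feat <- function(frame, xs, ys) {
    n <- length(xs)
    data.frame(frame = frame, object = seq_len(n), x_px = xs, y_px = ys,
               area_px2 = rep(100, n), perimeter_px = rep(40, n),
               n_ramifications = rep(0L, n), state = rep("roundish", n))
  }
  # static single cell over 10 frames -> one track of length 10
  fs <- lapply(1:10, function(f) feat(f, 50, 50))
  trks <- track_cells(fs, pixel_size_um = 1, frame_interval_s = 60)
  expect_length(trks, 1L)
  expect_equal(nrow(trks[[1]]), 10L)
  # cell disappearing at frame 6 -> track ends at frame 5
  fs2 <- c(lapply(1:5, function(f) feat(f, c(20, 60), c(20, 60))),
           lapply(6:8, function(f) feat(f, 60, 60)))
  trks2 <- track_cells(fs2, pixel_size_um = 1, frame_interval_s = 60)
  lens <- sort(vapply(trks2, nrow, integer(1)))
  expect_equal(lens, c(5L, 8L))
  # five drifting cells recovered with identities matching the
  # Hungarian-assignment oracle against the planted start positions
  set.seed(3)
  starts <- cbind(x = c(20, 20, 60, 60, 100), y = c(20, 80, 40, 110, 70))
  paths <- lapply(1:5, function(k)
    cbind(starts[k, 1] + cumsum(rnorm(12, sd = 1)),
          starts[k, 2] + cumsum(rnorm(12, sd = 1))))
  fs3 <- lapply(1:12, function(f)
    feat(f, vapply(paths, function(p) p[f, 1], numeric(1)),
         vapply(paths, function(p) p[f, 2], numeric(1))))
  trks3 <- track_cells(fs3, pixel_size_um = 1, frame_interval_s = 60,
                       max_step_um = 10, min_track_len = 12)
  expect_length(trks3, 5L)
  cost <- outer(seq_len(5), seq_len(5), Vectorize(function(a, b)
    sqrt((trks3[[a]]$x_px[1] - paths[[b]][1, 1])^2 +
           (trks3[[a]]$y_px[1] - paths[[b]][1, 2])^2)))
  assign <- hungarian_oracle(cost)
  for (a in 1:5) {
    b <- assign[a]
    expect_lt(max(abs(trks3[[a]]$x_px - paths[[b]][, 1])), 1e-9)
  }
})

test_that("summaries follow hand arithmetic", {
  m <- data.frame(cell_id = 1:2, n_frames = c(10, 10),
                  cell_speed_um_min = c(1, 3),
                  mean_dA_over_p_um = c(0.2, 0.2),
                  transitions = c(0L, 2L),
                  morphing_speed_per_h = c(0, 2))
  s <- summarize_movie(m)
  sp <- s$summary[s$summary$metric == "cell_speed_um_min", ]
  expect_equal(sp$mean, 2)
  expect_equal(sp$sd, sqrt(2))
  expect_equal(sp$n, 2L)
  s1 <- summarize_movie(m[1, ])
  expect_equal(s1$summary$sd, rep(0, 3))
})

test_that("cohort speed recovery from the generator (scaled)", {
  # scaled-down analogue of the full-cohort recovery: 5 cells, 20 frames
  spec <- tiny_movie_spec(n_cells = 5, duration_frames = 20,
                          translocation_speed_um_min = 1.2,
                          image_shape = c(320L, 320L), seed = 23)
  sim <- generate_cell_movie(spec)
  res <- analyze_motility(sim$movie, min_track_len = 20)
  expect_lt(abs(mean(res$per_cell$cell_speed_um_min) - 1.2) / 1.2, 0.05)
})
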