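#' Segmentation settings
#'
#' @param smooth_sigma Gaussian smoothing scale in px (0 disables).
#' @param threshold `"otsu"` or `"fixed"` (then `threshold_value` is used).
#' @param threshold_value intensity threshold when `threshold = "fixed"`.
#' @param min_area_px minimum object area in px^2.
#' @param fill_holes fill interior holes of each object.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma = 1, threshold = c("otsu", "fixed"),
                       threshold_value = NULL, min_area_px = 50,
                       fill_holes = TRUE) {
  threshold <- match.arg(threshold)
  check_number(smooth_sigma, "smooth_sigma", min = 0)
  check_number(min_area_px, "min_area_px", min = 0)
  if (threshold == "fixed" && is.null(threshold_value))
    stop_glia("'threshold_value' required for fixed thresholding",
              "invalid_spec")
  structure(list(smooth_sigma = smooth_sigma, threshold = threshold,
                 threshold_value = threshold_value,
                 min_area_px = min_area_px, fill_holes = fill_holes),
            class = "seg_params")
}

# separable Gaussian smoothing with border renormalisation
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  band <- function(n) {
    K <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) K[cbind(idx, idx + d)] <- w[d + r + 1L]
      else K[cbind(idx - d, idx)] <- w[d + r + 1L]
    }
    K / rowSums(K)
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

# Otsu threshold on a 256-bin histogram; returns the intensity cut
otsu_threshold <- function(img) {
  rng <- range(img)
  # degenerate (near-constant) images have no foreground
  if (diff(rng) <= max(1e-12, 1e-9 * max(abs(rng)))) return(Inf)
  h <- tabulate(pmin(256L, floor((img - rng[1]) / diff(rng) * 256) + 1L),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

#' Segment one movie frame into cell masks
#'
#' Gaussian smoothing, global thresholding (Otsu by default), optional hole
#' filling, 8-connected labelling, and a minimum-area filter. If no object
#' survives the area filter an empty labelling is returned with a warning,
#' not an error.
#'
#' @param frame numeric intensity matrix.
#' @param params a [seg_params()].
#' @return Integer label matrix (0 = background) with attribute `n` =
#'   number of objects; labels are 1..n.
#' @export
segment_frame <- function(frame, params = seg_params()) {
  stopifnot(is.matrix(frame))
  sm <- gaussian_smooth(frame, params$smooth_sigma)
  thr <- if (params$threshold == "otsu") otsu_threshold(sm)
         else params$threshold_value
  mask <- sm > thr
  if (params$fill_holes && any(mask)) mask <- .fill_holes(mask)
  lab <- .cc_label(mask)
  n <- attr(lab, "n")
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= params$min_area_px)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    attr(lab, "n") <- length(keep)
  }
  if (attr(lab, "n") == 0L)
    warning("no object above the minimum area in this frame")
  lab
}

#' Extract individual masks from a label matrix
#' @param labels label matrix from [segment_frame()].
#' @return List of logical matrices, one per object.
#' @export
masks_from_labels <- function(labels) {
  n <- attr(labels, "n")
  if (is.null(n)) n <- max(labels)
  lapply(seq_len(n), function(k) labels == k)
}

#' Classify a cell mask as roundish or polarized
#'
#' Skeletonises the mask (Zhang-Suen thinning) and counts ramifications:
#' skeleton branches that terminate in an endpoint outside the maximal
#' inscribed soma disk and are at least `min_branch_px` long. A cell is
#' polarized iff it has at least two ramifications, otherwise roundish
#' (a single long protrusion is still roundish).
#'
#' @param mask logical matrix (one cell).
#' @param min_branch_px minimum branch length, px.
#' @param min_area_px masks smaller than this raise an invalid-shape error.
#' @param soma_margin_px extra clearance beyond the inscribed soma radius an
#'   endpoint must have before it can seed a ramification.
#' @return A list with `state` (`"roundish"`/`"polarized"`) and
#'   `n_ramifications`.
#' @export
classify_morphology <- function(mask, min_branch_px = 5, min_area_px = 20,
                                soma_margin_px = 2) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (sum(mask) < min_area_px)
    stop_glia("mask smaller than the minimum object area", "invalid_shape")
  mask <- .fill_holes(mask)
  dist <- .chamfer_dist(mask)
  ctr <- which(dist == max(dist), arr.ind = TRUE)[1, ]
  soma_r <- max(dist)
  skel <- .thin_mask(mask)
  pts <- which(skel, arr.ind = TRUE)
  if (nrow(pts) == 0L)
    return(list(state = "roundish", n_ramifications = 0L))
  # endpoints: skeleton pixels with exactly one skeleton neighbour
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- skel
  nbrs <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbrs <- nbrs + pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  ep <- which(skel & nbrs == 1L, arr.ind = TRUE)
  if (nrow(ep) == 0L)
    return(list(state = "roundish", n_ramifications = 0L))
  # a ramification is an endpoint whose radial clearance beyond the
  # inscribed soma disk is at least the minimum branch length (a lower
  # bound on the branch's true path length, robust to skeleton staircases)
  d_ctr <- sqrt((ep[, 1] - ctr[1])^2 + (ep[, 2] - ctr[2])^2)
  keep <- d_ctr >= soma_r + max(min_branch_px, soma_margin_px)
  ep <- ep[keep, , drop = FALSE]
  # merge endpoints closer than 3 px (side spurs at a branch tip)
  n_ram <- 0L
  taken <- logical(nrow(ep))
  for (q in seq_len(nrow(ep))) {
    if (taken[q]) next
    n_ram <- n_ram + 1L
    dd <- sqrt((ep[, 1] - ep[q, 1])^2 + (ep[, 2] - ep[q, 2])^2)
    taken[dd < 3] <- TRUE
  }
  list(state = if (n_ram >= 2L) "polarized" else "roundish",
       n_ramifications = n_ram)
}

#' Per-object shape features of a segmented frame
#'
#' @param labels label matrix from [segment_frame()].
#' @param pixel_size_um microns per pixel.
#' @param frame_index frame number recorded in the output.
#' @param classify also run [classify_morphology()] per object.
#' @param min_branch_px passed to [classify_morphology()].
#' @return Data frame with one row per object: centroids (0-based px and
#'   um), area and perimeter in px and um, ramification count and state;
#'   the object's pixel linear indices are kept in the list column `pixels`
#'   for overlap-based track tie-breaking.
#' @export
shape_features <- function(labels, pixel_size_um, frame_index = NA_integer_,
                           classify = TRUE, min_branch_px = 5) {
  n <- attr(labels, "n")
  if (is.null(n)) n <- max(labels)
  if (n == 0L)
    return(data.frame(frame = integer(0), object = integer(0)))
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    wl <- which(labels == k)
    w <- arrayInd(wl, dim(labels))
    i0 <- max(1L, min(w[, 1]) - 2L); i1 <- min(nrow(labels), max(w[, 1]) + 2L)
    j0 <- max(1L, min(w[, 2]) - 2L); j1 <- min(ncol(labels), max(w[, 2]) + 2L)
    crop <- labels[i0:i1, j0:j1] == k
    mm <- mask_metrics(crop, offset = c(i0 - 1L, j0 - 1L))
    st <- if (classify)
      classify_morphology(crop, min_branch_px = min_branch_px)
    else list(state = NA_character_, n_ramifications = NA_integer_)
    rows[[k]] <- data.frame(
      frame = frame_index, object = k,
      x_px = mm$x_px, y_px = mm$y_px,
      x_um = mm$x_px * pixel_size_um, y_um = mm$y_px * pixel_size_um,
      area_px2 = mm$area_px2, perimeter_px = mm$perimeter_px,
      area_um2 = mm$area_px2 * pixel_size_um^2,
      perimeter_um = mm$perimeter_px * pixel_size_um,
      n_ramifications = st$n_ramifications, state = st$state,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$pixels <- lapply(seq_len(n), function(k) which(labels == k))
  out
}
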