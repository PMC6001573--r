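#' Link segmented objects across frames into cell tracks
#'
#' Greedy nearest-centroid linking: for each frame, candidate (track,
#' object) pairs closer than `max_step_um` are accepted in order of
#' increasing centroid distance; exact distance ties are broken by larger
#' pixel overlap with the track's previous mask, then by lower track id.
#' Unlinked objects start new tracks; a track that finds no match in a
#' frame ends there (no gap bridging). Tracks shorter than `min_track_len`
#' frames are dropped.
#'
#' @param features list of per-frame data frames from [shape_features()]
#'   (in frame order), or a single data frame with a `frame` column.
#' @param pixel_size_um,frame_interval_s movie metadata attached to each
#'   track for the metric computations.
#' @param max_step_um maximum centroid displacement per frame.
#' @param min_track_len minimum track length in frames.
#' @return List of `cell_track` data frames (per-frame shape rows plus
#'   `cell_id`), each carrying `pixel_size_um` and `frame_interval_s`
#'   attributes.
#' @export
track_cells <- function(features, pixel_size_um, frame_interval_s,
                        max_step_um = 10, min_track_len = 2) {
  if (is.data.frame(features))
    features <- split(features, features$frame)
  if (length(features) < 2L)
    stop_glia("tracking needs at least 2 frames of masks", "invalid_track")
  max_step_px <- max_step_um / pixel_size_um
  rows <- list(); last <- list(); pix <- list()
  last_seen <- integer(0)
  has_pix <- function(fr) !is.null(fr$pixels)
  for (f in seq_along(features)) {
    fr <- features[[f]]
    nobj <- if (is.null(fr) || nrow(fr) == 0L) 0L else nrow(fr)
    active <- which(last_seen == f - 1L)
    matched_obj <- integer(0)
    if (nobj > 0L && length(active) > 0L) {
      lx <- vapply(last[active], function(r) r$x_px, numeric(1))
      ly <- vapply(last[active], function(r) r$y_px, numeric(1))
      d <- sqrt(outer(lx, fr$x_px, "-")^2 + outer(ly, fr$y_px, "-")^2)
      cand <- which(d <= max_step_px, arr.ind = TRUE)
      if (length(cand) > 0L) {
        cand <- matrix(cand, ncol = 2)
        dist <- d[cand]
        ov <- if (has_pix(fr)) {
          vapply(seq_len(nrow(cand)), function(q)
            length(intersect(pix[[active[cand[q, 1]]]],
                             fr$pixels[[cand[q, 2]]])), numeric(1))
        } else numeric(nrow(cand))
        ord <- order(dist, -ov, active[cand[, 1]])
        used_t <- logical(length(active)); used_o <- logical(nobj)
        for (q in ord) {
          a <- cand[q, 1]; b <- cand[q, 2]
          if (used_t[a] || used_o[b]) next
          used_t[a] <- TRUE; used_o[b] <- TRUE
          ti <- active[a]
          row <- fr[b, , drop = FALSE]
          rows[[ti]][[length(rows[[ti]]) + 1L]] <- row
          last[[ti]] <- row
          if (has_pix(fr)) pix[[ti]] <- fr$pixels[[b]]
          last_seen[ti] <- f
          matched_obj <- c(matched_obj, b)
        }
      }
    }
    for (b in setdiff(seq_len(nobj), matched_obj)) {
      row <- fr[b, , drop = FALSE]
      ti <- length(rows) + 1L
      rows[[ti]] <- list(row)
      last[[ti]] <- row
      pix[[ti]] <- if (has_pix(fr)) fr$pixels[[b]] else integer(0)
      last_seen[ti] <- f
    }
  }
  out <- list()
  for (ti in seq_along(rows)) {
    df <- do.call(rbind, rows[[ti]])
    if (nrow(df) < min_track_len) next
    df$pixels <- NULL
    df$cell_id <- length(out) + 1L
    attr(df, "pixel_size_um") <- pixel_size_um
    attr(df, "frame_interval_s") <- frame_interval_s
    class(df) <- c("cell_track", "data.frame")
    out[[length(out) + 1L]] <- df
  }
  out
}
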