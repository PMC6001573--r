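# Shared mask geometry. The synthetic-movie ground truth and the imaging
# pipeline use the *same* estimators (pixel-count area, exposed-edge-count
# perimeter, pixel-centroid), so oracle comparisons test the analysis chain
# rather than two perimeter conventions against each other.

# number of exposed pixel edges (4-neighbourhood) of a logical mask
edge_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sum(core & !pad[1:nr, 2:(nc + 1L)]) +
    sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) +
    sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

# area (px^2), perimeter (px) and 0-based centroid of a logical mask.
# `offset` = (row, col) 0-based position of the mask's [1,1] pixel within
# the full frame; centroids are reported in full-frame coordinates with
# x = column, y = row, both 0-based from the top-left pixel centre.
mask_metrics <- function(m, offset = c(0L, 0L)) {
  w <- which(m, arr.ind = TRUE)
  if (nrow(w) == 0L)
    return(list(area_px2 = 0L, perimeter_px = 0L, x_px = NA_real_,
                y_px = NA_real_))
  list(area_px2 = nrow(w),
       perimeter_px = edge_count(m),
       x_px = mean(w[, 2L] - 1L) + offset[2L],
       y_px = mean(w[, 1L] - 1L) + offset[1L])
}
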