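## Internal image primitives shared by the seed and rosette segmenters.
## Heavy lifting (4-connected labelling, hole filling, Otsu threshold) is
## EBImage; labels are then merged across diagonal adjacencies to get the
## 8-connectivity the counting rules assume.

## Label connected components with 8-connectivity. Returns an integer
## matrix, 0 = background, components numbered 1..k.
label_components <- function(mask) {
  mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  ## pairs of distinct labels touching diagonally
  d1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))    # \ diagonal
  d2 <- cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # / diagonal
  pairs <- rbind(d1, d2)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(k), find, 1L)
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

## Pixel count of the convex image of a set of pixels (regionprops-style
## "convex area"): hull of pixel centres, then count pixels whose centres
## lie inside or on the hull.
convex_pixel_area <- function(ys, xs) {
  n <- length(ys)
  if (n <= 2) return(n)
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) <= 2) return(n)
  h <- chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  if (length(h) <= 2) return(n)
  ## candidate pixels: bounding box of the hull
  gx <- seq(min(hx), max(hx))
  gy <- seq(min(hy), max(hy))
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  m <- length(hx)
  ## chull returns vertices clockwise; a point is inside iff it is on the
  ## clockwise side of (or on) every edge
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (cross <= 1e-9)
  }
  sum(inside)
}

## Per-component geometry for a binary mask (8-connectivity):
## area, convex area, solidity, centroid. Coordinates are within-mask,
## 1-based (row = y, col = x); `offset` shifts centroids to full-image
## coordinates.
component_stats <- function(mask, offset = c(0, 0)) {
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0) {
    return(tibble(object_id = integer(), area_px = integer(),
                  convex_area_px = integer(), solidity = numeric(),
                  centroid_x = numeric(), centroid_y = numeric()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  map(seq_len(k), function(i) {
    sel <- labs == i
    ys <- idx[sel, 1]; xs <- idx[sel, 2]
    area <- length(ys)
    carea <- convex_pixel_area(ys, xs)
    tibble(
      object_id = i, area_px = area, convex_area_px = as.integer(carea),
      solidity = area / carea,
      centroid_x = mean(xs) + offset[1], centroid_y = mean(ys) + offset[2]
    )
  }) |> list_rbind()
}

## Remove components smaller than min_area; keep border-touching objects.
remove_small <- function(mask, min_area) {
  if (min_area <= 1) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

## Keep only the largest component (empty mask passes through).
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

fill_holes <- function(mask) {
  m <- mask
  mode(m) <- "integer"
  out <- EBImage::fillHull(m)
  matrix(as.logical(out), nrow(mask), ncol(mask))
}

## Otsu threshold of values in [0,1]; returns NA when the values are too
## uniform for a meaningful split (guards blank wells).
otsu_threshold <- function(values, min_contrast = 0) {
  values <- values[is.finite(values)]
  if (!length(values)) return(NA_real_)
  th <- EBImage::otsu(matrix(values, nrow = 1), range = c(0, 1))
  if (min_contrast > 0) {
    lo <- values[values < th]; hi <- values[values >= th]
    if (!length(lo) || !length(hi) || (mean(hi) - mean(lo)) < min_contrast) {
      return(NA_real_)
    }
  }
  th
}
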