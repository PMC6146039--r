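# Shared fixtures, all built in code.

mini_layout <- function(n_rows = 2, n_cols = 3, plate_id = "mini") {
  plate_layout(n_rows, n_cols, origin_px = c(80, 80), pitch_px = 140,
               radius_px = 65, plate_id = plate_id)
}

mini_layout_48 <- function(n_rows = 2, n_cols = 2, plate_id = "mini48") {
  plate_layout(n_rows, n_cols, origin_px = c(55, 55), pitch_px = 90,
               radius_px = 40, plate_id = plate_id)
}

# uniform-colour plate image
flat_image <- function(layout, color = c(0.9, 0.9, 0.9), timestamp_h = 0) {
  d <- layout$image_size
  px <- array(rep(color, each = prod(d)), c(d[1], d[2], 3))
  plate_image(px, layout, timestamp_h = timestamp_h)
}

# paint an ellipse onto a plate image, returns the modified image
paint_ellipse <- function(image, cx, cy, a, b, theta = 0,
                          color = c(0.3, 0.2, 0.1)) {
  d <- dim(image$pixels)
  pix <- phenoplate:::ellipse_pixels(cx, cy, a, b, theta, d[2], d[1])
  for (ch in 1:3) image$pixels[cbind(pix, ch)] <- color[ch]
  image
}

# logical mask with a filled disk
disk_mask <- function(nrow, ncol, cx, cy, r) {
  outer(seq_len(nrow), seq_len(ncol),
        function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

# brute-force convex hull area of a pixel set: count grid points inside
# the hull polygon by exhaustive point-in-polygon over the bounding box
brute_convex_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1]; xs <- idx[, 2]
  if (length(ys) <= 2) return(length(ys))
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  count <- 0
  for (py in seq(min(hy), max(hy))) {
    for (px in seq(min(hx), max(hx))) {
      inside <- TRUE
      m <- length(hx)
      for (i in seq_len(m)) {
        j <- if (i == m) 1 else i + 1
        cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
        if (cr > 1e-9) { inside <- FALSE; break }  # chull is clockwise
      }
      if (inside) count <- count + 1
    }
  }
  count
}
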