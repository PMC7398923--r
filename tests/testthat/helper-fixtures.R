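# Shared fixtures, built in code.

# A random convex polygon: points on a jittered circle, sorted by angle.
random_convex_polygon <- function(n = 8, cx = 32, cy = 32, r = 20) {
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- r * runif(n, 0.6, 1)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# Independent per-pixel point-in-polygon oracle (even-odd rule, pixel
# centers at integer + 0.5), written as a plain double loop.
pip_oracle <- function(vertices, width, height) {
  n <- nrow(vertices)
  mask <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    yc <- r - 0.5
    for (c in seq_len(width)) {
      xc <- c - 0.5
      crossings <- 0
      for (k in seq_len(n)) {
        x1 <- vertices[k, 1]; y1 <- vertices[k, 2]
        k2 <- if (k == n) 1 else k + 1
        x2 <- vertices[k2, 1]; y2 <- vertices[k2, 2]
        if ((y1 <= yc) != (y2 <= yc)) {
          xint <- x1 + (yc - y1) * (x2 - x1) / (y2 - y1)
          if (xint < xc) crossings <- crossings + 1
        }
      }
      mask[r, c] <- crossings %% 2 == 1
    }
  }
  mask
}

random_box <- function(image_size = 128) {
  w <- runif(1, 4, image_size / 2)
  h <- runif(1, 4, image_size / 2)
  box(runif(1, 0, image_size - w), runif(1, 0, image_size - h), w, h)
}

# A tiny annotated image with one rectangle instance per class.
tiny_annotated_image <- function(id = "tiny", size = 64) {
  rect <- function(x0, y0, w, h) rbind(c(x0, y0), c(x0 + w, y0),
                                       c(x0 + w, y0 + h), c(x0, y0 + h))
  anns <- list(
    polygon_annotation("thorax", rect(5, 5, 12, 10)),
    polygon_annotation("abdomen", rect(25, 8, 20, 12)),
    polygon_annotation("wing", rect(10, 30, 18, 8)),
    polygon_annotation("leg", rbind(c(50, 30), c(55, 45), c(50, 58)),
                       shape = "polyline"))
  px <- array(as.integer(round(runif(size * size * 3, 0, 255))),
              c(size, size, 3))
  annotated_image(id, size, size, px, anns)
}

# Build a detection object directly (for evaluation tests).
make_detection <- function(label, score, b, size = 64, mask = NULL) {
  if (is.null(mask)) {
    mask <- matrix(FALSE, size, size)
    r <- (floor(b$y) + 1):min(size, ceiling(b$y + b$h))
    c <- (floor(b$x) + 1):min(size, ceiling(b$x + b$w))
    mask[r, c] <- TRUE
  }
  structure(list(label = label, score = score, box = b, mask = mask),
            class = "detection")
}
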