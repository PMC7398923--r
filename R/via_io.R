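#' Polygon annotations and annotated images
#'
#' A `polygon_annotation` is one instance: a class label (`thorax`,
#' `abdomen`, `wing` or `leg`) and an ordered ring of at least three `(x, y)`
#' vertices in continuous pixel coordinates (origin top-left, x rightward,
#' y downward).  `shape` distinguishes filled polygons from open polylines
#' (thin leg strokes), mirroring the two VIA region types.
#'
#' @param label One of `thorax`, `abdomen`, `wing`, `leg`.
#' @param vertices Numeric n x 2 matrix of `(x, y)` vertices, `n >= 3`,
#'   all coordinates finite and non-negative.
#' @param shape `"polygon"` (closed, filled) or `"polyline"` (open stroke).
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(label, vertices,
                               shape = c("polygon", "polyline")) {
  shape <- match.arg(shape)
  label <- as.character(label)
  if (!label %in% ANATOMY_CLASSES)
    stop("unknown anatomy label: ", label)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("polygon needs at least 3 vertices")
  if (!all(is.finite(vertices)) || any(vertices < 0))
    stop("vertices must be finite and non-negative")
  structure(list(label = label, vertices = unname(vertices), shape = shape),
            class = "polygon_annotation")
}

#' @param image_id Unique string identifier (usually the file name).
#' @param width,height Image dimensions in pixels.
#' @param pixels Optional `height x width x 3` integer array in `[0, 255]`.
#' @param annotations List of [polygon_annotation()] objects; every vertex
#'   must lie inside `[0, width] x [0, height]`.
#' @rdname polygon_annotation
#' @export
annotated_image <- function(image_id, width, height, pixels = NULL,
                            annotations = list()) {
  for (a in annotations) {
    if (any(a$vertices[, 1] > width) || any(a$vertices[, 2] > height))
      stop("annotation vertices outside image bounds in ", image_id)
  }
  if (!is.null(pixels) && !all(dim(pixels)[1:2] == c(height, width)))
    stop("pixel array does not match width/height in ", image_id)
  structure(list(image_id = image_id, width = width, height = height,
                 pixels = pixels, annotations = annotations),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  tab <- table(factor(vapply(x$annotations, `[[`, "", "label"),
                      levels = ANATOMY_CLASSES))
  cat(sprintf("<annotated_image %s %dx%d: %s>\n", x$image_id, x$width,
              x$height, paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Read a VGG Image Annotator (VIA) project
#'
#' Accepts both a flat image map and the VIA-2 `_via_img_metadata` wrapper.
#' Regions must have polygon or polyline `shape_attributes`; the class label
#' is taken from `region_attributes[[class_key]]`, falling back to the single
#' attribute present if `class_key` is absent.  Regions with labels outside
#' the four-class vocabulary are skipped with a warning.
#'
#' @param path Path to the VIA project JSON.
#' @param image_dir Optional directory searched for the image files named in
#'   the project; when found, pixels are loaded (PNG).
#' @param class_key Name of the region attribute holding the class label.
#' @return List of [annotated_image()] objects.
#' @export
read_via <- function(path, image_dir = NULL, class_key = "anatomy") {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("VIA parse error in '", path, "': ", conditionMessage(e)))
  imgs <- doc[["_via_img_metadata"]] %||% doc
  imgs <- imgs[!startsWith(names(imgs) %||% character(0), "_via_")]
  out <- vector("list", length(imgs))
  for (k in seq_along(imgs)) {
    entry <- imgs[[k]]
    fname <- entry$filename %||% names(imgs)[k]
    fa <- entry$file_attributes %||% list()
    pixels <- NULL
    if (!is.null(image_dir) && file.exists(file.path(image_dir, fname))) {
      pixels <- read_image_png(file.path(image_dir, fname))
    }
    width <- fa$width %||% (if (!is.null(pixels)) dim(pixels)[2] else NULL)
    height <- fa$height %||% (if (!is.null(pixels)) dim(pixels)[1] else NULL)
    anns <- list()
    for (reg in entry$regions %||% list()) {
      sa <- reg$shape_attributes
      if (is.null(sa) || !(sa$name %in% c("polygon", "polyline"))) next
      ra <- reg$region_attributes %||% list()
      label <- ra[[class_key]] %||% (if (length(ra) == 1) ra[[1]] else NULL)
      if (is.null(label) || !label %in% ANATOMY_CLASSES) {
        warning("skipping region with unknown label in ", fname)
        next
      }
      xs <- unlist(sa$all_points_x); ys <- unlist(sa$all_points_y)
      if (length(xs) < 3)
        stop("region with fewer than 3 vertices in image ", fname)
      anns <- c(anns, list(polygon_annotation(label, cbind(xs, ys), sa$name)))
    }
    if (is.null(width)) {
      vmax <- if (length(anns)) do.call(rbind, lapply(anns, `[[`, "vertices")) else cbind(1, 1)
      width <- ceiling(max(vmax[, 1])); height <- ceiling(max(vmax[, 2]))
    }
    out[[k]] <- annotated_image(fname, width, height, pixels, anns)
  }
  ids <- vapply(out, `[[`, "", "image_id")
  if (anyDuplicated(ids)) stop("duplicate image_id in VIA project: ",
                               ids[duplicated(ids)][1])
  out
}

#' Write annotations as a VIA project
#'
#' Emits the `_via_img_metadata` dialect readable by [read_via()]; vertex
#' coordinates and labels round-trip exactly.  Image width/height are stored
#' as file attributes (VIA itself records only the byte size).
#'
#' @param images List of [annotated_image()] objects.
#' @param path Output JSON path.
#' @param class_key Region attribute name used for the class label.
#' @export
write_via <- function(images, path, class_key = "anatomy") {
  meta <- list()
  for (im in images) {
    regions <- lapply(im$annotations, function(a) {
      ra <- list(); ra[[class_key]] <- a$label
      list(shape_attributes = list(name = a$shape,
                                   all_points_x = a$vertices[, 1],
                                   all_points_y = a$vertices[, 2]),
           region_attributes = ra)
    })
    meta[[im$image_id]] <- list(
      filename = im$image_id, size = -1L,
      regions = regions,
      file_attributes = list(width = im$width, height = im$height))
  }
  doc <- list(`_via_img_metadata` = meta)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(NULL)
}

#' Rasterize a polygon annotation to a binary mask
#'
#' A pixel belongs to the mask exactly when its center (at integer + 0.5
#' coordinates) falls inside the polygon under the even-odd rule.  Open
#' polylines and degenerate (near-zero-area) polygons are stroked instead:
#' a pixel is set when its center lies within `stroke_width / 2` of the
#' vertex path.
#'
#' @param poly A [polygon_annotation()].
#' @param width,height Output mask dimensions in pixels.
#' @param stroke_width Stroke diameter in pixels for polylines/degenerate
#'   polygons (default 2).
#' @return Logical `height x width` matrix.
#' @export
rasterize <- function(poly, width, height, stroke_width = 2) {
  v <- poly$vertices
  stroke <- poly$shape == "polyline" || abs(polygon_area(v)) < 1e-6
  if (stroke) {
    if (stroke_width <= 0) {
      warning("zero-area polygon with stroke width 0: empty mask")
      return(matrix(FALSE, height, width))
    }
    return(stroke_mask(v, width, height, stroke_width, closed = poly$shape == "polygon"))
  }
  fill_mask(v, width, height)
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Even-odd scanline fill over pixel centers.
fill_mask <- function(v, width, height) {
  mask <- matrix(FALSE, height, width)
  n <- nrow(v)
  j <- c(2:n, 1)
  x1 <- v[, 1]; y1 <- v[, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
  r0 <- max(1L, floor(min(y1) + 0.5))
  r1 <- min(height, ceiling(max(y1) + 0.5))
  if (r1 < r0) return(mask)
  xc <- seq_len(width) - 0.5
  for (r in r0:r1) {
    yc <- r - 0.5
    cross <- (y1 <= yc) != (y2 <= yc)
    if (!any(cross)) next
    xi <- x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) / (y2[cross] - y1[cross])
    mask[r, ] <- findInterval(xc, sort(xi)) %% 2 == 1
  }
  mask
}

# Pixels whose centers are within w/2 of any segment of the path.
stroke_mask <- function(v, width, height, stroke_width, closed = FALSE) {
  mask <- matrix(FALSE, height, width)
  half <- stroke_width / 2
  n <- nrow(v)
  segs <- if (closed) cbind(1:n, c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  for (s in seq_len(nrow(segs))) {
    a <- v[segs[s, 1], ]; b <- v[segs[s, 2], ]
    c0 <- max(1L, floor(min(a[1], b[1]) - half + 0.5))
    c1 <- min(width, ceiling(max(a[1], b[1]) + half + 0.5))
    r0 <- max(1L, floor(min(a[2], b[2]) - half + 0.5))
    r1 <- min(height, ceiling(max(a[2], b[2]) + half + 0.5))
    if (c1 < c0 || r1 < r0) next
    xs <- (c0:c1) - 0.5; ys <- (r0:r1) - 0.5
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) 0 else clamp(((px - a[1]) * dx + (py - a[2]) * dy) / len2, 0, 1)
    d2 <- (px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2
    sub <- d2 <= half^2
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | sub
  }
  mask
}

#' Export a binary mask as a single-channel PNG (0/255)
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask > 0, 1, 0), path)
  invisible(NULL)
}

# Read a PNG into an integer H x W x 3 array in [0, 255].
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim(a))
}

write_image_png <- function(pixels, path) {
  png::writePNG(aperm(array(pixels / 255, dim(pixels)), c(1, 2, 3)), path)
  invisible(NULL)
}
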