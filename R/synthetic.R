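#' Synthetic insect images with exact ground truth
#'
#' Draws a stylised mosquito-like insect on a textured background: one dark
#' thorax (compact filled ellipse), one abdomen (elongated ellipse adjoining
#' the thorax along the body axis), 1-2 semi-transparent elongated wings
#' overlapping the abdomen, and 3-6 thin legs (two-jointed polylines, 1-3 px
#' stroke) radiating from the thorax.  Every instance is annotated with the
#' exact polygon/polyline used to render it, so the generator reproduces the
#' statistical structure an anatomy segmenter must cope with -- above all the
#' extreme background-vs-leg pixel imbalance of thin legs inside their
#' bounding boxes -- while remaining fully ground-truthed.
#'
#' @param image_size Square image side in pixels, `>= 64`.
#' @param n_wings Number of wings, 1 or 2.
#' @param n_legs Number of legs, 3 to 6.
#' @param leg_width_px Leg stroke diameter in pixels, in `[1, 3]`.
#' @param body_axis_angle Body axis direction in degrees (0 = rightward).
#' @param color_jitter Fractional per-channel color perturbation.
#' @param background_noise_sd Gaussian noise SD (intensity units, 0-255).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `insect_spec`.
#' @export
insect_spec <- function(image_size = 128, n_wings = 2, n_legs = 6,
                        leg_width_px = 2, body_axis_angle = 0,
                        color_jitter = 0.1, background_noise_sd = 8,
                        seed = 1L) {
  if (image_size < 64) stop("image_size must be at least 64")
  if (!n_wings %in% 1:2) stop("n_wings must be 1 or 2")
  if (!n_legs %in% 3:6) stop("n_legs must be in 3..6")
  if (leg_width_px < 1 || leg_width_px > 3) stop("leg_width_px must be in [1, 3]")
  structure(list(image_size = image_size, n_wings = n_wings, n_legs = n_legs,
                 leg_width_px = leg_width_px,
                 body_axis_angle = body_axis_angle,
                 color_jitter = color_jitter,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "insect_spec")
}

ellipse_poly <- function(center, a, b, angle, n = 28) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  px <- a * cos(t); py <- b * sin(t)
  cbind(center[1] + px * cos(angle) - py * sin(angle),
        center[2] + px * sin(angle) + py * cos(angle))
}

#' Generate one synthetic insect image
#'
#' @param spec An [insect_spec()].
#' @return An [annotated_image()] whose annotation list holds exactly one
#'   `thorax`, one `abdomen`, `n_wings` wing polygons and `n_legs` leg
#'   polylines, consistent with the rendered pixels.
#' @export
generate_insect <- function(spec) {
  stopifnot(inherits(spec, "insect_spec"))
  S <- spec$image_size
  with_seed(spec$seed, {
    th <- spec$body_axis_angle * pi / 180
    u <- c(cos(th), sin(th))
    c0 <- c(S / 2, S / 2) + runif(2, -0.03, 0.03) * S

    jit <- function(n = 1) 1 + runif(n, -0.1, 0.1)
    tc <- c0 + 0.09 * S * u
    ta <- 0.075 * S * jit(); tb <- 0.06 * S * jit()
    thorax_v <- ellipse_poly(tc, ta, tb, th)
    ac <- c0 - 0.10 * S * u
    abdomen_v <- ellipse_poly(ac, 0.14 * S * jit(), 0.058 * S * jit(), th)

    # wings: one per side of the body axis, pointing backwards over the
    # abdomen, attachment offset laterally so the two wing masks stay apart
    perp <- c(-sin(th), cos(th))
    sides <- if (spec$n_wings == 2) c(1, -1) else sample(c(1, -1), 1)
    wings <- lapply(sides, function(sgn) {
      wa <- th + pi + sgn * runif(1, 0.90, 1.15)
      wp <- c0 + sgn * 0.09 * S * perp
      wc <- wp + 0.21 * S * c(cos(wa), sin(wa))
      ellipse_poly(wc, 0.12 * S * jit(), 0.032 * S * jit(), wa)
    })

    # legs: two-jointed polylines fanning out from the thorax; both bends
    # curl in the same rotational sense (away from the body axis) so every
    # leg arcs -- keeping its bounding box compact -- and neighbouring legs
    # on one side stay roughly parallel instead of crossing
    rel <- seq(-2.25, 2.25, length.out = spec$n_legs) +
      runif(spec$n_legs, -0.12, 0.12)
    legs <- lapply(rel, function(ra) {
      ang <- th + ra
      sgn <- if (abs(ra) < 1e-8) sample(c(1, -1), 1) else sign(ra)
      dirs <- ang + sgn * cumsum(c(0, runif(1, 0.5, 0.8), runif(1, 0.45, 0.7)))
      start <- tc + 0.9 * c(ta * cos(ang), tb * sin(ang))
      lens <- runif(3, 0.085, 0.115) * S
      pts <- matrix(start, 1, 2)
      for (s in 1:3)
        pts <- rbind(pts, pts[s, ] + lens[s] * c(cos(dirs[s]), sin(dirs[s])))
      pts
    })

    clampv <- function(v) cbind(clamp(v[, 1], 0, S), clamp(v[, 2], 0, S))
    anns <- c(list(polygon_annotation("thorax", clampv(thorax_v)),
                   polygon_annotation("abdomen", clampv(abdomen_v))),
              lapply(wings, function(v) polygon_annotation("wing", clampv(v))),
              lapply(legs, function(v) polygon_annotation("leg", clampv(v),
                                                          shape = "polyline")))

    # background: low-frequency gradient + Gaussian noise + dark speckle
    # grains (dust/debris), so foreground is not separable by thresholding
    gdir <- runif(2, -1, 1); gamp <- runif(1, 10, 25)
    xs <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE) / S
    ys <- matrix(seq_len(S) - 0.5, S, S) / S
    base <- 195 + gamp * (gdir[1] * xs + gdir[2] * ys)
    tint <- c(4, 0, -4)
    canvas <- array(0, c(S, S, 3))
    for (ch in 1:3)
      canvas[, , ch] <- base + tint[ch] +
        rnorm(S * S, sd = spec$background_noise_sd)
    nspeck <- round(120 * (S / 128)^2)
    sx <- runif(nspeck, 1, S - 1); sy <- runif(nspeck, 1, S - 1)
    sr <- runif(nspeck, 0.4, 1.2)
    sdark <- runif(nspeck, 0.25, 0.65)
    for (k in seq_len(nspeck)) {
      c0s <- max(1, floor(sx[k] - sr[k])); c1s <- min(S, ceiling(sx[k] + sr[k]) + 1)
      r0s <- max(1, floor(sy[k] - sr[k])); r1s <- min(S, ceiling(sy[k] + sr[k]) + 1)
      for (rr in r0s:r1s) for (cc in c0s:c1s) {
        if ((cc - 0.5 - sx[k])^2 + (rr - 0.5 - sy[k])^2 <= sr[k]^2)
          canvas[rr, cc, ] <- canvas[rr, cc, ] * sdark[k]
      }
    }

    cj <- function(col) col * (1 + runif(3, -spec$color_jitter, spec$color_jitter))
    paint <- function(canvas, mask, col, alpha = 1) {
      tex <- rnorm(sum(mask), sd = 5)
      for (ch in 1:3) {
        pl <- canvas[, , ch]
        pl[mask] <- (1 - alpha) * pl[mask] + alpha * (col[ch] + tex)
        canvas[, , ch] <- pl
      }
      canvas
    }

    body_col <- cj(c(72, 54, 38))
    draw_order <- c(2L, 1L, seq(3, 2 + spec$n_wings),
                    seq(3 + spec$n_wings, length(anns)))  # abdomen under thorax
    for (k in draw_order) {
      a <- anns[[k]]
      m <- rasterize(a, S, S, stroke_width = spec$leg_width_px)
      col <- switch(a$label,
                    thorax = body_col * 0.82,
                    abdomen = body_col,
                    wing = cj(c(185, 175, 160)),
                    leg = cj(c(55, 42, 30)))
      alpha <- if (a$label == "wing") 0.4 else 1
      if (a$label == "abdomen") {
        # pale transverse bands, purely cosmetic
        if (runif(1) < 0.5) {
          proj <- (xs * S - ac[1]) * cos(th) + (ys * S - ac[2]) * sin(th)
          band <- m & (sin(proj / (0.03 * S)) > 0.55)
          canvas <- paint(canvas, m, col)
          canvas <- paint(canvas, band, col * 1.7)
          next
        }
      }
      canvas <- paint(canvas, m, col, alpha)
    }
    pixels <- array(as.integer(round(clamp(canvas, 0, 255))), c(S, S, 3))
    annotated_image(sprintf("insect_%010d", spec$seed), S, S, pixels, anns)
  })
}

#' Generate a reproducible dataset of synthetic insects
#'
#' Per-image specs are drawn uniformly from `spec_ranges` under a stream
#' seeded by `seed`; each image gets its own derived seed, so the dataset is
#' reproducible as a whole and image-by-image.
#'
#' @param n Number of images, `>= 1`.
#' @param spec_ranges List of ranges: `n_wings` (integer candidates),
#'   `n_legs` (integer candidates), `leg_width_px` (min/max), plus scalar
#'   `image_size`, `color_jitter`, `background_noise_sd`.
#' @param seed Master seed.
#' @return List of [annotated_image()] objects.
#' @export
generate_dataset <- function(n, spec_ranges = list(), seed = 1L) {
  stopifnot(n >= 1)
  r <- modifyList(list(image_size = 128, n_wings = 1:2, n_legs = 3:6,
                       leg_width_px = c(1, 3), color_jitter = 0.1,
                       background_noise_sd = 8), spec_ranges)
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      insect_spec(image_size = r$image_size,
                  n_wings = sample(r$n_wings, 1),
                  n_legs = sample(r$n_legs, 1),
                  leg_width_px = runif(1, min(r$leg_width_px), max(r$leg_width_px)),
                  body_axis_angle = runif(1, 0, 360),
                  color_jitter = r$color_jitter,
                  background_noise_sd = r$background_noise_sd,
                  seed = sample.int(2147483646, 1))
    })
  })
  imgs <- lapply(specs, generate_insect)
  for (i in seq_along(imgs)) imgs[[i]]$image_id <- sprintf("insect_%04d", i)
  imgs
}

#' Write a synthetic dataset to disk (PNGs + one VIA project)
#'
#' @inheritParams generate_dataset
#' @param out_dir Output directory (created if missing).
#' @param image_size Square image side in pixels.
#' @return Invisibly, the list of generated images.
#' @export
simulate_to_dir <- function(n, image_size = 128, seed = 1L, out_dir,
                            spec_ranges = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec_ranges$image_size <- image_size
  imgs <- generate_dataset(n, spec_ranges, seed)
  for (im in imgs) {
    im$image_id <- paste0(im$image_id, ".png")
    write_image_png(im$pixels, file.path(out_dir, im$image_id))
  }
  for (i in seq_along(imgs)) imgs[[i]]$image_id <- paste0(imgs[[i]]$image_id, ".png")
  write_via(imgs, file.path(out_dir, "annotations.json"))
  invisible(imgs)
}
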