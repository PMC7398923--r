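test_that("the learning-rate schedule keeps its published shape when rescaled", {
  # four phases at epoch fractions 0.2 / 0.4 / 0.8
  expect_equal(schedule_lr(50, 500), 1e-3)
  expect_equal(schedule_lr(150, 500), 5e-4)
  expect_equal(schedule_lr(250, 500), 1e-5)   # fraction 0.5 -> third phase
  expect_equal(schedule_lr(450, 500), 1e-6)
  # desk-scale runs inherit the same fractions
  expect_equal(schedule_lr(25, 50), 1e-5)
  expect_equal(schedule_lr(5, 50), 1e-3)
  expect_equal(schedule_lr(10, 100, lr_scale = 10), 1e-2)
  lr <- vapply(1:100, schedule_lr, 0, total = 100)
  expect_true(all(diff(lr) <= 0))
  expect_true(all(lr > 0))
})

test_that("preprocess rescales pixels and vertices consistently", {
  im <- generate_insect(insect_spec(image_size = 256, seed = 12))
  small <- preprocess(im, 128)
  expect_equal(dim(small$pixels), c(128, 128, 3))
  for (k in seq_along(im$annotations))
    expect_equal(small$annotations[[k]]$vertices,
                 im$annotations[[k]]$vertices / 2)
  expect_identical(preprocess(small, 128), small)
  # mask area scales with the product of the scale factors (convex bodies)
  big_m <- rasterize(im$annotations[[2]], 256, 256)
  small_m <- rasterize(small$annotations[[2]], 128, 128)
  expect_equal(sum(small_m) / sum(big_m), 0.25, tolerance = 0.05)
})

test_that("augmentation flips geometry consistently and never relabels", {
  im <- generate_insect(insect_spec(seed = 13))
  ns <- asNamespace("insectseg")
  fl <- ns$hflip_image(im)
  expect_identical(vapply(fl$annotations, `[[`, "", "label"),
                   vapply(im$annotations, `[[`, "", "label"))
  for (k in seq_along(im$annotations)) {
    expect_equal(fl$annotations[[k]]$vertices[, 1],
                 im$width - im$annotations[[k]]$vertices[, 1])
    expect_equal(fl$annotations[[k]]$vertices[, 2],
                 im$annotations[[k]]$vertices[, 2])
  }
  # involution
  expect_equal(ns$hflip_image(fl)$annotations, im$annotations)
  expect_identical(ns$hflip_image(fl)$pixels, im$pixels)
  # sigma 0 leaves pixels unchanged
  set.seed(1)
  a0 <- augment(im, hflip_probability = 0, blur_sigma_range = c(0, 0))
  expect_identical(a0$pixels, im$pixels)
  set.seed(1)
  ab <- augment(im, hflip_probability = 0, blur_sigma_range = c(1.5, 1.5))
  expect_false(identical(ab$pixels, im$pixels))
  expect_length(ab$annotations, length(im$annotations))
})

test_that("training targets compose rasterization, matching and encoding", {
  im <- generate_insect(insect_spec(seed = 14))
  cfg <- model_config()
  anchors <- make_anchors(cfg$image_size)
  tg <- build_targets(im, anchors)
  expect_equal(length(tg$masks), length(im$annotations))
  expect_equal(nrow(tg$gt_boxes), length(tg$gt_labels))
  # every ground-truth instance trains at least one positive anchor
  pos_gts <- unique(tg$match$gt_index[tg$match$label == "positive"])
  expect_setequal(pos_gts, seq_along(tg$gt_labels))
  # an anchor equal to a gt box is positive with a zero delta
  a2 <- rbind(anchors[, c("x", "y", "w", "h")], tg$gt_boxes[1, ])
  m2 <- match_anchors(a2, tg$gt_boxes)
  k <- nrow(a2)
  expect_equal(as.character(m2$label[k]), "positive")
  expect_equal(unname(unlist(m2$delta[k, ])), c(0, 0, 0, 0))
})

test_that("mask targets of a full-box instance are all ones", {
  ns <- asNamespace("insectseg")
  m <- matrix(FALSE, 64, 64)
  m[11:40, 11:30] <- TRUE
  tgt <- ns$mask_target(m, box(10, 10, 20, 30), 28)
  expect_true(all(tgt))
})

test_that("an image with no annotations yields all-negative targets", {
  px <- array(200L, c(64, 64, 3))
  im <- annotated_image("empty", 64, 64, px)
  anchors <- make_anchors(64)
  expect_message(tg <- build_targets(im, anchors), "all-negative")
  expect_true(all(tg$match$label == "negative"))
})

test_that("short training runs are deterministic and loss decreases", {
  imgs <- generate_dataset(4, list(image_size = 64), seed = 15)
  cfg <- train_config(image_size = 64, epochs = 8, batch_size = 1, seed = 2)
  f1 <- train(imgs, cfg, quiet = TRUE)
  f2 <- train(imgs, cfg, quiet = TRUE)
  expect_equal(f1$log, f2$log, tolerance = 1e-12)
  expect_identical(f1$model$params, f2$model$params)
  expect_lt(mean(tail(f1$log$loss_total, 2)), f1$log$loss_total[1])
  expect_true(all(is.finite(f1$log$loss_total)))
})

test_that("the focal/BCE mask comparison reports both arms' pixel metrics", {
  imgs <- generate_dataset(6, list(leg_width_px = c(1, 2)), seed = 16)
  res <- compare_mask_losses(imgs, epochs = 1, seed = 1)
  expect_equal(res$arm, c("focal", "bce"))
  expect_true(all(res$recall >= 0 & res$recall <= 1))
  expect_true(all(is.na(res$precision) | (res$precision >= 0 & res$precision <= 1)))
})
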