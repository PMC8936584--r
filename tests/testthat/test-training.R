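# Augmentation, splitting, the two-stage protocol, checkpoints.

test_that("augmentation draws stay in range and degenerate to identity", {
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- blob_mask(64, 0.5, 0.5, 0.2, 0.2)
  # all-zero spec is the identity
  set.seed(41)
  a <- augment(img, msk, augmentation_spec(rotation = 0, shift = 0, scales = 1,
                                           hflip = FALSE, vflip = FALSE))
  expect_equal(a$image, img)
  expect_identical(a$mask, msk)
  # a horizontal flip is an involution
  flip_spec <- augmentation_spec(rotation = 0, shift = 0, scales = 1,
                                 hflip = TRUE, vflip = FALSE)
  repeat {
    f1 <- augment(img, msk, flip_spec)
    if (f1$transform$flip[1]) break
  }
  repeat {
    f2 <- augment(f1$image, f1$mask, flip_spec)
    if (f2$transform$flip[1]) break
  }
  expect_equal(f2$image, img, tolerance = 1e-12)
  expect_identical(f2$mask, msk)
  # rotation draws are within [-15, 15] and close to uniform
  set.seed(42)
  angs <- replicate(1000, augment(img, msk)$transform$angle)
  expect_true(all(angs >= -15 & angs <= 15))
  ks <- suppressWarnings(ks.test(angs, "punif", -15, 15))
  expect_gt(ks$p.value, 0.01)
  # identical transform applied to image and mask
  set.seed(43)
  b <- augment(img, msk)
  expect_equal(dim(b$image), dim(img))
  expect_true(all(b$mask %in% c(0L, 1L)))
})

test_that("subject-wise splits are disjoint, sized and reproducible", {
  ds <- generate_dataset("plax", 10, 2, seed = 61, size = 64)
  sp <- split_dataset(ds, c(0.2, 0.6, 0.2), seed = 4)
  subj <- function(x) unique(vapply(x, function(s) s$subject_id, integer(1)))
  expect_length(subj(sp$coarse), 2)
  expect_length(subj(sp$fine), 6)
  expect_length(subj(sp$test), 2)
  expect_length(intersect(subj(sp$coarse), subj(sp$fine)), 0)
  expect_length(intersect(subj(sp$fine), subj(sp$test)), 0)
  sp2 <- split_dataset(ds, c(0.2, 0.6, 0.2), seed = 4)
  expect_identical(lapply(sp, subj), lapply(sp2, subj))
  expect_false(identical(subj(split_dataset(ds, seed = 5)$fine), subj(sp$fine)))
  expect_error(split_dataset(ds[1:2], c(0.2, 0.6, 0.2), seed = 1),
               "cannot fill")
})

test_that("the untrained localizer starts at the identity transform", {
  m <- es_model("plax", size = 64L, crop_size = 32L, seed = 77L)
  z <- matrix(sample(0:5, 64 * 64, TRUE), 64, 64)
  ts <- predict_theta(m, z)
  expect_length(ts, 5L)
  for (th in ts$thetas) {
    v <- theta_vec(th)
    expect_true(all(is.finite(v)))
    expect_lt(max(abs(v - c(1, 1, 0, 0))), 0.05)
    M <- as.matrix(th)
    expect_identical(M[1, 2], 0)      # shear entries are exact zeros
    expect_identical(M[2, 1], 0)
  }
  mi <- es_model("ivc", size = 64L, crop_size = 32L, seed = 77L)
  expect_length(predict_theta(mi, matrix(0L, 64, 64)), 1L)
  expect_error(predict_theta(mi, z), "region count")
})

test_that("localizer pre-training reduces the smooth-L1 parameter error", {
  ds <- generate_dataset("plax", 6, 2, seed = 63, size = 64)
  m <- es_model("plax", size = 64L, crop_size = 32L, seed = 19L)
  cfg <- train_config(batch_size = 4, augment = FALSE, coarse_epochs = 10,
                      loc_epochs = 10, val_frac = 0.2, seed = 7)
  pretrain_coarse(m, ds, cfg)
  init_loss <- {
    errs <- vapply(ds, function(s) {
      smooth_l1(predict_theta(m, coarse_segment(m, s$image)), s$thetas_gt)
    }, numeric(1))
    mean(errs)
  }
  hist <- pretrain_localizer(m, ds, cfg)
  final_loss <- mean(vapply(ds, function(s) {
    smooth_l1(predict_theta(m, coarse_segment(m, s$image)), s$thetas_gt)
  }, numeric(1)))
  expect_lt(final_loss, init_loss)          # descent sanity
  expect_lt(tail(hist$val_loss, 1), hist$val_loss[1])
  expect_error(pretrain_localizer(m, list(), cfg), "empty")
  expect_error(pretrain_coarse(m, list(), cfg), "empty")
})

test_that("training is deterministic given a fixed seed without augmentation", {
  ds <- generate_dataset("plax", 4, 2, seed = 65, size = 64)
  cfg <- train_config(batch_size = 4, augment = FALSE, coarse_epochs = 3,
                      val_frac = 0.25, seed = 13)
  m1 <- es_model("plax", size = 64L, crop_size = 32L, seed = 5L)
  h1 <- pretrain_coarse(m1, ds, cfg)
  m2 <- es_model("plax", size = 64L, crop_size = 32L, seed = 5L)
  h2 <- pretrain_coarse(m2, ds, cfg)
  expect_identical(h1, h2)                 # bitwise-identical loss curves
  z1 <- coarse_segment(m1, ds[[1]]$image)
  z2 <- coarse_segment(m2, ds[[1]]$image)
  expect_identical(z1, z2)
})

test_that("fine-tuning updates everything except anchors and the coarse net", {
  ds <- generate_dataset("plax", 4, 2, seed = 67, size = 64)
  m <- es_model("plax", size = 64L, crop_size = 32L, seed = 3L)
  cfg <- train_config(batch_size = 2, augment = FALSE, seed = 11)
  audit <- grad_flow_audit(m, ds[1:2], cfg)
  expect_equal(audit$n_nonzero_grad, audit$n_learnable)
  expect_length(audit$dead, 0)
  expect_length(audit$frozen_touched, 0)
  # short fine-tuning run decreases the training loss
  cfg2 <- train_config(batch_size = 2, augment = FALSE, epochs = 3,
                       coarse_epochs = 4, loc_epochs = 4, val_frac = 0.25,
                       seed = 11)
  pretrain_coarse(m, ds, cfg2)
  pretrain_localizer(m, ds, cfg2)
  anchors_before <- m$hp$l2$fixed$W$value
  coarse_before <- m$coarse$s1$conv$W$value
  h <- finetune_end_to_end(m, ds, cfg2)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_identical(m$hp$l2$fixed$W$value, anchors_before)
  expect_identical(m$coarse$s1$conv$W$value, coarse_before)
})

test_that("checkpoints round-trip the model bit-for-bit", {
  ds <- generate_dataset("plax", 3, 2, seed = 69, size = 64)
  m <- es_model("plax", size = 64L, crop_size = 32L, seed = 21L)
  cfg <- train_config(batch_size = 3, augment = FALSE, coarse_epochs = 2,
                      loc_epochs = 2, epochs = 1, val_frac = 0.34, seed = 2)
  pretrain_coarse(m, ds, cfg)
  pretrain_localizer(m, ds, cfg)
  finetune_end_to_end(m, ds, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  # same predictions and same next-step loss from the restored model
  expect_identical(predict_mask(m2, ds[[1]]$image),
                   predict_mask(m, ds[[1]]$image))
  g1 <- es$ag_graph()
  l1 <- es$finetune_loss(g1, m, ds[1:2], cfg, training = FALSE)$value
  g2 <- es$ag_graph()
  l2 <- es$finetune_loss(g2, m2, ds[1:2], cfg, training = FALSE)$value
  expect_identical(l1, l2)
})

test_that("pre-training gives fine-tuning a head start over from-scratch", {
  ds <- generate_dataset("plax", 5, 2, seed = 71, size = 64)
  cfg <- train_config(batch_size = 2, augment = FALSE, coarse_epochs = 8,
                      loc_epochs = 8, epochs = 4, val_frac = 0.2, seed = 9)
  heldout <- generate_dataset("plax", 2, 2, seed = 72, size = 64)
  pre <- es_model("plax", size = 64L, crop_size = 32L, seed = 33L)
  pretrain_coarse(pre, ds, cfg)
  pretrain_localizer(pre, ds, cfg)
  finetune_end_to_end(pre, ds, cfg)
  scratch <- es_model("plax", size = 64L, crop_size = 32L, seed = 33L)
  # scratch route: identical fine-tuning budget, no pre-training
  finetune_end_to_end(scratch, ds, cfg)
  expect_gt(evaluate_model(pre, heldout)$mean_iou,
            evaluate_model(scratch, heldout)$mean_iou)
})
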