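# Synthetic echo phantom generator.

test_that("phantoms are deterministic and carry all configured regions", {
  p1 <- generate_phantom("plax", 128, seed = 5)
  p2 <- generate_phantom("plax", 128, seed = 5)
  expect_identical(p1, p2)
  p3 <- generate_phantom("plax", 128, seed = 6)
  expect_false(identical(p1$image, p3$image))
  # plax: exactly 5 non-background labels, each present
  expect_setequal(setdiff(unique(as.integer(p1$mask)), 0L), 1:5)
  expect_true(all(p1$image >= 0 & p1$image <= 1))
  # ivc: single elongated region
  iv <- generate_phantom("ivc", 96, seed = 2)
  expect_setequal(setdiff(unique(as.integer(iv$mask)), 0L), 1L)
  expect_equal(length(iv$thetas_gt), 1L)
  expect_error(generate_phantom("plax", 32, seed = 1), "size")
  # theta_gt is consistent with the mask it was derived from
  for (i in 1:5) {
    th <- p1$thetas_gt$thetas[[i]]
    expect_true(th$s_x > 0 && th$s_x <= 1 && th$s_y > 0 && th$s_y <= 1)
    crop <- crop_mask(p1$mask, th, 64, 64)
    expect_gt(mean(crop == i), mean(p1$mask == i))  # crop concentrates the ROI
  }
})

test_that("datasets have subject structure with within-subject coherence", {
  ds <- generate_dataset("plax", n_subjects = 10, frames_per_subject = 4,
                         seed = 31, size = 64)
  expect_length(ds, 40)
  expect_equal(sort(unique(vapply(ds, function(s) s$subject_id, integer(1)))),
               1:10)
  # frames of one subject are more alike than frames across subjects
  mask_iou <- function(a, b) {
    r <- iou_dice(a$mask, b$mask, 1:5)
    r$mean_iou
  }
  within <- mean(vapply(seq(1, 40, by = 4), function(i)
    mask_iou(ds[[i]], ds[[i + 1]]), numeric(1)))
  between <- mean(vapply(seq(1, 36, by = 4), function(i)
    mask_iou(ds[[i]], ds[[i + 4]]), numeric(1)))
  expect_gt(within, between)
  # ivc mode: every theta set has exactly one region
  di <- generate_dataset("ivc", 3, 2, seed = 8, size = 64)
  expect_true(all(vapply(di, function(s) length(s$thetas_gt), integer(1)) == 1L))
})

test_that("speckle is unit-mean and the wall ribbons stay thin", {
  # unit-mean multiplicative speckle: empirical mean within 2%
  set.seed(77)
  noise <- rgamma(2e5, shape = 4, rate = 4)
  expect_lt(abs(mean(noise) - 1), 0.02)
  # ribbon thickness: measured through the wall along the LV minor axis,
  # SW/PW runs stay <= 8% of the frame height
  size <- 256L
  for (seed in c(9, 10, 11)) {
    p <- generate_phantom("plax", size, seed = seed)
    lv <- p$geometry$LV
    for (lab in c(2L, 3L)) {  # SW above, PW below
      dirsign <- if (lab == 2L) -1 else 1
      tt <- seq(0, 0.6, length.out = 400)
      rr <- round((lv$cy + dirsign * cos(lv$ang) * tt) * size)
      cc <- round((lv$cx - dirsign * sin(lv$ang) * tt) * size)
      ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
      hits <- p$mask[cbind(rr[ok], cc[ok])] == lab
      run <- sum(hits) * 0.6 / 400  # wall extent along the ray (frame units)
      expect_gt(run, 0)
      expect_lte(run, 0.08)
    }
  }
})
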