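# Spatial-transformer geometry: grids, sampling, ground-truth crops, remap.

test_that("sampling grid matches the per-point matrix-multiply oracle", {
  expect_error(make_sampling_grid(affine_theta(1, 1, 0, 0), 0, 5), ">= 1")
  # identity theta reproduces the target grid
  g <- make_sampling_grid(affine_theta(1, 1, 0, 0), 5, 7)
  o <- naive_grid(affine_theta(1, 1, 0, 0), 5, 7)
  expect_identical(g$x_s, o$x_s)
  expect_identical(g$y_s, o$y_s)
  expect_equal(g$x_s[1, 1], -1)
  expect_equal(g$y_s[5, 7], 1)
  # pure translation shifts x only
  gt <- make_sampling_grid(affine_theta(1, 1, 0.5, 0), 5, 7)
  expect_equal(gt$x_s, g$x_s + 0.5)
  expect_identical(gt$y_s, g$y_s)
  # random thetas agree with the oracle
  set.seed(1)
  for (r in 1:10) {
    th <- affine_theta(runif(1, 0.1, 1.2), runif(1, 0.1, 1.2),
                       runif(1, -0.5, 0.5), runif(1, -0.5, 0.5))
    gg <- make_sampling_grid(th, 7, 5)
    oo <- naive_grid(th, 7, 5)
    expect_lt(max(abs(gg$x_s - oo$x_s), abs(gg$y_s - oo$y_s)), 1e-12)
  }
  expect_error(make_sampling_grid(affine_theta(1, 1, 0, 0), 4, NaN))
})

test_that("bilinear sampling reproduces the truncated-kernel sum", {
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  # identity grid at matching resolution is exact
  gid <- make_sampling_grid(affine_theta(1, 1, 0, 0), 8, 8)
  expect_equal(bilinear_sample(img, gid), img)
  # random thetas vs the brute-force double loop
  for (r in 1:10) {
    th <- affine_theta(runif(1, 0.2, 1), runif(1, 0.2, 1),
                       runif(1, -0.4, 0.4), runif(1, -0.4, 0.4))
    gr <- make_sampling_grid(th, 8, 8)
    expect_lt(max(abs(bilinear_sample(img, gr) -
                        naive_bilinear(img, gr$x_s, gr$y_s))), 1e-6)
  }
  # grid fully outside [-1,1] samples zeros
  gout <- make_sampling_grid(affine_theta(1, 1, 4, 4), 8, 8)
  expect_true(all(bilinear_sample(img, gout) == 0))
  # channel handling
  arr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  s3 <- bilinear_sample(arr, gid)
  expect_equal(dim(s3), c(8L, 8L, 3L))
  expect_equal(s3, arr)
  expect_error(bilinear_sample(matrix(c(NA, runif(63)), 8, 8), gid), "non-finite")
})

test_that("sampling is linear in the image and preserves [0,1] bounds", {
  set.seed(3)
  X <- matrix(runif(100), 10, 10)
  Y <- matrix(runif(100), 10, 10)
  for (r in 1:5) {
    th <- affine_theta(runif(1, 0.2, 1.3), runif(1, 0.2, 1.3),
                       runif(1, -0.6, 0.6), runif(1, -0.6, 0.6))
    gr <- make_sampling_grid(th, 6, 9)
    a <- rnorm(1); b <- rnorm(1)
    lhs <- bilinear_sample(a * X + b * Y, gr)
    rhs <- a * bilinear_sample(X, gr) + b * bilinear_sample(Y, gr)
    expect_equal(lhs, rhs, tolerance = 1e-12)
    s <- bilinear_sample(X, gr)
    expect_true(all(s >= 0 & s <= 1 + 1e-12))
  }
})

test_that("sampler gradients w.r.t. theta match finite differences", {
  set.seed(4)
  img <- array(runif(12 * 12), c(12, 12, 1))
  tgt <- array(runif(6 * 6), c(6, 6, 1))
  th <- es$es_param(c(0.62, 0.55, 0.13, -0.21))
  loss_fn <- function() {
    g <- es$ag_graph()
    cr <- es$ag_stn_crop(g, img, es$ag_wrap(g, th), 6, 6)
    l <- es$ag_node(g, sum((cr$value - tgt)^2), list(cr),
                    function(gr) list(2 * (cr$value - tgt) * gr))
    list(g = g, l = l)
  }
  r <- loss_fn()
  es$zero_grads(list(th))
  es$ag_backward(r$g, r$l)
  ana <- th$grad
  eps <- 1e-6
  for (i in 1:4) {
    v0 <- th$value
    th$value[i] <- v0[i] + eps; fp <- loss_fn()$l$value
    th$value[i] <- v0[i] - eps; fm <- loss_fn()$l$value
    th$value[i] <- v0[i]
    expect_lt(abs(ana[i] - (fp - fm) / (2 * eps)), 1e-4)
  }
})

test_that("ground-truth theta crops the expanded bounding box", {
  # region covering the whole frame, margin 0 -> identity
  full <- matrix(1L, 32, 32)
  th <- theta_gt_from_mask(full, 1L, margin = 0)
  expect_equal(theta_vec(th), c(1, 1, 0, 0), ignore_attr = TRUE)
  # left-half rectangle: the crop contains exactly the rectangle
  m <- matrix(0L, 32, 32); m[, 1:16] <- 1L
  th2 <- theta_gt_from_mask(m, 1L, margin = 0)
  crop <- crop_mask(m, th2, 32, 32)
  expect_true(all(crop == 1L))
  expect_equal(th2$s_y, 1)
  expect_lt(abs(th2$s_x - 0.5), 0.05)       # half width up to pixel-center discretization
  expect_lt(abs(th2$t_x + 0.5), 0.05)
  expect_equal(th2$t_y, 0)
  # scales stay in (0, 1] and the margin-0.1 crop contains the margin-0 crop
  blob <- blob_mask(48, 0.4, 0.6, 0.15, 0.2)
  t0 <- theta_gt_from_mask(blob, 1L, margin = 0)
  t1 <- theta_gt_from_mask(blob, 1L, margin = 0.1)
  expect_true(t0$s_x > 0 && t0$s_x <= 1 && t0$s_y > 0 && t0$s_y <= 1)
  # the margin-0.1 footprint contains the margin-0 footprint on every axis
  expect_gte(t1$t_x + t1$s_x, t0$t_x + t0$s_x)
  expect_lte(t1$t_x - t1$s_x, t0$t_x - t0$s_x)
  expect_gte(t1$t_y + t1$s_y, t0$t_y + t0$s_y)
  expect_lte(t1$t_y - t1$s_y, t0$t_y - t0$s_y)
  # the crop concentrates the region relative to the full frame
  c1 <- crop_mask(blob, t1, 48, 48)
  expect_gt(mean(c1 == 1L), mean(blob == 1L))
  expect_error(theta_gt_from_mask(blob, 7L), "absent")
})

test_that("inverse remap restores crops to frame coordinates", {
  # identity theta round trip
  m <- blob_mask(32, 0.5, 0.5, 0.2, 0.3)
  ts <- theta_set(list(affine_theta(1, 1, 0, 0)), 1L)
  expect_identical(inverse_remap(list(m), ts, 32, 32), m)
  # crop-then-remap of a blob keeps IoU >= 0.98
  blob <- blob_mask(96, 0.45, 0.55, 0.18, 0.12)
  tg <- theta_gt_from_mask(blob, 1L, margin = 0.1)
  crop <- crop_mask(blob, tg, 96, 96)
  back <- inverse_remap(list(crop), theta_set(list(tg), 1L), 96, 96)
  ov <- iou_dice(back, blob)
  expect_gte(ov$per_region$iou[1], 0.98)
  # two crops writing disjoint areas produce their union
  m1 <- blob_mask(64, 0.3, 0.3, 0.1, 0.1, 1L)
  m2 <- blob_mask(64, 0.7, 0.7, 0.1, 0.1, 2L)
  t1 <- theta_gt_from_mask(m1, 1L, 0.1)
  t2 <- theta_gt_from_mask(m2, 2L, 0.1)
  crops <- list(crop_mask(m1, t1, 64, 64), crop_mask(m2, t2, 64, 64))
  un <- inverse_remap(crops, theta_set(list(t1, t2), 1:2), 64, 64)
  ov1 <- iou_dice(un, m1 + m2, 1:2)
  expect_gte(min(ov1$per_region$iou), 0.97)
  # singular theta is rejected
  expect_error(
    inverse_remap(list(m), theta_set(list(affine_theta(1e-14, 1, 0, 0)), 1L),
                  32, 32),
    "singular")
})

test_that("theta sets serialize to JSON and back", {
  ts <- theta_set(list(affine_theta(0.5, 0.25, -0.125, 0.375),
                       affine_theta(1, 1, 0, 0)), c(1L, 3L))
  f <- withr::local_tempfile(fileext = ".json")
  write_theta_json(ts, f)
  ts2 <- read_theta_json(f)
  expect_equal(ts2$region_ids, ts$region_ids)
  for (i in 1:2)
    expect_equal(theta_vec(ts2$thetas[[i]]), theta_vec(ts$thetas[[i]]),
                 ignore_attr = TRUE)
  j <- jsonlite::read_json(f)
  expect_equal(j$theta[[1]][[1]][[2]], 0)    # shear stored as exact zero
})
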