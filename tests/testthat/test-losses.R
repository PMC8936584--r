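# Losses and overlap metrics.

test_that("segmentation loss reduces to closed forms", {
  # 1-pixel 2-class uniform logits, true class 0, no auxiliaries: ln 2
  logit1 <- array(0, c(1, 1, 2))
  gt1 <- matrix(0L, 1, 1)
  expect_equal(seg_loss(logit1, NULL, NULL, gt1, loss_config(0, 0)), log(2),
               tolerance = 1e-12)
  # alpha1 = alpha2 = 0 returns the principal loss alone
  set.seed(21)
  Y <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  Y1 <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  Y2 <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  gt <- matrix(sample(0:2, 36, TRUE), 6, 6)
  lp <- seg_loss(Y, Y1, Y2, gt, loss_config(0, 0))
  expect_equal(lp, seg_loss(Y, NULL, NULL, gt, loss_config()))
  # equal to the hand-summed per-pixel oracle with alpha1 = alpha2 = 1
  hand_ce <- function(logits, gt) {
    tot <- 0
    for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
      p <- exp(logits[i, j, ]); p <- p / sum(p)
      tot <- tot - log(p[gt[i, j] + 1])
    }
    tot / length(gt)
  }
  up <- function(l) es$upsample_logits(l, 6, 6)
  expect_lt(abs(seg_loss(Y, Y1, Y2, gt, loss_config(1, 1)) -
                  (hand_ce(Y, gt) + hand_ce(up(Y1), gt) + hand_ce(up(Y2), gt))),
            1e-6)
  # loss is nonnegative and labels out of range are rejected
  expect_gte(lp, 0)
  expect_error(seg_loss(Y, NULL, NULL, matrix(5L, 6, 6), loss_config()),
               "class range")
})

test_that("total loss is the arithmetic mean over regions", {
  expect_equal(total_loss(0.7), 0.7)
  expect_equal(total_loss(c(0.2, 0.4, 0.6, 0.8, 1.0)), 0.6)
  set.seed(22)
  v <- runif(7)
  expect_equal(total_loss(v), total_loss(sample(v)))
  expect_error(total_loss(numeric(0)), "at least one")
  # 1/N Lipschitz in each component
  v2 <- v; v2[3] <- v2[3] + 0.5
  expect_equal(total_loss(v2) - total_loss(v), 0.5 / 7)
})

test_that("smooth-L1 matches both branches and is C1 at |r| = 1", {
  z <- affine_theta(0.5, 0.5, 0, 0)
  expect_equal(smooth_l1(z, z), 0)
  expect_equal(smooth_l1(0.5, 0), 0.125)
  expect_equal(smooth_l1(2, 0), 1.5)
  expect_equal(smooth_l1(1, 0), 0.5)        # both branches agree at r = 1
  expect_equal(smooth_l1(-1, 0), 0.5)
  # one-sided derivatives at |r| = 1 both equal 1
  eps <- 1e-7
  dplus <- (smooth_l1(1 + eps, 0) - smooth_l1(1, 0)) / eps
  dminus <- (smooth_l1(1, 0) - smooth_l1(1 - eps, 0)) / eps
  expect_lt(abs(dplus - 1), 1e-6)
  expect_lt(abs(dminus - 1), 1e-6)
  # theta sets: mean over regions and entries
  a <- theta_set(list(affine_theta(1, 1, 0, 0), affine_theta(0.5, 0.5, 0, 0)), 1:2)
  b <- theta_set(list(affine_theta(1, 1, 0.5, 0), affine_theta(0.5, 0.5, 0, 2)), 1:2)
  expect_equal(smooth_l1(a, b), (0.125 + 1.5) / 8)
  expect_error(smooth_l1(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("IoU and Dice satisfy their identities on masks", {
  # identical masks
  m <- matrix(sample(0:2, 64, TRUE), 8, 8)
  r <- iou_dice(m, m)
  expect_true(all(r$per_region$iou == 1) && all(r$per_region$dice == 1))
  # disjoint equal-area regions
  a <- matrix(0L, 8, 8); a[1:4, ] <- 1L
  b <- matrix(0L, 8, 8); b[5:8, ] <- 1L
  r2 <- iou_dice(a, b, 1L)
  expect_equal(r2$per_region$iou, 0)
  expect_equal(r2$per_region$dice, 0)
  # two equal squares overlapping on half their area: IoU 1/3, Dice 1/2
  p <- matrix(0L, 8, 8); p[1:4, 1:4] <- 1L
  g <- matrix(0L, 8, 8); g[1:4, 3:6] <- 1L
  r3 <- iou_dice(p, g, 1L)
  expect_equal(r3$per_region$iou, 1 / 3)
  expect_equal(r3$per_region$dice, 1 / 2)
  # Dice = 2 IoU / (1 + IoU) on random masks
  set.seed(23)
  for (k in 1:20) {
    pm <- matrix(sample(0:3, 100, TRUE), 10, 10)
    gm <- matrix(sample(0:3, 100, TRUE), 10, 10)
    rr <- iou_dice(pm, gm)
    expect_equal(rr$per_region$dice,
                 2 * rr$per_region$iou / (1 + rr$per_region$iou),
                 tolerance = 1e-12)
    expect_true(all(rr$per_region$iou <= rr$per_region$dice + 1e-12))
  }
  # region absent from gt is skipped; absent from prediction only scores 0
  gt <- matrix(0L, 4, 4); gt[1:2, 1:2] <- 2L
  pred <- matrix(0L, 4, 4); pred[3:4, 3:4] <- 9L
  r4 <- iou_dice(pred, gt, c(2L, 9L))
  expect_equal(r4$per_region$region, 2)
  expect_equal(r4$per_region$iou, 0)
  expect_error(iou_dice(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
})
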