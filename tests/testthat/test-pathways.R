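# Segmentation pathways: spatial, handcrafted (LBC), context, fusion, head.

test_that("spatial pathway obeys the stride/channel contract", {
  m <- tiny_model()
  out <- spatial_path_forward(matrix(runif(128 * 128), 128, 128), m$sp)
  expect_equal(dim(out), c(16L, 16L, 128L))
  out2 <- spatial_path_forward(matrix(runif(64 * 64), 64, 64), m$sp)
  expect_equal(dim(out2), c(8L, 8L, 128L))
  expect_error(spatial_path_forward(matrix(runif(60 * 60), 60, 60), m$sp),
               "divisible by 8")
  # learnable parameter count equals the closed-form conv + BN sum
  got <- es$n_learnable(es$collect_params(m$sp))
  expected <- (9 * 1 * 64 + 2 * 64) + (9 * 64 * 64 + 2 * 64) +
    (9 * 64 * 128 + 2 * 128)
  expect_equal(got, expected)
})

test_that("LBC blocks follow the fixed-anchor + 1x1 recombination formula", {
  set.seed(11)
  spec <- lbc_block_spec(c_in = 2, c_out = 5, k = 3, m = 4, sparsity = 0.5,
                         stride = 2, seed = 3)
  # anchors: nonzeros in {-1, +1}, count set by the sparsity
  anchors <- spec$fixed$W$value
  for (f in 1:4) {
    nz <- anchors[, , , f][anchors[, , , f] != 0]
    expect_equal(length(nz), ceiling(0.5 * 9 * 2))
    expect_true(all(nz %in% c(-1, 1)))
  }
  # zero recombination weights give a zero map
  spec$one$W$value[] <- 0
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  expect_true(all(lbc_block_forward(x, spec) == 0))
  # m = 1 centered identity anchor with v = 1 passes non-negative input through
  id_spec <- lbc_block_spec(c_in = 1, c_out = 1, k = 3, m = 1, stride = 1)
  id_spec$fixed$W$value[] <- 0
  id_spec$fixed$W$value[2, 2, 1, 1] <- 1
  id_spec$one$W$value[] <- 1
  xi <- array(runif(6 * 6), c(6, 6, 1))
  expect_equal(lbc_block_forward(xi, id_spec), xi)
  # random spec agrees with the explicit correlation/ReLU/recombination oracle
  spec2 <- lbc_block_spec(c_in = 3, c_out = 4, k = 3, m = 6, stride = 2, seed = 5)
  x2 <- array(rnorm(9 * 9 * 3), c(9, 9, 3))
  expect_lt(max(abs(lbc_block_forward(x2, spec2) - naive_lbc(x2, spec2))), 1e-5)
  expect_error(lbc_block_forward(array(rnorm(36), c(6, 6, 1)), spec2), "channels")
})

test_that("learnable-parameter counting matches the closed forms", {
  expect_equal(count_learnable_params("standard", 3, 16, 16), 9 * 16 * 16)
  expect_equal(count_learnable_params("lbc", 3, 16, 16, m = 16), 16 * 16)
  for (k in c(1, 3, 5, 7, 9, 11, 13)) {
    for (q in c(3, 16, 64)) {
      r <- count_learnable_params("standard", k, q, q) /
        count_learnable_params("lbc", k, q, q, m = q)
      expect_equal(r, k^2)
    }
  }
  expect_error(count_learnable_params("standard", 4, 8, 8), "odd")
  expect_error(count_learnable_params("lbc", 3, 0, 8), ">= 1")
})

test_that("handcrafted pathway mirrors SP resolution with frozen anchors", {
  m <- tiny_model()
  out <- handcrafted_path_forward(matrix(runif(128 * 128), 128, 128), m$hp)
  expect_equal(dim(out), c(16L, 16L, 128L))
  # anchors unchanged (bitwise) after an optimizer step on the block
  anchors_before <- lapply(list(m$hp$l1, m$hp$l2, m$hp$l3),
                           function(l) l$fixed$W$value)
  ps <- es$collect_params(m$hp)
  g <- es$ag_graph()
  x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  h <- es$hp_forward(g, m$hp, es$ag_leaf(g, x), TRUE)
  loss <- es$ag_node(g, sum(h$value^2), list(h),
                     function(gr) list(2 * h$value * gr))
  es$zero_grads(ps)
  es$ag_backward(g, loss)
  es$opt_step(es$opt_adam(ps))
  anchors_after <- lapply(list(m$hp$l1, m$hp$l2, m$hp$l3),
                          function(l) l$fixed$W$value)
  expect_identical(anchors_before, anchors_after)
  # while the learnable recombination weights received gradient
  expect_true(any(m$hp$l1$one$W$grad != 0))
  # strictly fewer learnable parameters than an SP stack of equal channels
  expect_lt(es$n_learnable(es$collect_params(m$hp)),
            es$n_learnable(es$collect_params(m$sp)))
})

test_that("context pathway pools globally and matches SP spatial dims", {
  m <- tiny_model()
  x <- matrix(runif(64 * 64), 64, 64)
  out <- context_path_forward(x, m$cp)
  sp_out <- spatial_path_forward(x, m$sp)
  expect_equal(dim(out$ctx)[1:2], dim(sp_out)[1:2])
  expect_equal(dim(out$aux1)[1:2], c(4L, 4L))    # 1/16
  expect_equal(dim(out$aux2)[1:2], c(2L, 2L))    # 1/32
  expect_equal(dim(out$aux1)[3], m$n_class)
  expect_error(context_path_forward(matrix(runif(48 * 48), 48, 48), m$cp),
               "divisible by 32")
  # the pooled global descriptor is 1x1: verify via the graph tap
  g <- es$ag_graph()
  r <- es$cp_forward(g, m$cp, es$ag_leaf(g, array(x, c(64, 64, 1, 1))), FALSE)
  expect_equal(dim(r$ctx$value)[1:2], c(8L, 8L))
  # constant input gives a spatially constant interior (shift invariance)
  xc <- matrix(0.6, 256, 256)
  ctx <- context_path_forward(xc, m$cp)$ctx
  interior <- ctx[12:20, 12:20, ]
  expect_lt(max(apply(interior, 3, function(p) diff(range(p)))), 1e-8)
})

test_that("fusion re-weighting follows v*w + v with sigmoid-bounded weights", {
  m <- tiny_model()
  set.seed(12)
  v <- array(runif(4 * 4 * 6), c(4, 4, 6))
  # forced w = 0 and w = 1
  expect_equal(fuse_reweight(v, rep(0, 6)), v)
  expect_equal(fuse_reweight(v, rep(1, 6)), 2 * v)
  # sigmoid weights on non-negative features stay within [v, 2v]
  for (r in 1:100) {
    vv <- array(runif(2 * 3 * 4), c(2, 3, 4))
    w <- 1 / (1 + exp(-rnorm(4, sd = 3)))
    out <- fuse_reweight(vv, w)
    expect_true(all(out >= vv - 1e-12) && all(out <= 2 * vv + 1e-12))
  }
  # full fusion: weight vector in (0,1), output shape preserved, deterministic
  sp_map <- array(runif(8 * 8 * 128), c(8, 8, 128))
  hp_map <- array(runif(8 * 8 * 128), c(8, 8, 128))
  cp_map <- array(runif(8 * 8 * 128), c(8, 8, 128))
  f1 <- fuse(sp_map, hp_map, cp_map, m$fus)
  f2 <- fuse(sp_map, hp_map, cp_map, m$fus)
  expect_true(all(f1$w_concat > 0 & f1$w_concat < 1))
  expect_equal(dim(f1$v_output), dim(f1$v_concat))
  expect_identical(f1$v_output, f2$v_output)
  expect_equal(f1$v_output, f1$v_concat * array(rep(f1$w_concat, each = 64),
                                                dim(f1$v_concat)) + f1$v_concat)
  expect_error(fuse(sp_map, hp_map, cp_map[1:4, 1:4, ], m$fus), "spatial")
})

test_that("segmentation head maps fused features to upsampled logits", {
  set.seed(13)
  head <- es$es_head(256, 2)
  v <- array(rnorm(16 * 16 * 256), c(16, 16, 256))
  logits <- segmentation_head(v, head, 128)
  expect_equal(dim(logits), c(128L, 128L, 2L))
  lab <- es$argmax_labels(logits)
  expect_true(all(lab %in% 0:1))
})
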