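# Independent brute-force oracles and small shared fixtures.

es <- asNamespace("echoseg")
theta_vec <- es$theta_vec
crop_mask <- echoseg::crop_mask

# Eq.-style truncated-kernel bilinear sampling, literal double sum over all
# source pixels (slow; for small images only).
naive_bilinear <- function(image, x_s, y_s) {
  H <- nrow(image); W <- ncol(image)
  out <- matrix(0, nrow(x_s), ncol(x_s))
  for (i in seq_len(nrow(x_s))) {
    for (j in seq_len(ncol(x_s))) {
      # normalized -> 0-based pixel coords (align corners)
      cx <- (x_s[i, j] + 1) / 2 * (W - 1)
      cy <- (y_s[i, j] + 1) / 2 * (H - 1)
      v <- 0
      for (n in 0:(H - 1)) {
        wy <- max(0, 1 - abs(cy - n))
        if (wy == 0) next
        for (m in 0:(W - 1)) {
          wx <- max(0, 1 - abs(cx - m))
          if (wx > 0) v <- v + image[n + 1, m + 1] * wx * wy
        }
      }
      out[i, j] <- v
    }
  }
  out
}

# per-point 2x3 matrix-multiply grid oracle
naive_grid <- function(theta, h, w) {
  M <- as.matrix(theta)
  xt <- if (w == 1) 0 else seq(-1, 1, length.out = w)
  yt <- if (h == 1) 0 else seq(-1, 1, length.out = h)
  xs <- matrix(0, h, w); ys <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      p <- M %*% c(xt[j], yt[i], 1)
      xs[i, j] <- p[1]; ys[i, j] <- p[2]
    }
  }
  list(x_s = xs, y_s = ys)
}

# explicit two-step LBC oracle: correlation loop, ReLU, weighted channel sum
naive_lbc <- function(x, spec) {
  anchors <- spec$fixed$W$value        # [k,k,c_in,m]
  v <- spec$one$W$value                # [1,1,m,c_out]
  k <- spec$k; s <- spec$fixed$stride; p <- spec$fixed$pad
  d <- dim(x)
  Ho <- (d[1] + 2 * p - k) %/% s + 1
  Wo <- (d[2] + 2 * p - k) %/% s + 1
  m <- spec$m
  diff_maps <- array(0, c(Ho, Wo, m))
  for (f in seq_len(m)) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) for (ci in seq_len(d[3])) {
        hi <- (ho - 1) * s - p + kh + 1
        wi <- (wo - 1) * s - p + kw + 1
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          acc <- acc + x[hi, wi, ci] * anchors[kh + 1, kw + 1, ci, f]
      }
      diff_maps[ho, wo, f] <- acc
    }
  }
  bitmaps <- pmax(diff_maps, 0)
  out <- array(0, c(Ho, Wo, spec$c_out))
  for (co in seq_len(spec$c_out)) {
    for (f in seq_len(m)) out[, , co] <- out[, , co] + bitmaps[, , f] * v[1, 1, f, co]
  }
  out
}

# blocky test mask with an ellipse blob
blob_mask <- function(size, cy, cx, a, b, label = 1L) {
  R <- matrix(seq_len(size), size, size) / size
  C <- matrix(rep(seq_len(size), each = size), size, size) / size
  m <- matrix(0L, size, size)
  m[((R - cy) / a)^2 + ((C - cx) / b)^2 <= 1] <- label
  m
}

# memoised tiny fixtures shared across test files
.fixtures <- new.env()

tiny_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- generate_dataset("plax", n_subjects = 6L,
                                     frames_per_subject = 2L, seed = 41L,
                                     size = 64L)
  .fixtures$ds
}

tiny_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- es_model("plax", size = 64L, crop_size = 64L, seed = 9L)
  .fixtures$model
}
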