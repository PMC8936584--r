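# Synthetic echo-phantom generator.
#
# Renders ultrasound-like frames: a dark background with a bright cone-shaped
# imaging sector, dark blood pools with bright walls for the cardiac
# chambers, thin bright ribbons for the septal and posterior walls,
# multiplicative unit-mean gamma speckle, and mild blur. Region geometry is
# parametric with subject-level and frame-level jitter, so frames within a
# subject look like consecutive video frames from one patient. Every sample
# carries its ground-truth label mask and the derived per-region affine
# parameters.

#' Region labels used by the phantom generator
#'
#' @param mode `"ivc"` (single tubular vessel) or `"plax"` (five cardiac
#'   regions: LV, SW, PW, RV, LA).
#' @return Named integer vector mapping region names to mask labels.
#' @export
phantom_labels <- function(mode = c("plax", "ivc")) {
  mode <- match.arg(mode)
  if (mode == "ivc") c(IVC = 1L)
  else c(LV = 1L, SW = 2L, PW = 3L, RV = 4L, LA = 5L)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

ellipse_uv <- function(R, C, cy, cx, a, b, ang) {
  dy <- R - cy; dx <- C - cx
  co <- cos(ang); si <- sin(ang)
  u <- co * dx + si * dy
  v <- -si * dx + co * dy
  (u / b)^2 + (v / a)^2
}

ellipse_vcoord <- function(R, C, cy, cx, ang) {
  dy <- R - cy; dx <- C - cx
  -sin(ang) * dx + cos(ang) * dy
}

# base geometry (fractions of the frame size); jittered per subject/frame
plax_base_params <- function() {
  list(
    cone = list(ay = 0.02, ax = 0.50, half = 0.72, radius = 0.95),
    LV = list(cy = 0.52, cx = 0.40, a = 0.150, b = 0.205, ang = -0.31),
    RV = list(cy = 0.185, cx = 0.52, a = 0.085, b = 0.150, ang = -0.26),
    LA = list(cy = 0.715, cx = 0.635, a = 0.100, b = 0.115, ang = 0.17),
    ring_lo = 1.14, ring_hi = 1.40, rim_hi = 1.11
  )
}

ivc_base_params <- function() {
  list(
    cone = list(ay = 0.02, ax = 0.50, half = 0.72, radius = 0.95),
    tube = list(py = 0.52, px = 0.52, ang = 0.85, halfw = 0.050,
                halflen = 0.34, wallw = 0.030)
  )
}

jitter_params <- function(p, center_sd, size_sd, ang_sd) {
  for (nm in setdiff(names(p), c("cone", "ring_lo", "ring_hi", "rim_hi"))) {
    q <- p[[nm]]
    if (!is.null(q$cy)) {
      q$cy <- q$cy + stats::runif(1, -center_sd, center_sd)
      q$cx <- q$cx + stats::runif(1, -center_sd, center_sd)
      q$a <- q$a * stats::runif(1, 1 - size_sd, 1 + size_sd)
      q$b <- q$b * stats::runif(1, 1 - size_sd, 1 + size_sd)
      q$ang <- q$ang + stats::runif(1, -ang_sd, ang_sd)
    } else {
      q$py <- q$py + stats::runif(1, -center_sd, center_sd)
      q$px <- q$px + stats::runif(1, -center_sd, center_sd)
      q$halfw <- q$halfw * stats::runif(1, 1 - size_sd, 1 + size_sd)
      q$ang <- q$ang + stats::runif(1, -ang_sd, ang_sd)
    }
    p[[nm]] <- q
  }
  p
}

gauss_blur <- function(img, sigma = 0.7) {
  k <- 5L
  xs <- seq(-2, 2)
  g1 <- exp(-xs^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  ker <- array(outer(g1, g1), c(k, k, 1L))
  d <- dim(img)
  out <- cpp_dwconv_fw(array(img, c(d, 1L)), d[1], d[2], 1L, ker, k, 1L, 2L)
  matrix(out, d[1], d[2])
}

render_phantom <- function(mode, size, p, speckle_shape = 4) {
  R <- matrix(seq_len(size), size, size) / size
  C <- matrix(rep(seq_len(size), each = size), size, size) / size
  cn <- p$cone
  dy <- R - cn$ay; dx <- C - cn$ax
  cone <- dy > 0 & abs(atan2(dx, dy)) < cn$half & sqrt(dy^2 + dx^2) < cn$radius
  img <- matrix(0.03, size, size)
  img[cone] <- 0.45
  mask <- matrix(0L, size, size)
  lab <- phantom_labels(mode)
  if (mode == "plax") {
    rho_lv <- ellipse_uv(R, C, p$LV$cy, p$LV$cx, p$LV$a, p$LV$b, p$LV$ang)
    v_lv <- ellipse_vcoord(R, C, p$LV$cy, p$LV$cx, p$LV$ang)
    lv <- rho_lv <= 1 & cone
    ring <- rho_lv > p$ring_lo^2 & rho_lv <= p$ring_hi^2 & cone
    sw <- ring & v_lv < 0
    pw <- ring & v_lv > 0
    rim_lv <- rho_lv > 1 & rho_lv <= p$rim_hi^2 & cone
    rho_rv <- ellipse_uv(R, C, p$RV$cy, p$RV$cx, p$RV$a, p$RV$b, p$RV$ang)
    rho_la <- ellipse_uv(R, C, p$LA$cy, p$LA$cx, p$LA$a, p$LA$b, p$LA$ang)
    taken <- lv | sw | pw
    rv <- rho_rv <= 1 & cone & !taken
    taken <- taken | rv
    la <- rho_la <= 1 & cone & !taken
    rim_rv <- rho_rv > 1 & rho_rv <= 1.2^2 & cone
    rim_la <- rho_la > 1 & rho_la <= 1.2^2 & cone
    img[rim_lv | rim_rv | rim_la] <- 0.78
    img[sw | pw] <- 0.85
    img[lv | rv | la] <- 0.10
    mask[lv] <- lab[["LV"]]; mask[sw] <- lab[["SW"]]; mask[pw] <- lab[["PW"]]
    mask[rv] <- lab[["RV"]]; mask[la] <- lab[["LA"]]
  } else {
    tb <- p$tube
    co <- cos(tb$ang); si <- sin(tb$ang)
    t_along <- co * (R - tb$py) + si * (C - tb$px)
    d_perp <- abs(-si * (R - tb$py) + co * (C - tb$px))
    inlen <- abs(t_along) < tb$halflen
    lumen <- d_perp <= tb$halfw & inlen & cone
    wall <- d_perp > tb$halfw & d_perp <= tb$halfw + tb$wallw & inlen & cone
    img[wall] <- 0.85
    img[lumen] <- 0.08
    mask[lumen] <- lab[["IVC"]]
  }
  noise <- matrix(stats::rgamma(size * size, shape = speckle_shape,
                                rate = speckle_shape), size, size)
  img <- gauss_blur(img * noise)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate one synthetic echo phantom
#'
#' @param mode `"plax"` (5 regions) or `"ivc"` (1 region).
#' @param size Frame side length in pixels (>= 64).
#' @param seed Integer seed; the sample is a deterministic function of
#'   (mode, size, seed).
#' @param speckle_shape Gamma shape of the multiplicative unit-mean speckle.
#' @return A `phantom_sample`: list with `image` (matrix in \[0,1\]), `mask`
#'   (integer label matrix), `thetas_gt` (a [theta_set]), `subject_id`,
#'   `sample_id` and `mode`.
#' @export
generate_phantom <- function(mode = c("plax", "ivc"), size = 128L,
                             seed = 1L, speckle_shape = 4) {
  mode <- match.arg(mode)
  if (size < 64) stop("generate_phantom: size must be >= 64")
  with_seed(seed, {
    p <- if (mode == "plax") plax_base_params() else ivc_base_params()
    p <- jitter_params(p, center_sd = 0.025, size_sd = 0.08, ang_sd = 0.10)
    p <- jitter_params(p, center_sd = 0.008, size_sd = 0.03, ang_sd = 0.035)
    sample_from_params(mode, size, p, speckle_shape,
                       subject_id = 1L, sample_id = 1L)
  })
}

sample_from_params <- function(mode, size, p, speckle_shape, subject_id, sample_id) {
  rp <- render_phantom(mode, size, p, speckle_shape)
  labs <- phantom_labels(mode)
  missing <- labs[!labs %in% unique(as.integer(rp$mask))]
  if (length(missing) > 0)
    stop("phantom: size too small to place region(s) ",
         paste(names(missing), collapse = ", "))
  structure(list(image = rp$image, mask = rp$mask,
                 thetas_gt = theta_gt_set(rp$mask, unname(labs)),
                 subject_id = as.integer(subject_id),
                 sample_id = as.integer(sample_id),
                 mode = mode, geometry = p),
            class = "phantom_sample")
}

#' Generate a phantom dataset with subject structure
#'
#' Frames within a subject share region geometry up to a small frame-to-frame
#' jitter (mimicking consecutive video frames); subjects differ by a larger
#' geometry jitter. Subject ids support subject-wise splitting.
#'
#' @inheritParams generate_phantom
#' @param n_subjects Number of subjects (>= 1).
#' @param frames_per_subject Frames per subject.
#' @return List of `phantom_sample` objects.
#' @export
generate_dataset <- function(mode = c("plax", "ivc"), n_subjects = 10L,
                             frames_per_subject = 4L, seed = 1L,
                             size = 128L, speckle_shape = 4) {
  mode <- match.arg(mode)
  if (n_subjects < 1) stop("generate_dataset: n_subjects must be >= 1")
  with_seed(seed, {
    out <- vector("list", n_subjects * frames_per_subject)
    k <- 0L
    for (s in seq_len(n_subjects)) {
      base <- if (mode == "plax") plax_base_params() else ivc_base_params()
      subj <- jitter_params(base, center_sd = 0.025, size_sd = 0.08, ang_sd = 0.10)
      for (f in seq_len(frames_per_subject)) {
        pf <- jitter_params(subj, center_sd = 0.008, size_sd = 0.03, ang_sd = 0.035)
        k <- k + 1L
        out[[k]] <- sample_from_params(mode, size, pf, speckle_shape,
                                       subject_id = s, sample_id = k)
      }
    }
    out
  })
}
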