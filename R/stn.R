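# Spatial-transformer geometry: affine parameters, sampling grids, bilinear
# sampling, ground-truth crop derivation and inverse remapping.
#
# Normalized coordinates follow the align-corners convention: (-1,-1) is the
# center of the top-left pixel and (+1,+1) the center of the bottom-right
# pixel, so the identity transform is an exact identity map.

#' Per-region affine crop parameters
#'
#' Constructs the restricted 2x3 affine transform used for region cropping:
#' horizontal/vertical scales and translations with shear fixed at zero,
#' \deqn{\theta = \begin{bmatrix} s_x & 0 & t_x \\ 0 & s_y & t_y \end{bmatrix}}
#' in normalized (align-corners) coordinates.
#'
#' @param s_x,s_y Dimensionless scales (crop extent / frame extent).
#' @param t_x,t_y Translations of the crop center in normalized coordinates.
#' @return An object of class `affine_theta`.
#' @export
affine_theta <- function(s_x, s_y, t_x, t_y) {
  v <- c(s_x = s_x, s_y = s_y, t_x = t_x, t_y = t_y)
  if (any(!is.finite(v))) stop("affine_theta: all entries must be finite")
  structure(as.list(v), class = "affine_theta")
}

#' @export
format.affine_theta <- function(x, ...) {
  sprintf("theta(s_x=%.4f, s_y=%.4f, t_x=%.4f, t_y=%.4f)",
          x$s_x, x$s_y, x$t_x, x$t_y)
}

#' @export
print.affine_theta <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
as.matrix.affine_theta <- function(x, ...) {
  matrix(c(x$s_x, 0, 0, x$s_y, x$t_x, x$t_y), 2, 3)
}

theta_vec <- function(theta) c(theta$s_x, theta$s_y, theta$t_x, theta$t_y)

#' Ordered set of per-region affine parameters
#'
#' @param thetas List of [affine_theta], one per region.
#' @param region_ids Positive integer labels; must be unique and ascending.
#' @return An object of class `theta_set`.
#' @export
theta_set <- function(thetas, region_ids) {
  if (length(thetas) != length(region_ids))
    stop("theta_set: thetas and region_ids lengths differ")
  if (is.unsorted(region_ids, strictly = TRUE))
    stop("theta_set: region_ids must be unique and ascending")
  structure(list(thetas = thetas, region_ids = as.integer(region_ids)),
            class = "theta_set")
}

#' @export
length.theta_set <- function(x) length(x$thetas)

#' Build the affine sampling grid for a crop
#'
#' Maps the canonical target grid (H' x W' pixel centers evenly spaced in
#' \[-1, 1\]) through the pointwise affine transform to source coordinates:
#' `x_s = s_x * x_t + t_x`, `y_s = s_y * y_t + t_y`. Source coordinates may
#' fall outside \[-1, 1\]; the sampler zero-pads there.
#'
#' @param theta An [affine_theta].
#' @param h,w Target grid height and width (>= 1).
#' @return A list of class `sampling_grid` with `x_s`, `y_s` (h x w matrices)
#'   and the target dims.
#' @export
make_sampling_grid <- function(theta, h, w) {
  if (h < 1 || w < 1) stop("make_sampling_grid: h and w must be >= 1")
  v <- theta_vec(theta)
  if (any(!is.finite(v))) stop("make_sampling_grid: non-finite theta")
  tg <- target_grid(h, w)
  structure(list(x_s = v[1] * tg$GX + v[3],
                 y_s = v[2] * tg$GY + v[4],
                 h = as.integer(h), w = as.integer(w)),
            class = "sampling_grid")
}

as_hwc <- function(image) {
  if (is.matrix(image)) array(image, c(dim(image), 1L))
  else if (is.array(image) && length(dim(image)) == 3L) image
  else stop("expected an [H,W] matrix or [H,W,C] array")
}

#' Differentiable bilinear sampling of an image through a grid
#'
#' Each output pixel is the truncated-kernel weighted sum
#' `sum_nm I[n,m] * max(0, 1-|x_s-m|) * max(0, 1-|y_s-n|)` over source pixels,
#' so source coordinates outside the image contribute zero. The same kernel
#' (with analytic gradients for both the image and the grid) drives the
#' region crops inside the network.
#'
#' @param image `[H,W]` matrix or `[H,W,C]` array of finite values.
#' @param grid A [sampling_grid].
#' @return Sampled `[h,w,C]` array (a matrix is returned for C = 1 input
#'   matrices).
#' @export
bilinear_sample <- function(image, grid) {
  was_mat <- is.matrix(image)
  x <- as_hwc(image)
  if (any(!is.finite(x))) stop("bilinear_sample: non-finite image")
  d <- dim(x)
  out <- cpp_gs_fw(x, d[1], d[2], d[3],
                   as.numeric(grid$x_s), as.numeric(grid$y_s), grid$h, grid$w)
  if (was_mat) matrix(out, grid$h, grid$w) else out
}

# pixel index (1-based) -> normalized align-corners coordinate
px_to_norm <- function(i, n) {
  if (n == 1) return(rep(0, length(i)))
  -1 + 2 * (i - 1) / (n - 1)
}

#' Ground-truth crop parameters for a labeled region
#'
#' Derives the affine parameters whose crop covers the tight axis-aligned
#' bounding box of `region_id` in the mask, expanded by `margin` of the box
#' extent on each side and clipped to the frame. Scales are the box/frame
#' extent ratios; translations are the normalized box-center offsets.
#'
#' @param gt_mask Integer label matrix (0 = background).
#' @param region_id Positive integer label; must be present in the mask.
#' @param margin Fractional expansion of the box per side (default 0.1).
#' @return An [affine_theta] with `0 < s <= 1`.
#' @export
theta_gt_from_mask <- function(gt_mask, region_id, margin = 0.1) {
  idx <- which(gt_mask == region_id, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("theta_gt_from_mask: region ", region_id, " absent from mask")
  H <- nrow(gt_mask); W <- ncol(gt_mask)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  mr <- margin * (r1 - r0 + 1)
  mc <- margin * (c1 - c0 + 1)
  r0 <- max(1, r0 - mr); r1 <- min(H, r1 + mr)
  c0 <- max(1, c0 - mc); c1 <- min(W, c1 + mc)
  y0 <- px_to_norm(r0, H); y1 <- px_to_norm(r1, H)
  x0 <- px_to_norm(c0, W); x1 <- px_to_norm(c1, W)
  affine_theta(s_x = max((x1 - x0) / 2, 1 / max(W - 1, 1)),
               s_y = max((y1 - y0) / 2, 1 / max(H - 1, 1)),
               t_x = (x1 + x0) / 2,
               t_y = (y1 + y0) / 2)
}

#' Ground-truth parameters for every region of a mask
#'
#' @inheritParams theta_gt_from_mask
#' @param region_ids Integer labels to derive; defaults to all labels present.
#' @return A [theta_set].
#' @export
theta_gt_set <- function(gt_mask, region_ids = NULL, margin = 0.1) {
  if (is.null(region_ids)) {
    region_ids <- sort(setdiff(unique(as.integer(gt_mask)), 0L))
  }
  theta_set(lapply(region_ids, function(r) theta_gt_from_mask(gt_mask, r, margin)),
            region_ids)
}

#' Crop an integer label mask through a region's affine parameters
#'
#' Nearest-neighbour counterpart of [bilinear_sample] for categorical maps.
#'
#' @param mask Integer label matrix.
#' @param theta An [affine_theta].
#' @param h,w Output dims.
#' @param fill Value for out-of-frame samples (default 0).
#' @return Integer `h x w` matrix.
#' @export
crop_mask <- function(mask, theta, h, w, fill = 0L) {
  gr <- make_sampling_grid(theta, h, w)
  out <- cpp_gs_nearest(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                        as.numeric(gr$x_s), as.numeric(gr$y_s), h, w,
                        as.integer(fill))
  matrix(out, h, w)
}

#' Remap per-region crop labels back to frame coordinates
#'
#' Pastes each crop's label map into the frame through the inverse affine of
#' its theta. Pixels claimed by no crop are background (0); pixels claimed by
#' several crops go to the crop whose sampling point lies nearest its crop
#' center (Euclidean distance in crop-normalized coordinates), with ties
#' broken by the lower region id.
#'
#' @param roi_masks List of integer label matrices, one per region crop.
#' @param thetas A [theta_set] (one theta per crop, same order).
#' @param h,w Frame dims.
#' @return Integer `h x w` label matrix.
#' @export
inverse_remap <- function(roi_masks, thetas, h, w) {
  if (length(roi_masks) != length(thetas))
    stop("inverse_remap: one label map per theta required")
  tg <- target_grid(h, w)
  out <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  for (i in seq_along(roi_masks)) {
    th <- thetas$thetas[[i]]
    if (abs(th$s_x) < 1e-12 || abs(th$s_y) < 1e-12)
      stop("inverse_remap: singular theta (zero scale) for region ",
           thetas$region_ids[i])
    xc <- (tg$GX - th$t_x) / th$s_x
    yc <- (tg$GY - th$t_y) / th$s_y
    m <- roi_masks[[i]]
    lab <- matrix(cpp_gs_nearest(matrix(as.integer(m), nrow(m), ncol(m)),
                                 as.numeric(xc), as.numeric(yc),
                                 h, w, 0L), h, w)
    dist <- xc * xc + yc * yc
    take <- lab > 0L & dist < best
    out[take] <- lab[take]
    best[take] <- dist[take]
  }
  out
}

# General affine warp (used by augmentation): A is a 2x3 matrix mapping
# target normalized coords to source normalized coords.
warp_affine <- function(x, A, h = NULL, w = NULL, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (is.null(h)) h <- nrow(x)
  if (is.null(w)) w <- ncol(x)
  tg <- target_grid(h, w)
  xs <- A[1, 1] * tg$GX + A[1, 2] * tg$GY + A[1, 3]
  ys <- A[2, 1] * tg$GX + A[2, 2] * tg$GY + A[2, 3]
  if (interp == "nearest") {
    matrix(cpp_gs_nearest(matrix(as.integer(x), nrow(x), ncol(x)),
                          as.numeric(xs), as.numeric(ys), h, w, 0L), h, w)
  } else {
    xa <- as_hwc(x)
    d <- dim(xa)
    out <- cpp_gs_fw(xa, d[1], d[2], d[3], as.numeric(xs), as.numeric(ys), h, w)
    if (is.matrix(x)) matrix(out, h, w) else out
  }
}

#' Serialize a theta set to JSON
#'
#' Writes the `[N, 2, 3]` row-major matrices alongside the region ids.
#'
#' @param thetas A [theta_set].
#' @param path Output file.
#' @export
write_theta_json <- function(thetas, path) {
  mats <- lapply(thetas$thetas, function(t) {
    list(c(t$s_x, 0, t$t_x), c(0, t$s_y, t$t_y))
  })
  jsonlite::write_json(list(region_ids = thetas$region_ids, theta = mats),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a theta set written by [write_theta_json]
#' @param path JSON file.
#' @return A [theta_set].
#' @export
read_theta_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ths <- lapply(seq_along(j$region_ids), function(i) {
    m <- j$theta[i, , ]
    affine_theta(m[1, 1], m[2, 2], m[1, 3], m[2, 3])
  })
  theta_set(ths, j$region_ids)
}
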