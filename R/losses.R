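# Training losses and overlap metrics.

#' Loss configuration
#'
#' Weights of the two auxiliary deep-supervision terms; both default to 1.
#'
#' @param alpha1,alpha2 Finite real weights.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(alpha1 = 1, alpha2 = 1) {
  if (!is.finite(alpha1) || !is.finite(alpha2))
    stop("loss_config: weights must be finite")
  structure(list(alpha1 = alpha1, alpha2 = alpha2), class = "loss_config")
}

softmax_ce_plain <- function(logits, labels) {
  # mean per-pixel softmax cross-entropy; logits [H,W,C], labels [H,W] in 0..C-1
  d <- dim(logits)
  C <- d[3]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= C)) stop("label outside class range")
  L <- matrix(logits, d[1] * d[2], C)
  m <- L[, 1]
  if (C > 1) for (j in 2:C) m <- pmax(m, L[, j])
  Z <- rowSums(exp(L - m))
  -mean(L[cbind(seq_len(nrow(L)), lab + 1L)] - m - log(Z))
}

upsample_logits <- function(logits, h, w) {
  d <- dim(logits)
  if (d[1] == h && d[2] == w) return(logits)
  array(up_apply(array(logits, c(d, 1L)), interp_matrix(h, d[1]),
                 interp_matrix(w, d[2])), c(h, w, d[3]))
}

#' Segmentation loss with auxiliary deep supervision
#'
#' Mean per-pixel softmax cross-entropy of the principal logits plus the two
#' weighted auxiliary terms from the context pathway:
#' `L = L_p + alpha1 * L_aux1 + alpha2 * L_aux2`. Auxiliary logit maps are
#' bilinearly upsampled to the ground-truth resolution before the loss so the
#' weights are resolution-independent and thin-wall labels are preserved.
#'
#' @param main_logits `[H,W,C]` principal logits.
#' @param aux1,aux2 Auxiliary logit maps (any resolution), or NULL to skip.
#' @param gt_labels `[H,W]` integer labels in `0..C-1`.
#' @param cfg A [loss_config].
#' @return Scalar loss.
#' @export
seg_loss <- function(main_logits, aux1, aux2, gt_labels, cfg = loss_config()) {
  h <- nrow(gt_labels); w <- ncol(gt_labels)
  l <- softmax_ce_plain(main_logits, gt_labels)
  if (!is.null(aux1) && cfg$alpha1 != 0)
    l <- l + cfg$alpha1 * softmax_ce_plain(upsample_logits(aux1, h, w), gt_labels)
  if (!is.null(aux2) && cfg$alpha2 != 0)
    l <- l + cfg$alpha2 * softmax_ce_plain(upsample_logits(aux2, h, w), gt_labels)
  l
}

#' Total loss over regions
#'
#' Arithmetic mean of the per-region segmentation losses.
#'
#' @param per_roi_losses Nonempty numeric vector or list of scalars.
#' @return Scalar mean.
#' @export
total_loss <- function(per_roi_losses) {
  v <- unlist(per_roi_losses)
  if (length(v) == 0) stop("total_loss: at least one per-region loss required")
  mean(v)
}

smooth_l1_elem <- function(r) {
  a <- abs(r)
  ifelse(a < 1, 0.5 * r * r, a - 0.5)
}

#' Smooth-L1 loss between predicted and ground-truth affine parameters
#'
#' Element-wise on the four free entries per region:
#' `0.5 r^2` for `|r| < 1`, `|r| - 0.5` otherwise (continuous with matching
#' one-sided derivatives at `|r| = 1`), averaged over entries and regions.
#'
#' @param theta_pred,theta_gt [theta_set]s (or numeric vectors) of matching
#'   shape.
#' @return Scalar loss.
#' @export
smooth_l1 <- function(theta_pred, theta_gt) {
  as_vec <- function(x) {
    if (inherits(x, "theta_set")) unlist(lapply(x$thetas, theta_vec))
    else if (inherits(x, "affine_theta")) theta_vec(x)
    else as.numeric(x)
  }
  p <- as_vec(theta_pred); q <- as_vec(theta_gt)
  if (length(p) != length(q)) stop("smooth_l1: shape mismatch")
  mean(smooth_l1_elem(p - q))
}

#' Per-region IoU and Dice of a predicted mask
#'
#' For each region id r: `IoU = |P..G| / |P..G|` (intersection over union) and
#' `Dice = 2|P..G| / (|P| + |G|)`. Regions absent from the ground truth are
#' skipped; regions present in the ground truth but absent from the
#' prediction score 0.
#'
#' @param pred_mask,gt_mask Integer label matrices of equal shape.
#' @param region_ids Integer labels to evaluate (default: labels present in
#'   the ground truth).
#' @return A list of class `region_metrics` with `per_region` (data.frame:
#'   region, iou, dice), `mean_iou` and `mean_dice` (means over regions
#'   present in the ground truth).
#' @export
iou_dice <- function(pred_mask, gt_mask, region_ids = NULL) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("iou_dice: masks must share shape")
  if (is.null(region_ids))
    region_ids <- sort(setdiff(unique(as.integer(gt_mask)), 0L))
  rows <- list()
  for (r in region_ids) {
    P <- pred_mask == r
    G <- gt_mask == r
    ng <- sum(G)
    if (ng == 0) next               # absent from ground truth: skipped
    i <- sum(P & G)
    u <- sum(P | G)
    rows[[length(rows) + 1L]] <- data.frame(
      region = r,
      iou = if (u == 0) 0 else i / u,
      dice = if (sum(P) + ng == 0) 0 else 2 * i / (sum(P) + ng))
  }
  per <- if (length(rows)) do.call(rbind, rows)
  else data.frame(region = integer(0), iou = numeric(0), dice = numeric(0))
  structure(list(per_region = per,
                 mean_iou = if (nrow(per)) mean(per$iou) else NA_real_,
                 mean_dice = if (nrow(per)) mean(per$dice) else NA_real_),
            class = "region_metrics")
}

#' @export
print.region_metrics <- function(x, ...) {
  print(x$per_region, row.names = FALSE)
  cat(sprintf("mean IoU %.4f | mean Dice %.4f (background excluded)\n",
              x$mean_iou, x$mean_dice))
  invisible(x)
}
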