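# Two-stage training protocol and evaluation.
#
# Stage 1a: the coarse segmentation net is trained with per-pixel
# cross-entropy. Stage 1b: with the coarse net frozen, the localization net
# is trained to regress the ground-truth crop parameters under smooth-L1.
# Stage 2: everything except the coarse net and the fixed LBC anchors is
# fine-tuned end-to-end against the mean per-region segmentation loss with
# auxiliary deep supervision.

#' Training configuration
#'
#' @param batch_size Minibatch size (frames per optimizer step).
#' @param lr Adam learning rate.
#' @param epochs Fine-tuning epochs.
#' @param coarse_epochs,loc_epochs Epochs for the two pre-training steps.
#' @param steps Optional hard cap on optimizer steps (overrides epochs when
#'   reached; mainly for quick runs).
#' @param seed RNG seed for shuffling, augmentation and initialization.
#' @param val_frac Fraction of training subjects held out for validation
#'   (plateau schedule and best-checkpoint selection).
#' @param augment Apply the augmentation recipe during training.
#' @param margin Ground-truth crop margin per side (fraction of box extent).
#' @param alpha1,alpha2 Auxiliary loss weights.
#' @param theta_loss_weight Weight of the smooth-L1 crop-parameter term kept
#'   in the fine-tuning loss. It anchors the localizer to the ground-truth
#'   boxes during joint training; without it the mean per-pixel loss favors
#'   inflating crops (easy background dilutes hard pixels). The smooth-L1
#'   term is averaged over all `4 N` free entries, which scales its gradient
#'   down by an order of magnitude relative to the segmentation gradient
#'   reaching theta through the sampler; the default of 10 restores
#'   commensurate scales. Set 0 to fine-tune against the segmentation loss
#'   alone.
#' @param plateau_factor,plateau_patience Learning-rate reduction on
#'   validation-loss plateau.
#' @param split Subject-wise split fractions (coarse-train, fine-train, test).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, lr = 1e-3, epochs = 100L,
                         coarse_epochs = 30L, loc_epochs = 30L, steps = NULL,
                         seed = 1L, val_frac = 0.2, augment = TRUE,
                         margin = 0.1, alpha1 = 1, alpha2 = 1,
                         theta_loss_weight = 10,
                         plateau_factor = 0.5, plateau_patience = 5L,
                         split = c(0.2, 0.6, 0.2)) {
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs),
                 coarse_epochs = as.integer(coarse_epochs),
                 loc_epochs = as.integer(loc_epochs), steps = steps,
                 seed = as.integer(seed), val_frac = val_frac,
                 augment = isTRUE(augment), margin = margin,
                 alpha1 = alpha1, alpha2 = alpha2,
                 theta_loss_weight = theta_loss_weight,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 split = split),
            class = "train_config")
}

#' Augmentation specification
#'
#' Defaults follow the training recipe: rotation in \[-15, +15\] degrees,
#' horizontal/vertical shift in \[-0.25, 0.25\] of the frame, scale drawn
#' from \{0.75, 1, 1.25\}, and random horizontal and vertical flips.
#'
#' @param rotation Max absolute rotation (degrees).
#' @param shift Max absolute shift (fraction of the frame side).
#' @param scales Finite set of scale factors.
#' @param hflip,vflip Allow the corresponding flip.
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation = 15, shift = 0.25,
                              scales = c(0.75, 1, 1.25),
                              hflip = TRUE, vflip = TRUE) {
  structure(list(rotation = rotation, shift = shift, scales = scales,
                 hflip = isTRUE(hflip), vflip = isTRUE(vflip)),
            class = "augmentation_spec")
}

#' Randomly augment an aligned image/mask pair
#'
#' Draws one rotation, shift, scale and flip combination from the spec and
#' applies the identical geometric transform to the image (bilinear) and the
#' mask (nearest neighbour). Deterministic given the R RNG state.
#'
#' @param image `[H,W]` matrix.
#' @param mask Integer label matrix aligned with `image`.
#' @param spec An [augmentation_spec].
#' @return List with `image`, `mask` and the drawn `transform`.
#' @export
augment <- function(image, mask, spec = augmentation_spec()) {
  ang <- stats::runif(1, -spec$rotation, spec$rotation) * pi / 180
  dx <- stats::runif(1, -spec$shift, spec$shift)
  dy <- stats::runif(1, -spec$shift, spec$shift)
  s <- spec$scales[sample.int(length(spec$scales), 1L)]
  fx <- if (spec$hflip && stats::runif(1) < 0.5) -1 else 1
  fy <- if (spec$vflip && stats::runif(1) < 0.5) -1 else 1
  M <- diag(c(fx, fy)) %*%
    matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2) / s
  tv <- c(2 * dx, 2 * dy)
  A <- cbind(M, -M %*% tv)
  list(image = warp_affine(image, A, interp = "bilinear"),
       mask = warp_affine(mask, A, interp = "nearest"),
       transform = list(angle = ang * 180 / pi, shift = c(dx, dy),
                        scale = s, flip = c(fx, fy) < 0))
}

#' Subject-wise dataset split
#'
#' Splits samples into coarse-training, fine-training and test sets at the
#' given fractions, keeping all frames of a subject in one split.
#'
#' @param samples List of `phantom_sample` (or any list whose elements have a
#'   `subject_id`).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Split seed.
#' @return List with `coarse`, `fine`, `test` sample lists.
#' @export
split_dataset <- function(samples, fractions = c(0.2, 0.6, 0.2), seed = 1L) {
  subj <- vapply(samples, function(s) s$subject_id, integer(1))
  us <- sort(unique(subj))
  ns <- length(us)
  nsplit <- sum(fractions > 0)
  if (ns < nsplit)
    stop("split_dataset: ", ns, " subject(s) cannot fill ", nsplit, " splits")
  counts <- floor(fractions * ns)
  counts[fractions > 0] <- pmax(counts[fractions > 0], 1L)
  while (sum(counts) > ns) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < ns) {
    frac_part <- fractions * ns - counts
    counts[which.max(frac_part)] <- counts[which.max(frac_part)] + 1L
  }
  perm <- with_seed(seed, sample(us))
  bounds <- cumsum(counts)
  pick <- function(lo, hi) {
    ids <- perm[seq.int(lo, hi)]
    samples[subj %in% ids]
  }
  list(coarse = if (counts[1] > 0) pick(1, bounds[1]) else list(),
       fine = if (counts[2] > 0) pick(bounds[1] + 1, bounds[2]) else list(),
       test = if (counts[3] > 0) pick(bounds[2] + 1, bounds[3]) else list())
}

# ---- shared training helpers --------------------------------------------

val_split <- function(samples, val_frac) {
  subj <- vapply(samples, function(s) s$subject_id, integer(1))
  us <- sort(unique(subj))
  if (length(us) >= 2 && val_frac > 0) {
    nv <- max(1L, round(val_frac * length(us)))
    vids <- us[seq_len(nv)]          # deterministic: lowest subject ids
    list(train = samples[!subj %in% vids], val = samples[subj %in% vids])
  } else {
    list(train = samples, val = samples)
  }
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

images_to_batch <- function(items) {
  d <- dim(items[[1]]$image)
  x <- array(0, c(d[1], d[2], 1L, length(items)))
  for (b in seq_along(items)) x[, , 1L, b] <- items[[b]]$image
  x
}

masks_to_batch <- function(items) {
  d <- dim(items[[1]]$mask)
  y <- array(0L, c(d[1], d[2], length(items)))
  for (b in seq_along(items)) y[, , b] <- items[[b]]$mask
  y
}

maybe_augment <- function(items, cfg, spec) {
  if (!cfg$augment) return(items)
  lapply(items, function(it) {
    a <- augment(it$image, it$mask, spec)
    it$image <- a$image
    it$mask <- a$mask
    it
  })
}

component_state <- function(obj) {
  list(params = lapply(collect_params(obj), function(p) p$value),
       bn = lapply(collect_layers(obj, "bn"), function(l) list(rm = l$rm, rv = l$rv)))
}

restore_component <- function(obj, st) {
  ps <- collect_params(obj)
  stopifnot(length(ps) == length(st$params))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$value) == length(st$params[[i]]))
    ps[[i]]$value <- st$params[[i]]
  }
  bns <- collect_layers(obj, "bn")
  stopifnot(length(bns) == length(st$bn))
  for (i in seq_along(bns)) {
    bns[[i]]$rm <- st$bn[[i]]$rm
    bns[[i]]$rv <- st$bn[[i]]$rv
  }
  invisible(obj)
}

# ---- stage 1a: coarse net pre-training ----------------------------------

#' Pre-train the coarse segmentation network
#'
#' Per-pixel cross-entropy against the ground-truth masks, Adam optimizer,
#' learning rate reduced on validation-loss plateau; the best-validation
#' parameters are restored at the end. The model's coarse net is trained in
#' place.
#'
#' @param model An [es_model].
#' @param samples Nonempty list of `phantom_sample`-like training samples.
#' @param cfg A [train_config] (`coarse_epochs`, `batch_size`, `lr`, ...).
#' @return Invisibly, a data.frame training history (epoch, train/val loss,
#'   lr).
#' @export
pretrain_coarse <- function(model, samples, cfg = train_config()) {
  if (length(samples) == 0) stop("pretrain_coarse: empty training set")
  set.seed(cfg$seed)
  sv <- val_split(samples, cfg$val_frac)
  spec <- augmentation_spec()
  params <- collect_params(model$coarse)
  for (p in params) p$frozen <- FALSE   # stage 1a owns the coarse net
  opt <- opt_adam(params, lr = cfg$lr)
  sched <- plateau_sched(opt, cfg$plateau_factor, cfg$plateau_patience)
  hist <- NULL
  best <- Inf
  best_state <- NULL
  step <- 0L
  val_loss_fn <- function() {
    g <- ag_graph()
    logits <- coarse_forward(g, model$coarse, ag_leaf(g, images_to_batch(sv$val)),
                             training = FALSE)
    ag_softmax_ce(g, logits, masks_to_batch(sv$val))$value
  }
  for (epoch in seq_len(cfg$coarse_epochs)) {
    ord <- sample(length(sv$train))
    tr_losses <- c()
    for (bi in batch_indices(length(ord), cfg$batch_size)) {
      items <- maybe_augment(sv$train[ord[bi]], cfg, spec)
      g <- ag_graph()
      logits <- coarse_forward(g, model$coarse, ag_leaf(g, images_to_batch(items)),
                               training = TRUE)
      loss <- ag_softmax_ce(g, logits, masks_to_batch(items))
      if (!is.finite(loss$value))
        stop("pretrain_coarse: non-finite loss at step ", step,
             " (training diverged)")
      zero_grads(params)
      ag_backward(g, loss)
      opt_step(opt)
      step <- step + 1L
      tr_losses <- c(tr_losses, loss$value)
      if (!is.null(cfg$steps) && step >= cfg$steps) break
    }
    vl <- val_loss_fn()
    sched_step(sched, vl)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(tr_losses),
                                   val_loss = vl, lr = opt$lr))
    if (vl < best) {
      best <- vl
      best_state <- component_state(model$coarse)
    }
    if (!is.null(cfg$steps) && step >= cfg$steps) break
  }
  if (!is.null(best_state)) restore_component(model$coarse, best_state)
  invisible(hist)
}

# ---- stage 1b: localizer pre-training -----------------------------------

loc_targets <- function(items, model, cfg) {
  # [4N, B] matrix of ground-truth (s_x, s_y, t_x, t_y) per region; NULL
  # column marker for samples with a missing region
  n <- model$n_regions
  out <- matrix(NA_real_, 4 * n, length(items))
  for (b in seq_along(items)) {
    tg <- tryCatch(
      theta_gt_set(items[[b]]$mask, seq_len(n), margin = cfg$margin),
      error = function(e) NULL)
    if (is.null(tg)) next
    out[, b] <- unlist(lapply(tg$thetas, theta_vec))
  }
  out
}

#' Pre-train the localization network
#'
#' With the coarse net frozen, the localizer learns to regress the
#' ground-truth crop parameters from the predicted coarse masks under the
#' smooth-L1 loss. Samples whose ground truth lacks a configured region are
#' skipped with a warning.
#'
#' @inheritParams pretrain_coarse
#' @return Invisibly, the training history data.frame.
#' @export
pretrain_localizer <- function(model, samples, cfg = train_config()) {
  if (length(samples) == 0) stop("pretrain_localizer: empty training set")
  set.seed(cfg$seed + 1L)
  sv <- val_split(samples, cfg$val_frac)
  spec <- augmentation_spec()
  params <- collect_params(model$loc)
  opt <- opt_adam(params, lr = cfg$lr)
  sched <- plateau_sched(opt, cfg$plateau_factor, cfg$plateau_patience)
  nc <- model$n_class
  encode <- function(items) {
    zs <- coarse_segment(model, lapply(items, function(it) it$image))
    x <- array(0, c(dim(items[[1]]$image), nc, length(items)))
    for (b in seq_along(zs)) x[, , , b] <- one_hot_mask(zs[[b]], nc)
    x
  }
  # without augmentation the coarse masks and targets are fixed: cache them
  cache <- NULL
  if (!cfg$augment) {
    cache <- list(x = encode(sv$train), t = loc_targets(sv$train, model, cfg))
  }
  val_x <- encode(sv$val)
  val_t <- loc_targets(sv$val, model, cfg)
  hist <- NULL
  best <- Inf
  best_state <- NULL
  step <- 0L
  for (epoch in seq_len(cfg$loc_epochs)) {
    ord <- sample(length(sv$train))
    tr_losses <- c()
    for (bi in batch_indices(length(ord), cfg$batch_size)) {
      if (is.null(cache)) {
        items <- maybe_augment(sv$train[ord[bi]], cfg, spec)
        x <- encode(items)
        tt <- loc_targets(items, model, cfg)
      } else {
        x <- cache$x[, , , ord[bi], drop = FALSE]
        tt <- cache$t[, ord[bi], drop = FALSE]
      }
      keep <- !apply(is.na(tt), 2, any)
      if (!all(keep))
        warning("pretrain_localizer: skipping ", sum(!keep),
                " sample(s) with missing region(s)")
      if (!any(keep)) next
      x <- x[, , , keep, drop = FALSE]
      tt <- tt[, keep, drop = FALSE]
      g <- ag_graph()
      th <- loc_forward(g, model$loc, ag_leaf(g, x), training = TRUE)
      loss <- ag_smooth_l1(g, th, tt)
      if (!is.finite(loss$value))
        stop("pretrain_localizer: non-finite loss (training diverged)")
      zero_grads(params)
      ag_backward(g, loss)
      opt_step(opt)
      step <- step + 1L
      tr_losses <- c(tr_losses, loss$value)
      if (!is.null(cfg$steps) && step >= cfg$steps) break
    }
    gv <- ag_graph()
    vth <- loc_forward(gv, model$loc, ag_leaf(gv, val_x), training = FALSE)
    vkeep <- !apply(is.na(val_t), 2, any)
    vl <- ag_smooth_l1(gv, ag_node(gv, vth$value[, vkeep, drop = FALSE]),
                       val_t[, vkeep, drop = FALSE])$value
    sched_step(sched, vl)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = if (length(tr_losses)) mean(tr_losses) else NA,
                                   val_loss = vl, lr = opt$lr))
    if (vl < best) {
      best <- vl
      best_state <- component_state(model$loc)
    }
    if (!is.null(cfg$steps) && step >= cfg$steps) break
  }
  if (!is.null(best_state)) restore_component(model$loc, best_state)
  invisible(hist)
}

# ---- stage 2: end-to-end fine-tuning ------------------------------------

finetune_params <- function(model) {
  collect_params(list(model$loc, model$sp, model$hp, model$cp,
                      model$fus, model$head))
}

freeze_coarse <- function(model) {
  for (p in collect_params(model$coarse)) p$frozen <- TRUE
  invisible(model)
}

# Build the fine-tuning loss for one batch of frames on graph g.
# Returns the scalar loss node (mean segmentation loss over all region crops,
# each with auxiliary supervision).
finetune_loss <- function(g, model, items, cfg, training = TRUE) {
  B <- length(items)
  n <- model$n_regions
  cs <- model$crop_size
  nc <- model$n_class
  zs <- coarse_segment(model, lapply(items, function(it) it$image))
  xoh <- array(0, c(dim(items[[1]]$image), nc, B))
  for (b in seq_len(B)) xoh[, , , b] <- one_hot_mask(zs[[b]], nc)
  # The localizer keeps its stage-1 normalization statistics during joint
  # training (weights stay trainable): with the small fine-tuning batches,
  # per-batch statistics would make the trained mapping differ from the
  # inference-time mapping and let the inferred crops drift.
  th <- loc_forward(g, model$loc, ag_leaf(g, xoh), training = FALSE)
  crop_nodes <- vector("list", B * n)
  labels <- array(0L, c(cs, cs, B * n))
  k <- 0L
  for (b in seq_len(B)) {
    img <- array(items[[b]]$image, c(dim(items[[b]]$image), 1L))
    for (i in seq_len(n)) {
      rows <- (4 * i - 3):(4 * i)
      tn <- ag_sub(g, th, rows, b)
      k <- k + 1L
      crop_nodes[[k]] <- ag_stn_crop(g, img, tn, cs, cs)
      v <- tn$value
      labels[, , k] <- crop_mask(items[[b]]$mask,
                                 affine_theta(v[1], v[2], v[3], v[4]), cs, cs)
    }
  }
  crops <- ag_stack_b(g, crop_nodes)
  out <- seg_forward(g, model, crops, training)
  loss <- ag_softmax_ce(g, out$main, labels)
  if (cfg$alpha1 != 0)
    loss <- ag_axpy(g, loss,
                    ag_softmax_ce(g, ag_upsample(g, out$aux1, cs, cs), labels),
                    1, cfg$alpha1)
  if (cfg$alpha2 != 0)
    loss <- ag_axpy(g, loss,
                    ag_softmax_ce(g, ag_upsample(g, out$aux2, cs, cs), labels),
                    1, cfg$alpha2)
  if (cfg$theta_loss_weight != 0) {
    targets <- loc_targets(items, model, cfg)
    nav <- is.na(targets)
    if (any(nav)) targets[nav] <- th$value[nav]  # zero residual where no gt box
    loss <- ag_axpy(g, loss, ag_smooth_l1(g, th, targets),
                    1, cfg$theta_loss_weight)
  }
  loss
}

#' Fine-tune the whole network end-to-end
#'
#' Starting from the pre-trained coarse net and localizer, jointly updates
#' the localizer, the three pathways, fusion and head against the mean
#' per-region segmentation loss (principal + auxiliary cross-entropy). The
#' coarse net and the LBC anchor filters stay frozen.
#'
#' @inheritParams pretrain_coarse
#' @return Invisibly, the training history data.frame.
#' @export
finetune_end_to_end <- function(model, samples, cfg = train_config()) {
  if (length(samples) == 0) stop("finetune_end_to_end: empty training set")
  set.seed(cfg$seed + 2L)
  freeze_coarse(model)
  sv <- val_split(samples, cfg$val_frac)
  spec <- augmentation_spec()
  params <- finetune_params(model)
  opt <- opt_adam(params, lr = cfg$lr)
  sched <- plateau_sched(opt, cfg$plateau_factor, cfg$plateau_patience)
  hist <- NULL
  best <- Inf
  best_state <- NULL
  step <- 0L
  parts <- list(model$loc, model$sp, model$hp, model$cp, model$fus, model$head)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(sv$train))
    tr_losses <- c()
    for (bi in batch_indices(length(ord), cfg$batch_size)) {
      items <- maybe_augment(sv$train[ord[bi]], cfg, spec)
      g <- ag_graph()
      loss <- finetune_loss(g, model, items, cfg, training = TRUE)
      if (!is.finite(loss$value))
        stop("finetune_end_to_end: non-finite loss (training diverged)")
      zero_grads(params)
      ag_backward(g, loss)
      opt_step(opt)
      step <- step + 1L
      tr_losses <- c(tr_losses, loss$value)
      if (!is.null(cfg$steps) && step >= cfg$steps) break
    }
    gv <- ag_graph()
    vl <- finetune_loss(gv, model, sv$val, cfg, training = FALSE)$value
    sched_step(sched, vl)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(tr_losses),
                                   val_loss = vl, lr = opt$lr))
    if (vl < best) {
      best <- vl
      best_state <- lapply(parts, component_state)
    }
    if (!is.null(cfg$steps) && step >= cfg$steps) break
  }
  if (!is.null(best_state))
    for (i in seq_along(parts)) restore_component(parts[[i]], best_state[[i]])
  invisible(hist)
}

#' Audit gradient flow through the assembled network
#'
#' Builds the fine-tuning loss on one batch, backpropagates, and reports
#' which parameters received a nonzero gradient. All learnable parameters of
#' the localizer, pathways, fusion and head should; the frozen LBC anchors
#' and coarse net must not.
#'
#' @param model An [es_model] (coarse net should be frozen as in stage 2).
#' @param samples A small list of samples forming one batch.
#' @param cfg A [train_config].
#' @return List with `n_learnable`, `n_nonzero_grad`, `dead` (names of
#'   learnable parameters with zero/absent gradient) and `frozen_touched`.
#' @export
grad_flow_audit <- function(model, samples, cfg = train_config()) {
  freeze_coarse(model)
  all_params <- collect_params(list(model$coarse, model$loc, model$sp, model$hp,
                                    model$cp, model$fus, model$head))
  zero_grads(all_params)
  g <- ag_graph()
  loss <- finetune_loss(g, model, samples, cfg, training = TRUE)
  ag_backward(g, loss)
  learn <- Filter(function(p) !p$frozen, all_params)
  froz <- Filter(function(p) p$frozen, all_params)
  nz <- vapply(learn, function(p) !is.null(p$grad) && any(p$grad != 0), logical(1))
  touched <- vapply(froz, function(p) !is.null(p$grad) && any(p$grad != 0), logical(1))
  list(n_learnable = length(learn), n_nonzero_grad = sum(nz),
       dead = vapply(learn[!nz], function(p) p$name, character(1)),
       frozen_touched = vapply(froz[touched], function(p) p$name, character(1)))
}

# ---- evaluation ----------------------------------------------------------

#' Evaluate a trained model on labeled frames
#'
#' Runs full inference on each sample and scores the remapped predicted mask
#' against the ground truth. Per-frame metrics are averaged over frames, then
#' over regions for the summary means; background is excluded.
#'
#' @param model A trained [es_model].
#' @param samples List of samples with `image` and `mask`.
#' @return List of class `eval_report`: `per_sample` (data.frame: sample_id,
#'   region, iou, dice), `per_region`, `mean_iou`, `mean_dice`.
#' @export
evaluate_model <- function(model, samples) {
  rows <- list()
  for (s in samples) {
    pred <- predict_mask(model, s$image)
    m <- iou_dice(pred, s$mask, seq_len(model$n_regions))
    if (nrow(m$per_region))
      rows[[length(rows) + 1L]] <-
        cbind(sample_id = s$sample_id, m$per_region)
  }
  per_sample <- do.call(rbind, rows)
  per_region <- stats::aggregate(cbind(iou, dice) ~ region, per_sample, mean)
  structure(list(per_sample = per_sample, per_region = per_region,
                 mean_iou = mean(per_region$iou),
                 mean_dice = mean(per_region$dice)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$per_region, row.names = FALSE)
  cat(sprintf("mean IoU %.4f | mean Dice %.4f over %d frames (background excluded)\n",
              x$mean_iou, x$mean_dice, length(unique(x$per_sample$sample_id))))
  invisible(x)
}

# ---- checkpoints ---------------------------------------------------------

#' Save model weights and configuration to a checkpoint file
#'
#' The per-region affine parameters predicted for a reference mask are not
#' stored; weights, batch-norm running statistics and the construction
#' metadata are, so [load_checkpoint] rebuilds an identical model.
#'
#' @param model An [es_model].
#' @param path Output file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  comps <- c("coarse", "loc", "sp", "hp", "cp", "fus", "head")
  state <- lapply(comps, function(nm) component_state(model[[nm]]))
  names(state) <- comps
  saveRDS(list(mode = model$mode, size = model$size,
               crop_size = model$crop_size, c_in = model$c_in,
               meta = model$meta, state = state,
               frozen_coarse = all(vapply(collect_params(model$coarse),
                                          function(p) p$frozen, logical(1)))),
          path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint]
#'
#' @param path Checkpoint file.
#' @return An [es_model] with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- es_model(ck$mode, size = ck$size, crop_size = ck$crop_size,
                    c_in = ck$c_in, anchor_seed = ck$meta$anchor_seed,
                    sparsity = ck$meta$sparsity, seed = ck$meta$init_seed)
  for (nm in names(ck$state)) restore_component(model[[nm]], ck$state[[nm]])
  if (isTRUE(ck$frozen_coarse)) freeze_coarse(model)
  model
}
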