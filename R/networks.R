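# Network definitions: coarse segmentation net (FCN-8 style), localization
# net, the three segmentation pathways (spatial / handcrafted LBC / context),
# channel-attention fusion, and the segmentation head.

# ---- coarse segmentation -------------------------------------------------

# Compact VGG-style encoder with skip fusion from the 1/8, 1/16 and 1/32
# stages; total stride 32, output upsampled back to input resolution.
es_coarse_net <- function(c_in, n_class, widths = c(16, 32, 64, 128, 256)) {
  w <- widths
  new_layer("coarse_net",
            stem = nn_cbr(c_in, w[1], stride = 2, name = "coarse.stem"),
            s1 = nn_cbr(w[1], w[2], stride = 2, name = "coarse.s1"),
            s2 = nn_cbr(w[2], w[3], stride = 2, name = "coarse.s2"),
            s3 = nn_cbr(w[3], w[4], stride = 2, name = "coarse.s3"),
            s4 = nn_cbr(w[4], w[5], stride = 2, name = "coarse.s4"),
            score8 = nn_conv(w[3], n_class, 1, name = "coarse.score8"),
            score16 = nn_conv(w[4], n_class, 1, name = "coarse.score16"),
            score32 = nn_conv(w[5], n_class, 1, name = "coarse.score32"),
            c_in = c_in, n_class = n_class, params = NULL)
}

coarse_forward <- function(g, net, x, training) {
  d <- dim(x$value)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("coarse_forward: resolution must be divisible by 32 (got ",
         d[1], "x", d[2], "); resize the input first")
  h2 <- ly_cbr(g, net$stem, x, training)
  h4 <- ly_cbr(g, net$s1, h2, training)
  h8 <- ly_cbr(g, net$s2, h4, training)
  h16 <- ly_cbr(g, net$s3, h8, training)
  h32 <- ly_cbr(g, net$s4, h16, training)
  f16 <- ag_add(g, ag_upsample(g, ly_conv(g, net$score32, h32),
                               d[1] %/% 16, d[2] %/% 16),
                ly_conv(g, net$score16, h16))
  f8 <- ag_add(g, ag_upsample(g, f16, d[1] %/% 8, d[2] %/% 8),
               ly_conv(g, net$score8, h8))
  ag_upsample(g, f8, d[1], d[2])
}

argmax_labels <- function(logits) {
  # logits [H,W,C] -> integer [H,W] with labels 0..C-1
  d <- dim(logits)
  m <- matrix(logits, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Coarse multi-label segmentation of an echo frame
#'
#' Runs the FCN-8-style coarse network in inference mode and returns the
#' per-pixel argmax label mask `z` that drives the localization network.
#'
#' @param model An [es_model].
#' @param images A single `[H,W]` image matrix (or `echo_image`), or a list
#'   of them (processed as one batch).
#' @return An integer label mask (values in `0..N`), or a list of masks.
#' @export
coarse_segment <- function(model, images) {
  single <- !is.list(images) || inherits(images, "echo_image")
  if (single) images <- list(images)
  imgs <- lapply(images, function(im) {
    if (inherits(im, "echo_image")) im$values else as_hwc(im)
  })
  d <- dim(imgs[[1]])
  g <- ag_graph()
  x <- array(0, c(d[1], d[2], d[3], length(imgs)))
  for (b in seq_along(imgs)) x[, , , b] <- imgs[[b]]
  logits <- coarse_forward(g, model$coarse, ag_leaf(g, x), training = FALSE)
  out <- lapply(seq_along(imgs), function(b)
    argmax_labels(array(logits$value[, , , b], dim(logits$value)[1:3])))
  if (single) out[[1]] else out
}

# ---- localization network ------------------------------------------------

# Eight 3x3 conv+BN+ReLU layers (stride 2 every second layer), global average
# pooling, and a linear head regressing (s_x, s_y, t_x, t_y) per region.
# The head starts near the identity transform (s = 1, t = 0).
es_loc_net <- function(n_class, n_regions,
                       widths = c(16, 16, 32, 32, 64, 64, 128, 128)) {
  blocks <- list()
  cin <- n_class
  for (i in seq_along(widths)) {
    blocks[[i]] <- nn_cbr(cin, widths[i], stride = if (i %% 2 == 0) 2 else 1,
                          name = paste0("loc.b", i))
    cin <- widths[i]
  }
  head <- nn_linear(cin, 4 * n_regions, name = "loc.head", w_sd = 1e-3,
                    bias_init = rep(c(1, 1, 0, 0), n_regions))
  new_layer("loc_net", blocks = blocks, head = head,
            n_regions = n_regions, n_class = n_class,
            s_lo = 0.05, s_hi = 1.5, params = NULL)
}

loc_forward <- function(g, net, x, training) {
  h <- x
  for (bl in net$blocks) h <- ly_cbr(g, bl, h, training)
  th <- ly_linear(g, net$head, ag_gap(g, h))
  n <- net$n_regions
  lo <- rep(c(net$s_lo, net$s_lo, -Inf, -Inf), n)
  hi <- rep(c(net$s_hi, net$s_hi, Inf, Inf), n)
  ag_clamp(g, th, lo, hi)  # [4N, B]: rows (s_x, s_y, t_x, t_y) per region
}

one_hot_mask <- function(mask, n_class) {
  d <- dim(mask)
  oh <- array(0, c(d[1], d[2], n_class))
  v <- as.integer(mask)
  if (any(v < 0L | v >= n_class))
    stop("mask labels outside 0..", n_class - 1)
  for (k in seq_len(n_class)) oh[, , k] <- as.numeric(matrix(v == k - 1L, d[1], d[2]))
  oh
}

#' Regress per-region affine crop parameters from a coarse mask
#'
#' One-hot encodes the coarse mask and runs the localization network in
#' inference mode. Only the four free entries per region are regressed; the
#' shear entries of every returned matrix are exact zeros, and scales are
#' clamped to the valid range.
#'
#' @param model An [es_model].
#' @param coarse An integer coarse label mask (values in `0..N`).
#' @return A [theta_set] of length N (the model's configured region count).
#' @export
predict_theta <- function(model, coarse) {
  nc <- model$n_class
  if (any(!as.integer(coarse) %in% (seq_len(nc) - 1L)))
    stop("predict_theta: coarse mask labels exceed the configured region count")
  g <- ag_graph()
  x <- one_hot_mask(coarse, nc)
  th <- loc_forward(g, model$loc, ag_leaf(g, array(x, c(dim(x), 1L))),
                    training = FALSE)
  v <- as.numeric(th$value)
  theta_set(lapply(seq_len(model$n_regions), function(i) {
    e <- v[(4 * i - 3):(4 * i)]
    affine_theta(e[1], e[2], e[3], e[4])
  }), seq_len(model$n_regions))
}

# ---- spatial pathway -----------------------------------------------------

es_spatial_path <- function(c_in, widths = c(64, 64, 128)) {
  new_layer("spatial_path",
            b1 = nn_cbr(c_in, widths[1], stride = 2, name = "sp.b1"),
            b2 = nn_cbr(widths[1], widths[2], stride = 2, name = "sp.b2"),
            b3 = nn_cbr(widths[2], widths[3], stride = 2, name = "sp.b3"),
            c_in = c_in, c_out = widths[3], params = NULL)
}

sp_forward <- function(g, net, x, training) {
  d <- dim(x$value)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("spatial pathway: input dims must be divisible by 8")
  ly_cbr(g, net$b3, ly_cbr(g, net$b2, ly_cbr(g, net$b1, x, training),
                           training), training)
}

#' Spatial-pathway features for a region crop
#'
#' Three 3x3 stride-2 conv + batch-norm + ReLU blocks with 64, 64 and 128
#' filters; output resolution is 1/8 of the input.
#'
#' @param x `[H,W]` matrix or `[H,W,C]` array (dims divisible by 8).
#' @param net A spatial-pathway network (e.g. `model$sp`).
#' @return Feature array `[H/8, W/8, 128]`.
#' @export
spatial_path_forward <- function(x, net) {
  xa <- as_hwc(x)
  g <- ag_graph()
  out <- sp_forward(g, net, ag_leaf(g, array(xa, c(dim(xa), 1L))), FALSE)
  array(out$value, dim(out$value)[1:3])
}

# ---- handcrafted (LBC) pathway ------------------------------------------

#' Specification of one local-binary-convolution block
#'
#' An LBC block is a fixed sparse "anchor" convolution followed by ReLU and a
#' learnable 1x1 recombination:
#' `y = conv1x1( ReLU( conv_anchor(x) ) )`.
#' The `m` anchor filters are immutable after construction: each has
#' `ceil(sparsity * k^2 * c_in)` nonzero entries drawn from \{-1, +1\};
#' gradients flow through them to earlier layers but never update them. Only
#' the 1x1 recombination weights are learnable.
#'
#' @param c_in,c_out Input/output channels.
#' @param k Odd anchor kernel size.
#' @param m Number of anchor filters (default `2 * c_in`).
#' @param sparsity Fraction of nonzero anchor entries (default 0.5).
#' @param stride Stride of the anchor convolution.
#' @param seed Seed for the stochastic anchor draw (reproducibility).
#' @return An `es_layer` of type `"lbc"`.
#' @export
lbc_block_spec <- function(c_in, c_out, k = 3, m = 2 * c_in, sparsity = 0.5,
                           stride = 1, seed = 1L) {
  if (k %% 2 == 0) stop("lbc_block_spec: kernel size must be odd")
  nnz <- ceiling(sparsity * k * k * c_in)
  anchors <- with_seed(seed, {
    a <- array(0, c(k, k, c_in, m))
    for (i in seq_len(m)) {
      flat <- numeric(k * k * c_in)
      pos <- sample.int(k * k * c_in, nnz)
      flat[pos] <- sample(c(-1, 1), nnz, replace = TRUE)
      a[, , , i] <- flat
    }
    a
  })
  new_layer("lbc",
            fixed = nn_conv(c_in, m, k, stride, bias = FALSE, frozen = TRUE,
                            weight = anchors, name = "lbc.fixed"),
            one = nn_conv(m, c_out, 1, 1, bias = FALSE, name = "lbc.one"),
            c_in = c_in, c_out = c_out, m = m, k = k,
            sparsity = sparsity, nnz = nnz, params = NULL)
}

lbc_fwd <- function(g, spec, x) {
  ly_conv(g, spec$one, ag_relu(g, ly_conv(g, spec$fixed, x)))
}

#' Forward pass of one LBC block
#'
#' @param x `[H,W]` matrix or `[H,W,C]` array with `C = c_in` of the spec.
#' @param spec An [lbc_block_spec].
#' @return Feature array (stride-reduced spatially, `c_out` channels).
#' @export
lbc_block_forward <- function(x, spec) {
  xa <- as_hwc(x)
  if (dim(xa)[3] != spec$c_in)
    stop("lbc_block_forward: input has ", dim(xa)[3],
         " channels, spec expects ", spec$c_in)
  g <- ag_graph()
  out <- lbc_fwd(g, spec, ag_leaf(g, array(xa, c(dim(xa), 1L))))
  array(out$value, dim(out$value)[1:3])
}

#' Learnable-parameter count of a standard conv layer vs an LBC block
#'
#' Standard `k x k` convolution: `k^2 * c_in * c_out` learnable weights. LBC
#' block: the anchors are fixed, so only the `m * c_out` weights of the 1x1
#' recombination are learnable. Biases are excluded in both counts. With
#' `m = c_in` the ratio standard/LBC is exactly `k^2`.
#'
#' @param kind `"standard"` or `"lbc"`.
#' @param k Odd kernel size.
#' @param c_in,c_out Channel counts.
#' @param m Anchor filter count (LBC only).
#' @return Integer parameter count.
#' @export
count_learnable_params <- function(kind = c("standard", "lbc"), k, c_in, c_out,
                                   m = c_in) {
  kind <- match.arg(kind)
  if (k %% 2 == 0 || k < 1) stop("k must be odd and >= 1")
  if (any(c(c_in, c_out, m) < 1)) stop("all counts must be >= 1")
  if (kind == "standard") k * k * c_in * c_out else m * c_out
}

es_handcrafted_path <- function(c_in, widths = c(64, 64, 128), sparsity = 0.5,
                                anchor_seed = 7L) {
  new_layer("handcrafted_path",
            l1 = lbc_block_spec(c_in, widths[1], stride = 2, sparsity = sparsity,
                                seed = anchor_seed),
            n1 = nn_bn(widths[1], name = "hp.bn1"),
            l2 = lbc_block_spec(widths[1], widths[2], stride = 2,
                                sparsity = sparsity, seed = anchor_seed + 1L),
            n2 = nn_bn(widths[2], name = "hp.bn2"),
            l3 = lbc_block_spec(widths[2], widths[3], stride = 2,
                                sparsity = sparsity, seed = anchor_seed + 2L),
            n3 = nn_bn(widths[3], name = "hp.bn3"),
            c_in = c_in, c_out = widths[3], params = NULL)
}

hp_forward <- function(g, net, x, training) {
  d <- dim(x$value)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("handcrafted pathway: input dims must be divisible by 8")
  h <- ag_relu(g, ly_bn(g, net$n1, lbc_fwd(g, net$l1, x), training))
  h <- ag_relu(g, ly_bn(g, net$n2, lbc_fwd(g, net$l2, h), training))
  ag_relu(g, ly_bn(g, net$n3, lbc_fwd(g, net$l3, h), training))
}

#' Handcrafted-pathway features for a region crop
#'
#' Three LBC blocks (stride-2 anchor convolutions, batch-norm + ReLU between
#' blocks) mirroring the spatial pathway's 1/8 output resolution and 128
#' output channels.
#'
#' @inheritParams spatial_path_forward
#' @param net A handcrafted-pathway network (e.g. `model$hp`).
#' @return Feature array `[H/8, W/8, 128]`.
#' @export
handcrafted_path_forward <- function(x, net) {
  xa <- as_hwc(x)
  g <- ag_graph()
  out <- hp_forward(g, net, ag_leaf(g, array(xa, c(dim(xa), 1L))), FALSE)
  array(out$value, dim(out$value)[1:3])
}

# ---- context pathway -----------------------------------------------------

es_context_path <- function(c_in, n_class,
                            widths = c(32, 64, 128, 256, 256), c_out = 128) {
  stages <- list()
  cin <- c_in
  for (i in seq_along(widths)) {
    stages[[i]] <- nn_sep(cin, widths[i], stride = 2, name = paste0("cp.s", i))
    cin <- widths[i]
  }
  new_layer("context_path",
            stages = stages,
            proj = nn_conv(widths[5], c_out, 1, bias = FALSE, name = "cp.proj"),
            proj_bn = nn_bn(c_out, name = "cp.proj_bn"),
            aux1 = nn_conv(widths[4], n_class, 1, name = "cp.aux1"),
            aux2 = nn_conv(widths[5], n_class, 1, name = "cp.aux2"),
            c_in = stages[[1]]$dw$c_in, c_out = c_out, n_class = n_class,
            params = NULL)
}

cp_forward <- function(g, net, x, training) {
  d <- dim(x$value)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("context pathway: input dims must be divisible by 32")
  h <- x
  for (i in 1:3) h <- ly_sep(g, net$stages[[i]], h, training)
  h16 <- ly_sep(g, net$stages[[4]], h, training)
  h32 <- ly_sep(g, net$stages[[5]], h16, training)
  pooled <- ag_gap(g, h32)                      # 1x1 global descriptor [C,B]
  ctx32 <- ag_chanmul(g, h32, pooled)
  ctx <- ag_relu(g, ly_bn(g, net$proj_bn, ly_conv(g, net$proj, ctx32), training))
  ctx8 <- ag_upsample(g, ctx, d[1] %/% 8, d[2] %/% 8)
  list(ctx = ctx8,
       aux1 = ly_conv(g, net$aux1, h16),        # 1/16 class logits
       aux2 = ly_conv(g, net$aux2, h32))        # 1/32 class logits
}

#' Context-pathway features and auxiliary logits for a region crop
#'
#' A lightweight depthwise-separable stack downsamples to 1/32, a global
#' average pool provides a 1x1 global descriptor that re-weights the 1/32
#' map, and the result is projected and upsampled to 1/8 for fusion. The
#' auxiliary outputs are class logits tapped at 1/16 and 1/32 for deep
#' supervision.
#'
#' @inheritParams spatial_path_forward
#' @param net A context-pathway network (e.g. `model$cp`).
#' @return List with `ctx` (`[H/8, W/8, c_out]`), `aux1` (1/16 logits) and
#'   `aux2` (1/32 logits).
#' @export
context_path_forward <- function(x, net) {
  xa <- as_hwc(x)
  g <- ag_graph()
  out <- cp_forward(g, net, ag_leaf(g, array(xa, c(dim(xa), 1L))), FALSE)
  lapply(out, function(nd) array(nd$value, dim(nd$value)[1:3]))
}

# ---- fusion and head -----------------------------------------------------

es_fusion <- function(c_f, bottleneck = c_f %/% 4) {
  new_layer("fusion",
            bn = nn_bn(c_f, name = "fus.bn"),
            fc1 = nn_linear(c_f, bottleneck, name = "fus.fc1"),
            fc2 = nn_linear(bottleneck, c_f, name = "fus.fc2"),
            c_f = c_f, params = NULL)
}

fus_forward <- function(g, net, sp, hp, cp, training) {
  ds <- list(dim(sp$value), dim(hp$value), dim(cp$value))
  if (!identical(ds[[1]][c(1, 2)], ds[[2]][c(1, 2)]) ||
      !identical(ds[[1]][c(1, 2)], ds[[3]][c(1, 2)]))
    stop("fusion: pathway outputs must share spatial dims")
  v <- ly_bn(g, net$bn, ag_concat_c(g, list(sp, hp, cp)), training)
  w <- ag_sigmoid(g, ly_linear(g, net$fc2,
                               ag_relu(g, ly_linear(g, net$fc1, ag_gap(g, v)))))
  vout <- ag_add(g, ag_chanmul(g, v, w), v)
  list(v_concat = v, w_concat = w, v_output = vout)
}

#' Channel-attention re-weighting of concatenated features
#'
#' The fusion combination rule: `v_output = v_concat * w_concat + v_concat`,
#' applied per channel. With sigmoid weights `w` strictly in (0,1), a
#' non-negative `v_concat` satisfies `v <= v_output <= 2v` element-wise.
#'
#' @param v_concat `[H,W,C]` feature array.
#' @param w_concat Length-C weight vector.
#' @return Re-weighted array of the same shape as `v_concat`.
#' @export
fuse_reweight <- function(v_concat, w_concat) {
  d <- dim(v_concat)
  if (length(w_concat) != d[3])
    stop("fuse_reweight: one weight per channel required")
  wexp <- array(rep(w_concat, each = d[1] * d[2]), d)
  v_concat * wexp + v_concat
}

#' Fuse the three pathway outputs
#'
#' Concatenates the pathway feature maps along channels, batch-normalizes to
#' balance their scales, derives per-channel attention weights from a pooled
#' sigmoid bottleneck, and re-weights (see [fuse_reweight]).
#'
#' @param sp_map,hp_map,cp_map `[H,W,C]` feature arrays with equal spatial
#'   dims.
#' @param net A fusion network (e.g. `model$fus`).
#' @return List with `v_concat`, `w_concat` (vector in (0,1)) and `v_output`.
#' @export
fuse <- function(sp_map, hp_map, cp_map, net) {
  g <- ag_graph()
  as_node <- function(a) ag_leaf(g, array(as_hwc(a), c(dim(as_hwc(a)), 1L)))
  out <- fus_forward(g, net, as_node(sp_map), as_node(hp_map), as_node(cp_map),
                     training = FALSE)
  list(v_concat = array(out$v_concat$value, dim(out$v_concat$value)[1:3]),
       w_concat = as.numeric(out$w_concat$value),
       v_output = array(out$v_output$value, dim(out$v_output$value)[1:3]))
}

es_head <- function(c_f, n_class) {
  new_layer("head",
            conv = nn_conv(c_f, n_class, 1, name = "head.conv"),
            n_class = n_class, params = NULL)
}

head_forward <- function(g, net, v, out_h, out_w) {
  ag_upsample(g, ly_conv(g, net$conv, v), out_h, out_w)
}

#' Per-pixel class logits from fused features
#'
#' 1x1 convolution to the class count followed by bilinear upsampling to the
#' output resolution. This head is the only component that depends on the
#' class count downstream of fusion.
#'
#' @param v_output `[H,W,C]` fused feature array.
#' @param net A head network (e.g. `model$head`).
#' @param out_size Output side length.
#' @return Logit array `[out_size, out_size, n_class]`.
#' @export
segmentation_head <- function(v_output, net, out_size) {
  g <- ag_graph()
  va <- as_hwc(v_output)
  out <- head_forward(g, net, ag_leaf(g, array(va, c(dim(va), 1L))),
                      out_size, out_size)
  array(out$value, dim(out$value)[1:3])
}

# ---- full model ----------------------------------------------------------

#' Construct the full localization + segmentation model
#'
#' Assembles the coarse segmentation net, the localization net, the three
#' pathways, fusion and head for a given view configuration. Pathway weights
#' are shared across regions; each region crop is processed independently.
#'
#' @param mode `"plax"` (N = 5 regions) or `"ivc"` (N = 1).
#' @param size Working (square) resolution; must be divisible by 32.
#' @param crop_size Region-crop resolution (default: `size`).
#' @param c_in Input image channels (1 for grayscale echo).
#' @param anchor_seed Seed for the fixed LBC anchor draw.
#' @param sparsity Anchor sparsity of the handcrafted pathway.
#' @param seed Seed for weight initialization.
#' @return An object of class `es_model`.
#' @export
es_model <- function(mode = c("plax", "ivc"), size = 512L, crop_size = size,
                     c_in = 1L, anchor_seed = 7L, sparsity = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (size %% 32 != 0) stop("es_model: size must be divisible by 32")
  if (crop_size %% 32 != 0) stop("es_model: crop_size must be divisible by 32")
  n_regions <- length(phantom_labels(mode))
  n_class <- n_regions + 1L
  with_seed(seed, {
    sp <- es_spatial_path(c_in)
    hp <- es_handcrafted_path(c_in, sparsity = sparsity, anchor_seed = anchor_seed)
    cp <- es_context_path(c_in, n_class)
    c_f <- sp$c_out + hp$c_out + cp$c_out
    m <- list(mode = mode, size = as.integer(size),
              crop_size = as.integer(crop_size),
              c_in = as.integer(c_in),
              n_regions = n_regions, n_class = n_class,
              region_labels = phantom_labels(mode),
              coarse = es_coarse_net(c_in, n_class),
              loc = es_loc_net(n_class, n_regions),
              sp = sp, hp = hp, cp = cp,
              fus = es_fusion(c_f),
              head = es_head(c_f, n_class),
              meta = list(anchor_seed = anchor_seed, sparsity = sparsity,
                          init_seed = seed))
    class(m) <- "es_model"
    m
  })
}

#' @export
print.es_model <- function(x, ...) {
  cat("<es_model>", x$mode, "configuration:", x$n_regions, "region(s),",
      "resolution", x$size, "crop", x$crop_size, "\n")
  np <- function(o) n_learnable(collect_params(o))
  cat(sprintf("  coarse %d | localizer %d | SP %d | HP %d | CP %d | fusion+head %d learnable params\n",
              np(x$coarse), np(x$loc), np(x$sp), np(x$hp), np(x$cp),
              np(x$fus) + np(x$head)))
  invisible(x)
}

# joint pathway forward for a batch of crops [Hc,Wc,C,B]
seg_forward <- function(g, model, crops, training) {
  spo <- sp_forward(g, model$sp, crops, training)
  hpo <- hp_forward(g, model$hp, crops, training)
  cpo <- cp_forward(g, model$cp, crops, training)
  fo <- fus_forward(g, model$fus, spo, hpo, cpo$ctx, training)
  d <- dim(crops$value)
  list(main = head_forward(g, model$head, fo$v_output, d[1], d[2]),
       aux1 = cpo$aux1, aux2 = cpo$aux2)
}

#' Segment one frame end-to-end
#'
#' Full inference pipeline: coarse mask, per-region affine localization,
#' bilinear crop of each region, pathway segmentation of each crop, and
#' inverse remap of the predicted crop labels to frame coordinates.
#'
#' @param model A trained [es_model].
#' @param image `[H,W]` matrix (or `echo_image`) at the model's resolution.
#' @param return_crops If TRUE, also return per-region crops and predictions.
#' @return Integer label mask `[H,W]`, or a list if `return_crops`.
#' @export
predict_mask <- function(model, image, return_crops = FALSE) {
  img <- if (inherits(image, "echo_image")) image$values else as_hwc(image)
  z <- coarse_segment(model, matrix(img[, , 1], dim(img)[1], dim(img)[2]))
  ts <- predict_theta(model, z)
  cs <- model$crop_size
  g <- ag_graph()
  crops <- vector("list", model$n_regions)
  for (i in seq_len(model$n_regions)) {
    grd <- make_sampling_grid(ts$thetas[[i]], cs, cs)
    crops[[i]] <- bilinear_sample(img, grd)
  }
  x <- array(0, c(cs, cs, dim(img)[3], model$n_regions))
  for (i in seq_len(model$n_regions)) x[, , , i] <- crops[[i]]
  out <- seg_forward(g, model, ag_leaf(g, x), training = FALSE)
  roi_masks <- lapply(seq_len(model$n_regions), function(i)
    argmax_labels(array(out$main$value[, , , i], c(cs, cs, model$n_class))))
  full <- inverse_remap(roi_masks, ts, dim(img)[1], dim(img)[2])
  if (return_crops) list(mask = full, thetas = ts, crops = crops,
                         roi_masks = roi_masks, coarse = z)
  else full
}
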