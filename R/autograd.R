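# Minimal reverse-mode differentiation engine.
#
# A graph records operations in creation order; each node is an environment
# holding a value, its parent nodes, and a vector-Jacobian-product closure.
# Feature maps are numeric arrays [H, W, C, B] (height fastest, batch last);
# vectors such as pooled descriptors are [C, B] matrices; losses are scalars.
# Parameters are persistent environments ("es_param") reused across graphs;
# frozen parameters (and every node that depends only on frozen or constant
# inputs) are skipped during the backward sweep, which is how fixed LBC
# anchor filters and the frozen coarse network stay untouched while still
# letting gradients flow through them to upstream nodes.

es_param <- function(value, name = "", frozen = FALSE) {
  p <- new.env(parent = emptyenv())
  p$uid <- .es$param_counter <- get0("param_counter", .es, ifnotfound = 0L) + 1L
  p$value <- value
  p$grad <- NULL
  p$m <- NULL
  p$v <- NULL
  p$frozen <- frozen
  p$name <- name
  class(p) <- "es_param"
  p
}

.es <- new.env(parent = emptyenv())
.es$graph_counter <- 0L

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 64L)
  g$n <- 0L
  .es$graph_counter <- .es$graph_counter + 1L
  g$id <- .es$graph_counter
  class(g) <- "ag_graph"
  g
}

ag_node <- function(g, value, parents = list(), vjp = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  req <- FALSE
  if (!is.null(param)) req <- !param$frozen
  if (!req && length(parents) > 0) {
    for (p in parents) if (p$req) { req <- TRUE; break }
  }
  nd$req <- req
  nd$parents <- if (req) parents else list()
  nd$vjp <- if (req) vjp else NULL
  nd$param <- param
  nd$grad <- NULL
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  g$nodes[[g$n]] <- nd
  nd
}

#' @noRd
ag_leaf <- function(g, value) ag_node(g, value)

# Wrap a persistent parameter into the current graph (memoised per graph).
ag_wrap <- function(g, p) {
  if (!is.null(p$.gid) && identical(p$.gid, g$id)) return(p$.node)
  nd <- ag_node(g, p$value, param = p)
  p$.gid <- g$id
  p$.node <- nd
  nd
}

ag_backward <- function(g, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq.int(g$n, 1L)) {
    nd <- g$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$req) next
      gj <- gs[[j]]
      if (is.null(gj)) next
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
    nd$grad <- NULL  # free
  }
  for (i in seq_len(g$n)) {
    nd <- g$nodes[[i]]
    if (!is.null(nd$param) && !is.null(nd$grad)) {
      pp <- nd$param
      pp$grad <- if (is.null(pp$grad)) nd$grad else pp$grad + nd$grad
    }
  }
  invisible(NULL)
}

# ---- elementwise and shape ops ------------------------------------------

ag_relu <- function(g, x) {
  y <- cpp_relu_fw(x$value)
  ag_node(g, y, list(x), function(gr) {
    list(cpp_relu_bw(y, gr))
  })
}

ag_sigmoid <- function(g, x) {
  y <- 1 / (1 + exp(-x$value))
  ag_node(g, y, list(x), function(gr) list(gr * y * (1 - y)))
}

ag_clamp <- function(g, x, lo, hi) {
  y <- pmin(pmax(x$value, lo), hi)
  inside <- x$value > lo & x$value < hi
  ag_node(g, y, list(x), function(gr) list(gr * inside))
}

ag_add <- function(g, x, y) {
  ag_node(g, x$value + y$value, list(x, y), function(gr) list(gr, gr))
}

ag_axpy <- function(g, x, y, a = 1, b = 1) {
  # a*x + b*y for scalars or same-shaped tensors
  ag_node(g, a * x$value + b * y$value, list(x, y),
          function(gr) list(a * gr, b * gr))
}

ag_concat_c <- function(g, xs) {
  # concatenate [H,W,C,B] maps along the channel dimension
  ds <- lapply(xs, function(x) dim(x$value))
  d1 <- ds[[1]]
  for (d in ds) {
    if (!identical(d[c(1, 2, 4)], d1[c(1, 2, 4)]))
      stop("channel concat: spatial/batch dimensions differ")
  }
  cs <- vapply(ds, function(d) d[3], numeric(1))
  Ct <- sum(cs)
  out <- array(0, c(d1[1], d1[2], Ct, d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  ag_node(g, out, xs, function(gr) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      gi <- gr[, , at + seq_len(cs[i]), , drop = FALSE]
      dim(gi) <- c(d1[1], d1[2], cs[i], d1[4])
      res[[i]] <- gi
      at <- at + cs[i]
    }
    res
  })
}

ag_stack_b <- function(g, xs) {
  # stack single-sample [H,W,C] maps into a [H,W,C,B] batch
  d <- dim(xs[[1]]$value)
  B <- length(xs)
  out <- array(0, c(d, B))
  for (i in seq_len(B)) out[, , , i] <- xs[[i]]$value
  ag_node(g, out, xs, function(gr) {
    lapply(seq_len(B), function(i) array(gr[, , , i], d))
  })
}

ag_sub <- function(g, x, rows, col) {
  # slice rows of one column of a [R,B] matrix node -> vector node
  v <- x$value[rows, col]
  d <- dim(x$value)
  ag_node(g, v, list(x), function(gr) {
    gx <- matrix(0, d[1], d[2])
    gx[rows, col] <- gr
    list(gx)
  })
}

ag_rows <- function(g, x, rows) {
  # slice rows of a [R,B] matrix node
  v <- x$value[rows, , drop = FALSE]
  d <- dim(x$value)
  ag_node(g, v, list(x), function(gr) {
    gx <- matrix(0, d[1], d[2])
    gx[rows, ] <- gr
    list(gx)
  })
}

# ---- pooling / resampling -----------------------------------------------

ag_gap <- function(g, x) {
  # global average pool [H,W,C,B] -> [C,B]
  d <- dim(x$value)
  n <- d[1] * d[2]
  y <- matrix(.colSums(matrix(x$value, n, d[3] * d[4]), n, d[3] * d[4]) / n,
              d[3], d[4])
  ag_node(g, y, list(x), function(gr) {
    gx <- array(rep(as.numeric(gr), each = n) / n, d)
    list(gx)
  })
}

ag_chanmul <- function(g, x, w) {
  # multiply [H,W,C,B] map by per-(channel,batch) weights [C,B]
  d <- dim(x$value)
  n <- d[1] * d[2]
  wexp <- array(rep(as.numeric(w$value), each = n), d)
  ag_node(g, x$value * wexp, list(x, w), function(gr) {
    gx <- gr * wexp
    gw <- matrix(.colSums(matrix(gr * x$value, n, d[3] * d[4]), n, d[3] * d[4]),
                 d[3], d[4])
    list(gx, gw)
  })
}

interp_matrix <- function(n_out, n_in) {
  # align-corners linear interpolation matrix [n_out, n_in]
  U <- matrix(0, n_out, n_in)
  if (n_in == 1) { U[, 1] <- 1; return(U) }
  pos <- if (n_out == 1) 0 else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(pos), n_in - 2)
  f <- pos - i0
  for (r in seq_len(n_out)) {
    U[r, i0[r] + 1] <- 1 - f[r]
    U[r, i0[r] + 2] <- U[r, i0[r] + 2] + f[r]
  }
  U
}

up_apply <- function(x, Uh, Uw) {
  d <- dim(x)
  Ho <- nrow(Uh); Wo <- nrow(Uw)
  y <- Uh %*% matrix(x, d[1], d[2] * d[3] * d[4])
  dim(y) <- c(Ho, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  y <- Uw %*% matrix(y, d[2], Ho * d[3] * d[4])
  dim(y) <- c(Wo, Ho, d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

ag_upsample <- function(g, x, Ho, Wo) {
  d <- dim(x$value)
  Uh <- interp_matrix(Ho, d[1])
  Uw <- interp_matrix(Wo, d[2])
  y <- up_apply(x$value, Uh, Uw)
  ag_node(g, y, list(x), function(gr) {
    list(up_apply(gr, t(Uh), t(Uw)))
  })
}

# ---- dense / conv layers (parameter-consuming ops live in layers.R) -----

ag_matmul_linear <- function(g, W, x, b = NULL) {
  # W [Cout,Cin] %*% x [Cin,B] (+ b)
  y <- W$value %*% x$value
  if (!is.null(b)) y <- y + b$value
  parents <- if (is.null(b)) list(W, x) else list(W, x, b)
  ag_node(g, y, parents, function(gr) {
    gW <- gr %*% t(x$value)
    gx <- crossprod(W$value, gr)
    if (is.null(b)) list(gW, gx) else list(gW, gx, rowSums(gr))
  })
}

# ---- losses --------------------------------------------------------------

ag_softmax_ce <- function(g, logits, labels) {
  # logits [H,W,C,B]; labels integer array [H,W,B] with values in 0..C-1
  d <- dim(logits$value)
  C <- d[3]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= C)) stop("label outside class range")
  hw <- d[1] * d[2]
  loss <- cpp_ce_fw(logits$value, hw, C, d[4], lab)
  ag_node(g, loss, list(logits), function(gr) {
    list(cpp_ce_bw(logits$value, hw, C, d[4], lab, gr))
  })
}

ag_smooth_l1 <- function(g, pred, target) {
  r <- pred$value - target
  a <- abs(r)
  quad <- a < 1
  v <- mean(ifelse(quad, 0.5 * r * r, a - 0.5))
  n <- length(r)
  ag_node(g, v, list(pred), function(gr) {
    gp <- ifelse(quad, r, sign(r)) * (gr / n)
    dim(gp) <- dim(pred$value)
    list(gp)
  })
}

# ---- spatial transformer crop -------------------------------------------

target_grid <- function(Hp, Wp) {
  xt <- if (Wp == 1) 0 else seq(-1, 1, length.out = Wp)
  yt <- if (Hp == 1) 0 else seq(-1, 1, length.out = Hp)
  list(GX = matrix(rep(xt, each = Hp), Hp, Wp),
       GY = matrix(rep(yt, Wp), Hp, Wp))
}

ag_stn_crop <- function(g, img, theta, Hp, Wp) {
  # img: plain [H,W,C] array (network input; no gradient needed);
  # theta: node holding (s_x, s_y, t_x, t_y); output node [Hp,Wp,C].
  d <- dim(img)
  tg <- target_grid(Hp, Wp)
  th <- as.numeric(theta$value)
  gx <- th[1] * tg$GX + th[3]
  gy <- th[2] * tg$GY + th[4]
  out <- cpp_gs_fw(img, d[1], d[2], d[3], as.numeric(gx), as.numeric(gy), Hp, Wp)
  ag_node(g, out, list(theta), function(gr) {
    bw <- cpp_gs_bw(img, d[1], d[2], d[3], as.numeric(gx), as.numeric(gy),
                    Hp, Wp, as.numeric(gr))
    gth <- c(sum(bw$ggx * tg$GX), sum(bw$ggy * tg$GY),
             sum(bw$ggx), sum(bw$ggy))
    dim(gth) <- dim(theta$value)
    list(gth)
  })
}
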