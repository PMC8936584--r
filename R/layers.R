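# Layer constructors and their forward passes on the autograd graph.
# A layer is an environment of class "es_layer" with a $params list; batch
# normalisation additionally keeps running statistics as plain state.

new_layer <- function(type, ...) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = ly)
  class(ly) <- "es_layer"
  ly
}

he_init <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

nn_conv <- function(c_in, c_out, k = 3, stride = 1, pad = (k - 1) %/% 2,
                    bias = TRUE, frozen = FALSE, weight = NULL, name = "conv") {
  W <- if (is.null(weight)) {
    array(he_init(k * k * c_in * c_out, k * k * c_in), c(k, k, c_in, c_out))
  } else weight
  Wp <- es_param(W, paste0(name, ".W"), frozen = frozen)
  bp <- if (bias) es_param(numeric(c_out), paste0(name, ".b"), frozen = frozen) else NULL
  ps <- if (bias) list(Wp, bp) else list(Wp)
  new_layer("conv", W = Wp, b = bp, k = k, stride = stride, pad = pad,
            c_in = c_in, c_out = c_out, params = ps)
}

ly_conv <- function(g, ly, x) {
  d <- dim(x$value)
  if (d[3] != ly$c_in) stop("conv: expected ", ly$c_in, " input channels, got ", d[3])
  k <- ly$k; s <- ly$stride; p <- ly$pad
  Ho <- (d[1] + 2 * p - k) %/% s + 1
  Wo <- (d[2] + 2 * p - k) %/% s + 1
  B <- d[4]
  Wm <- matrix(ly$W$value, k * k * ly$c_in, ly$c_out)
  out <- array(0, c(Ho, Wo, ly$c_out, B))
  for (b in seq_len(B)) {
    cols <- cpp_im2col(x$value[, , , b], d[1], d[2], d[3], k, s, p)
    yb <- crossprod(cols, Wm)                    # [Ho*Wo, Cout]
    if (!is.null(ly$b)) yb <- yb + rep(ly$b$value, each = Ho * Wo)
    out[, , , b] <- yb
  }
  Wn <- ag_wrap(g, ly$W)
  parents <- list(Wn, x)
  if (!is.null(ly$b)) parents <- c(parents, list(ag_wrap(g, ly$b)))
  need_gw <- !ly$W$frozen
  ag_node(g, out, parents, function(gr) {
    gW <- if (need_gw) matrix(0, k * k * ly$c_in, ly$c_out) else NULL
    gx <- if (x$req) array(0, d) else NULL
    gb <- if (!is.null(ly$b)) numeric(ly$c_out) else NULL
    for (b in seq_len(B)) {
      G <- matrix(gr[, , , b], Ho * Wo, ly$c_out)
      if (need_gw || x$req)
        cols <- cpp_im2col(x$value[, , , b], d[1], d[2], d[3], k, s, p)
      if (need_gw) gW <- gW + cols %*% G
      if (x$req) {
        gcols <- Wm %*% t(G)
        gx[, , , b] <- cpp_col2im(gcols, d[1], d[2], d[3], k, s, p)
      }
      if (!is.null(gb)) gb <- gb + .colSums(G, Ho * Wo, ly$c_out)
    }
    if (!is.null(gW)) dim(gW) <- c(k, k, ly$c_in, ly$c_out)
    if (is.null(ly$b)) list(gW, gx) else list(gW, gx, gb)
  })
}

nn_dwconv <- function(c_in, k = 3, stride = 1, pad = (k - 1) %/% 2, name = "dwconv") {
  Wp <- es_param(array(he_init(k * k * c_in, k * k), c(k, k, c_in)),
                 paste0(name, ".W"))
  new_layer("dwconv", W = Wp, k = k, stride = stride, pad = pad,
            c_in = c_in, params = list(Wp))
}

ly_dwconv <- function(g, ly, x) {
  d <- dim(x$value)
  if (d[3] != ly$c_in) stop("dwconv: channel mismatch")
  k <- ly$k; s <- ly$stride; p <- ly$pad
  Ho <- (d[1] + 2 * p - k) %/% s + 1
  Wo <- (d[2] + 2 * p - k) %/% s + 1
  B <- d[4]
  out <- array(0, c(Ho, Wo, ly$c_in, B))
  for (b in seq_len(B))
    out[, , , b] <- cpp_dwconv_fw(x$value[, , , b], d[1], d[2], d[3],
                                  ly$W$value, k, s, p)
  Wn <- ag_wrap(g, ly$W)
  ag_node(g, out, list(Wn, x), function(gr) {
    gW <- array(0, c(k, k, ly$c_in))
    gx <- if (x$req) array(0, d) else NULL
    for (b in seq_len(B)) {
      bw <- cpp_dwconv_bw(x$value[, , , b], d[1], d[2], d[3],
                          ly$W$value, k, s, p, gr[, , , b])
      gW <- gW + bw$gw
      if (x$req) gx[, , , b] <- bw$gx
    }
    list(gW, gx)
  })
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5, name = "bn") {
  gp <- es_param(rep(1, c), paste0(name, ".gamma"))
  bp <- es_param(numeric(c), paste0(name, ".beta"))
  new_layer("bn", gamma = gp, beta = bp, c = c, momentum = momentum, eps = eps,
            rm = numeric(c), rv = rep(1, c), params = list(gp, bp))
}

ly_bn <- function(g, ly, x, training) {
  d <- dim(x$value)
  C <- d[3]
  if (C != ly$c) stop("bn: channel mismatch")
  hw <- d[1] * d[2]
  n <- hw * d[4]
  if (training) {
    st <- cpp_chan_stats(x$value, hw, C, d[4])
    mu <- st$mean
    va <- st$var
    ly$rm <- (1 - ly$momentum) * ly$rm + ly$momentum * mu
    ly$rv <- (1 - ly$momentum) * ly$rv + ly$momentum * va * n / max(n - 1, 1)
  } else {
    mu <- ly$rm
    va <- ly$rv
  }
  invstd <- 1 / sqrt(va + ly$eps)
  a <- invstd * ly$gamma$value
  y <- cpp_chan_affine(x$value, hw, C, d[4], a, ly$beta$value - mu * a)
  gn <- ag_wrap(g, ly$gamma)
  bn <- ag_wrap(g, ly$beta)
  ag_node(g, y, list(gn, bn, x), function(gr) {
    bw <- cpp_bn_bw(x$value, gr, hw, C, d[4], ly$gamma$value, mu, invstd,
                    batch_stats = training, need_gx = x$req)
    list(bw$ggamma, bw$gbeta, if (x$req) bw$gx else NULL)
  })
}

nn_linear <- function(c_in, c_out, name = "linear", w_sd = NULL, bias_init = NULL) {
  sd0 <- if (is.null(w_sd)) sqrt(1 / c_in) else w_sd
  Wp <- es_param(matrix(stats::rnorm(c_out * c_in, sd = sd0), c_out, c_in),
                 paste0(name, ".W"))
  b0 <- if (is.null(bias_init)) numeric(c_out) else bias_init
  bp <- es_param(b0, paste0(name, ".b"))
  new_layer("linear", W = Wp, b = bp, c_in = c_in, c_out = c_out,
            params = list(Wp, bp))
}

ly_linear <- function(g, ly, x) {
  ag_matmul_linear(g, ag_wrap(g, ly$W), x, ag_wrap(g, ly$b))
}

# conv + BN + ReLU block used throughout the pathways
nn_cbr <- function(c_in, c_out, k = 3, stride = 1, name = "cbr") {
  new_layer("cbr",
            conv = nn_conv(c_in, c_out, k, stride, bias = FALSE,
                           name = paste0(name, ".conv")),
            bn = nn_bn(c_out, name = paste0(name, ".bn")),
            params = NULL)
}

ly_cbr <- function(g, ly, x, training) {
  ag_relu(g, ly_bn(g, ly$bn, ly_conv(g, ly$conv, x), training))
}

# depthwise-separable conv + BN + ReLU (context pathway stages)
nn_sep <- function(c_in, c_out, stride = 1, name = "sep") {
  new_layer("sep",
            dw = nn_dwconv(c_in, 3, stride, name = paste0(name, ".dw")),
            pw = nn_conv(c_in, c_out, 1, 1, bias = FALSE,
                         name = paste0(name, ".pw")),
            bn = nn_bn(c_out, name = paste0(name, ".bn")),
            params = NULL)
}

ly_sep <- function(g, ly, x, training) {
  ag_relu(g, ly_bn(g, ly$bn, ly_conv(g, ly$pw, ly_dwconv(g, ly$dw, x)), training))
}

# ---- parameter bookkeeping ----------------------------------------------

collect_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "es_param")) {
      out[[length(out) + 1L]] <<- o
    } else if (inherits(o, "es_layer")) {
      if (!is.null(o$params)) for (p in o$params) walk(p)
      for (nm in ls(o)) {
        v <- get(nm, envir = o)
        if (inherits(v, "es_layer") || is.list(v)) walk(v)
      }
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  # de-duplicate (layers may be reachable twice)
  seen <- integer(0)
  res <- list()
  for (p in out) {
    if (!p$uid %in% seen) { seen <- c(seen, p$uid); res[[length(res) + 1L]] <- p }
  }
  res
}

collect_layers <- function(x, type = NULL) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "es_layer")) {
      if (is.null(type) || o$type %in% type) out[[length(out) + 1L]] <<- o
      for (nm in ls(o)) {
        v <- get(nm, envir = o)
        if (inherits(v, "es_layer") || is.list(v)) walk(v)
      }
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

n_learnable <- function(params) {
  sum(vapply(params, function(p) if (p$frozen) 0 else length(p$value), numeric(1)))
}
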