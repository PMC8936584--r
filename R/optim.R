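# Adam optimizer over es_param collections.

opt_adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$params <- params
  o$lr <- lr
  o$beta1 <- beta1
  o$beta2 <- beta2
  o$eps <- eps
  o$t <- 0L
  class(o) <- "es_adam"
  o
}

opt_step <- function(o) {
  o$t <- o$t + 1L
  b1 <- o$beta1; b2 <- o$beta2
  c1 <- 1 - b1^o$t
  c2 <- 1 - b2^o$t
  for (p in o$params) {
    if (p$frozen || is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- b1 * p$m + (1 - b1) * g
    p$v <- b2 * p$v + (1 - b2) * g * g
    p$value <- p$value - o$lr * (p$m / c1) / (sqrt(p$v / c2) + o$eps)
  }
  invisible(o)
}

# Reduce-on-plateau learning-rate schedule.
plateau_sched <- function(opt, factor = 0.5, patience = 5, min_lr = 1e-6) {
  s <- new.env(parent = emptyenv())
  s$opt <- opt; s$factor <- factor; s$patience <- patience; s$min_lr <- min_lr
  s$best <- Inf; s$wait <- 0L
  s
}

sched_step <- function(s, val_loss) {
  if (val_loss < s$best - 1e-8) {
    s$best <- val_loss
    s$wait <- 0L
  } else {
    s$wait <- s$wait + 1L
    if (s$wait >= s$patience) {
      s$opt$lr <- max(s$opt$lr * s$factor, s$min_lr)
      s$wait <- 0L
    }
  }
  invisible(s)
}
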