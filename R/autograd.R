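# A minimal reverse-mode tape for the conv-net engine. Feature maps are
# plain R arrays with dim = c(H, W, C, N); nodes are recorded on the tape
# during the forward pass and gradients are pushed back in reverse order.
# Parameter gradients are accumulated directly into layer environments
# (fields prefixed "g"), which is what the optimizer reads.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tp_push <- function(tp, val, op, parents = integer(0), ctx = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(val = val, op = op, parents = parents, ctx = ctx)
  tp$n
}

tp_val <- function(tp, id) tp$nodes[[id]]$val

op_input <- function(tp, x) tp_push(tp, x, "input")

# `cache_col = TRUE` keeps the im2col matrix for the backward pass
# (memory for speed; used in training passes). The gradient w.r.t. the
# network input itself is never needed, so convolutions consuming an
# "input" node skip dx in backward.
op_conv <- function(tp, x, layer, stride = 1L, pad = 1L,
                    cache_col = FALSE) {
  xv <- tp_val(tp, x)
  if (cache_col) {
    r <- .conv2d_fwd_cache(xv, layer$W, layer$b, as.integer(stride),
                           as.integer(pad))
    tp_push(tp, r$y, "conv", x,
            list(layer = layer, stride = stride, pad = pad, col = r$col,
                 xdim = dim(xv),
                 need_dx = tp$nodes[[x]]$op != "input"))
  } else {
    y <- .conv2d_fwd(xv, layer$W, layer$b, as.integer(stride),
                     as.integer(pad))
    tp_push(tp, y, "conv", x,
            list(layer = layer, stride = stride, pad = pad))
  }
}

op_bn <- function(tp, x, layer, training = TRUE) {
  xv <- tp_val(tp, x)
  d <- dim(xv)
  M <- d[1] * d[2] * d[4]
  eps <- layer$eps
  if (training) {
    m <- .chan_sum(xv) / M
    v <- .chan_sum(xv * xv) / M - m^2
    v[v < 0] <- 0
    layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * m
    layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * v
  } else {
    m <- layer$rmean
    v <- layer$rvar
  }
  istd <- 1 / sqrt(v + eps)
  r <- .bn_fwd(xv, m, istd, layer$gamma, layer$beta)
  tp_push(tp, r$y, "bn", x,
          list(layer = layer, xhat = r$xhat, istd = istd,
               training = training))
}

op_relu <- function(tp, x) {
  tp_push(tp, .relu_fwd(tp_val(tp, x)), "relu", x)
}

op_sigmoid <- function(tp, x) {
  y <- stats::plogis(tp_val(tp, x))
  tp_push(tp, y, "sigmoid", x)
}

op_add <- function(tp, a, b) {
  tp_push(tp, tp_val(tp, a) + tp_val(tp, b), "add", c(a, b))
}

op_concat <- function(tp, ids) {
  vals <- lapply(ids, function(i) tp_val(tp, i))
  chans <- vapply(vals, function(v) dim(v)[3], integer(1))
  tp_push(tp, .concat_channels(vals), "concat", ids, list(chans = chans))
}

op_maxpool2 <- function(tp, x) {
  xv <- tp_val(tp, x)
  r <- .maxpool2_fwd(xv)
  tp_push(tp, r$y, "maxpool2", x, list(idx = r$idx, xdim = dim(xv)))
}

op_upsample2 <- function(tp, x) {
  xv <- tp_val(tp, x)
  tp_push(tp, .upsample2_fwd(xv), "upsample2", x, list(xdim = dim(xv)))
}

# Global average pooling: (H,W,C,N) -> (C,N)
op_gap <- function(tp, x) {
  xv <- tp_val(tp, x)
  d <- dim(xv)
  z <- colMeans(matrix(xv, d[1] * d[2], d[3] * d[4]))
  dim(z) <- c(d[3], d[4])
  tp_push(tp, z, "gap", x, list(xdim = d))
}

# Zero-padded 1-D convolution over the channel axis of a (C,N) matrix,
# kernel length k (odd), no bias: the ECA excitation.
op_conv1d_channels <- function(tp, z, layer) {
  zv <- tp_val(tp, z)
  y <- conv1d_zero_pad(zv, layer$w)
  tp_push(tp, y, "conv1d", z, list(layer = layer))
}

# Per-channel, per-sample rescaling: x (H,W,C,N) * s (C,N)
op_scale_channels <- function(tp, x, s) {
  xv <- tp_val(tp, x)
  sv <- tp_val(tp, s)
  d <- dim(xv)
  y <- xv * rep(sv, each = d[1] * d[2])
  tp_push(tp, y, "scale_channels", c(x, s), list(xdim = d))
}

# Composite binary-segmentation loss on sigmoid probabilities:
# bce_w * BCE + dice_w * (1 - soft Dice), soft Dice per sample then
# averaged over the batch. Returns a scalar node.
op_bce_dice <- function(tp, p, target, bce_w = 0.5, dice_w = 0.5,
                        eps_clip = 1e-7, smooth = 1) {
  pv <- tp_val(tp, p)
  pc <- pmin(pmax(pv, eps_clip), 1 - eps_clip)
  d <- dim(pv)
  n <- d[4]
  m <- length(pv) / n
  bce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  pm <- matrix(pv, m, n)
  tm <- matrix(target, m, n)
  inter <- colSums(pm * tm)
  sums <- colSums(pm) + colSums(tm)
  sdice <- (2 * inter + smooth) / (sums + smooth)
  val <- bce_w * bce + dice_w * (1 - mean(sdice))
  tp_push(tp, val, "bce_dice", p,
          list(target = target, pc = pc, inter = inter, sums = sums,
               bce_w = bce_w, dice_w = dice_w, smooth = smooth, dims = d))
}

op_mean_scalars <- function(tp, ids) {
  vals <- vapply(ids, function(i) tp_val(tp, i), numeric(1))
  tp_push(tp, mean(vals), "mean_scalars", ids)
}

# Reverse pass. Accumulates parameter gradients into the layer
# environments captured in node contexts; returns gradients of any
# requested input nodes.
tape_backward <- function(tp, loss_id, want = integer(0)) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tp$nodes[[i]]
    p <- node$parents
    ctx <- node$ctx
    add_grad <- function(id, val) {
      grads[[id]] <<- if (is.null(grads[[id]])) val else grads[[id]] + val
    }
    switch(node$op,
      input = NULL,
      conv = {
        ly <- ctx$layer
        if (!is.null(ctx$col)) {
          r <- .conv2d_bwd_cached(ctx$col, ctx$xdim, ly$W, g,
                                  !is.null(ly$b), as.integer(ctx$stride),
                                  as.integer(ctx$pad), ctx$need_dx)
        } else {
          r <- .conv2d_bwd(tp_val(tp, p), ly$W, g, !is.null(ly$b),
                           as.integer(ctx$stride), as.integer(ctx$pad))
          r$need_dx <- TRUE
        }
        ly$gW <- ly$gW + r$dw
        if (!is.null(ly$b)) ly$gb <- ly$gb + r$db
        if (is.null(ctx$col) || ctx$need_dx) add_grad(p, r$dx)
      },
      bn = {
        ly <- ctx$layer
        r <- .bn_bwd(g, ctx$xhat, ly$gamma, ctx$istd, ctx$training)
        ly$ggamma <- ly$ggamma + r$dgamma
        ly$gbeta <- ly$gbeta + r$dbeta
        add_grad(p, r$dx)
      },
      relu = add_grad(p, .relu_bwd(g, node$val)),
      sigmoid = add_grad(p, g * node$val * (1 - node$val)),
      add = { add_grad(p[1], g); add_grad(p[2], g) },
      concat = {
        at <- 0L
        for (k in seq_along(p)) {
          cc <- ctx$chans[k]
          add_grad(p[k], .slice_channels(g, at + 1L, at + cc))
          at <- at + cc
        }
      },
      maxpool2 = add_grad(p, .maxpool2_bwd(g, ctx$idx, ctx$xdim)),
      upsample2 = add_grad(p, .upsample2_bwd(g, ctx$xdim)),
      gap = {
        d <- ctx$xdim
        add_grad(p, rep_channels(g / (d[1] * d[2]), d))
      },
      conv1d = {
        ly <- ctx$layer
        zv <- tp_val(tp, p)
        r <- conv1d_zero_pad_bwd(zv, ly$w, g)
        ly$gw <- ly$gw + r$dw
        add_grad(p, r$dz)
      },
      scale_channels = {
        xv <- tp_val(tp, p[1])
        sv <- tp_val(tp, p[2])
        d <- ctx$xdim
        add_grad(p[1], g * rep(sv, each = d[1] * d[2]))
        ds <- colSums(matrix(g * xv, d[1] * d[2], d[3] * d[4]))
        dim(ds) <- c(d[3], d[4])
        add_grad(p[2], ds)
      },
      bce_dice = {
        d <- ctx$dims
        n <- d[4]
        m <- prod(d) / n
        tg <- ctx$target
        pc <- ctx$pc
        dbce <- ctx$bce_w * (-tg / pc + (1 - tg) / (1 - pc)) / prod(d)
        den <- ctx$sums + ctx$smooth
        num <- 2 * ctx$inter + ctx$smooth
        # d(1 - mean_n dice_n)/dp: per sample -(2*t*den - num)/den^2 / n
        tgm <- matrix(tg, m, n)
        dd <- -(2 * tgm * rep(den, each = m) - rep(num, each = m)) /
          rep(den^2, each = m) / n * ctx$dice_w
        dp <- g * (dbce + array(dd, d))
        add_grad(p, dp)
      },
      mean_scalars = {
        for (k in p) add_grad(k, g / length(p))
      },
      stop("unknown op in backward: ", node$op)
    )
  }
  grads[want]
}

# ---- small array helpers ----

# broadcast a (C,N) matrix (or per-channel vector recycled over N) to (H,W,C,N)
rep_channels <- function(m, d) {
  array(rep(as.vector(m), each = d[1] * d[2]), d)
}

# zero-padded 1-D convolution along rows of z (C,N) with kernel w (odd k)
conv1d_zero_pad <- function(z, w) {
  k <- length(w)
  half <- (k - 1L) / 2L
  C <- nrow(z)
  zp <- rbind(matrix(0, half, ncol(z)), z, matrix(0, half, ncol(z)))
  y <- matrix(0, C, ncol(z))
  for (j in seq_len(k)) {
    y <- y + w[j] * zp[seq_len(C) + (j - 1L), , drop = FALSE]
  }
  y
}

conv1d_zero_pad_bwd <- function(z, w, dy) {
  k <- length(w)
  half <- (k - 1L) / 2L
  C <- nrow(z)
  zp <- rbind(matrix(0, half, ncol(z)), z, matrix(0, half, ncol(z)))
  dw <- numeric(k)
  dzp <- matrix(0, C + 2L * half, ncol(z))
  for (j in seq_len(k)) {
    rows <- seq_len(C) + (j - 1L)
    dw[j] <- sum(dy * zp[rows, , drop = FALSE])
    dzp[rows, ] <- dzp[rows, , drop = FALSE] + w[j] * dy
  }
  list(dw = dw, dz = dzp[half + seq_len(C), , drop = FALSE])
}
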