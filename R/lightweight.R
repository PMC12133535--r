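# Model compression: structured channel pruning by per-channel L1 norm
# (encoder scope, with coupled residual layers pruned consistently) and
# post-training per-tensor affine INT8 quantization with min/max
# calibration.

l1_per_output <- function(W) apply(abs(W), 4, sum)

top_keep <- function(score, fraction) {
  C <- length(score)
  k <- max(1L, round((1 - fraction) * C))
  sort(order(score, decreasing = TRUE)[seq_len(k)])
}

#' Prune encoder channels by L1 norm
#'
#' Structured one-shot pruning: within the encoder (stem, residual
#' stages, and the ECA modules attached to them), output channels of each
#' convolution are ranked by the L1 norm of their kernels and the lowest
#' `fraction` is removed. Channels that meet at a residual addition
#' (block outputs, shortcut projections) are coupled and pruned by the
#' union of the per-layer kept sets, so shortcut arithmetic stays valid;
#' downstream input channels, batch-norm parameters and running
#' statistics, and the decoder convolutions that consume encoder features
#' are re-wired consistently. Each ECA module's kernel size is recomputed
#' from its new channel count. The network's output shape contract is
#' unchanged. Decoder node widths and heads are left untouched.
#'
#' @param model A trained `us_model` (not quantized).
#' @param fraction Fraction of channels to remove per layer, in `[0, 1)`
#'   (default 0.30). `fraction = 0` reproduces the model exactly.
#' @return A new `us_model` with reduced widths and attribute
#'   `"prune_info"` (tibble of per-group original/kept channel counts).
#' @export
prune_model <- function(model, fraction = 0.30) {
  stopifnot(inherits(model, "us_model"))
  if (!is.null(model$quant)) stop("prune before quantization, not after")
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  cfg <- model$cfg
  L <- cfg$depth
  lys <- model$layers
  w_old <- model$widths

  info <- list()
  note <- function(group, kept, total) {
    info[[length(info) + 1L]] <<- tibble::tibble(
      group = group, original = total, kept = kept)
  }

  keep_stem <- top_keep(l1_per_output(lys[["stem.conv"]]$W), fraction)
  note("stem", length(keep_stem), w_old$stem)

  keep_iface <- vector("list", L)   # coupled interface channels per stage
  keep_inner <- vector("list", L)
  for (s in seq_len(L)) {
    B <- cfg$blocks[s]
    C <- w_old$stage_out[s]
    union_set <- integer(0)
    for (k in seq_len(B)) {
      base <- sprintf("stage%d.block%d", s, k)
      union_set <- union(union_set,
                         top_keep(l1_per_output(lys[[paste0(base, ".conv2")]]$W),
                                  fraction))
      if (!is.null(lys[[paste0(base, ".proj")]])) {
        union_set <- union(union_set,
                           top_keep(l1_per_output(lys[[paste0(base, ".proj")]]$W),
                                    fraction))
      }
    }
    keep_iface[[s]] <- sort(union_set)
    note(sprintf("stage%d.interface", s), length(union_set), C)
    keep_inner[[s]] <- lapply(seq_len(B), function(k) {
      base <- sprintf("stage%d.block%d", s, k)
      kp <- top_keep(l1_per_output(lys[[paste0(base, ".conv1")]]$W), fraction)
      note(sprintf("%s.inner", base), length(kp), w_old$block_inner[[s]][k])
      kp
    })
  }

  widths <- w_old
  widths$stem <- length(keep_stem)
  widths$stage_out <- vapply(keep_iface, length, integer(1))
  widths$block_inner <- lapply(seq_len(L), function(s) {
    vapply(keep_inner[[s]], length, integer(1))
  })

  new <- build_model(cfg, widths)
  enc_keep <- function(r) if (r == 0) keep_stem else keep_iface[[r]]

  cp_conv <- function(name, keep_in = NULL, keep_out = NULL) {
    src <- lys[[name]]
    dst <- new$layers[[name]]
    W <- src$W
    if (!is.null(keep_in)) W <- W[, , keep_in, , drop = FALSE]
    if (!is.null(keep_out)) W <- W[, , , keep_out, drop = FALSE]
    dst$W <- W
    if (!is.null(src$b)) {
      dst$b <- if (is.null(keep_out)) src$b else src$b[keep_out]
    }
    zero_grads(dst)
  }
  cp_bn <- function(name, keep = NULL) {
    src <- lys[[name]]
    dst <- new$layers[[name]]
    idx <- if (is.null(keep)) seq_along(src$gamma) else keep
    dst$gamma <- src$gamma[idx]
    dst$beta <- src$beta[idx]
    dst$rmean <- src$rmean[idx]
    dst$rvar <- src$rvar[idx]
    zero_grads(dst)
  }

  cp_conv("stem.conv", keep_out = keep_stem)
  cp_bn("stem.bn", keep_stem)
  for (s in seq_len(L)) {
    prev_keep <- if (s == 1) keep_stem else keep_iface[[s - 1]]
    for (k in seq_len(cfg$blocks[s])) {
      base <- sprintf("stage%d.block%d", s, k)
      in_keep <- if (k == 1) prev_keep else keep_iface[[s]]
      cp_conv(paste0(base, ".conv1"), in_keep, keep_inner[[s]][[k]])
      cp_bn(paste0(base, ".bn1"), keep_inner[[s]][[k]])
      cp_conv(paste0(base, ".conv2"), keep_inner[[s]][[k]], keep_iface[[s]])
      cp_bn(paste0(base, ".bn2"), keep_iface[[s]])
      if (!is.null(lys[[paste0(base, ".proj")]])) {
        cp_conv(paste0(base, ".proj"), in_keep, keep_iface[[s]])
        cp_bn(paste0(base, ".projbn"), keep_iface[[s]])
      }
    }
    src_eca <- lys[[sprintf("eca%d", s)]]
    if (!is.null(src_eca)) {
      dst_eca <- new$layers[[sprintf("eca%d", s)]]
      dst_eca$w <- resize_kernel(src_eca$w, dst_eca$k)
      zero_grads(dst_eca)
    }
  }
  # decoder: copy as-is, slicing only input blocks that carry encoder
  # channels (the first concat block, and the upsampled one when j = 1)
  for (j in seq_len(L)) {
    for (i in 0:(L - j)) {
      node <- sprintf("x_%d_%d", i, j)
      e_i <- encoder_row_width(w_old, i)
      d_i <- w_old$decoder[i + 1]
      up_w <- if (j == 1) encoder_row_width(w_old, i + 1) else
        w_old$decoder[i + 2]
      keep_in <- c(enc_keep(i),
                   if (j > 1) e_i + seq_len((j - 1) * d_i) else integer(0),
                   if (j == 1) e_i + match(enc_keep(i + 1), seq_len(up_w))
                   else e_i + (j - 1) * d_i + seq_len(up_w))
      cp_conv(paste0(node, ".conv1"), keep_in = keep_in)
      cp_bn(paste0(node, ".bn1"))
      cp_conv(paste0(node, ".conv2"))
      cp_bn(paste0(node, ".bn2"))
    }
  }
  for (j in seq_len(L)) {
    cp_conv(sprintf("head%d.conv", j))
  }
  attr(new, "prune_info") <- dplyr::bind_rows(info)
  attr(new, "prune_fraction") <- fraction
  new
}

# center-crop or zero-pad a 1-D kernel to length k
resize_kernel <- function(w, k) {
  if (length(w) == k) return(w)
  if (length(w) > k) {
    off <- (length(w) - k) %/% 2
    w[off + seq_len(k)]
  } else {
    pad <- (k - length(w)) %/% 2
    c(numeric(pad), w, numeric(k - length(w) - pad))
  }
}

# ---- INT8 post-training quantization ----

#' Quantize tensor values to INT8 (per-tensor affine)
#'
#' `scale = (max - min) / 255`, zero point chosen so the range maps onto
#' `[-128, 127]`. Returns integer codes plus the affine parameters.
#' @param x Numeric values.
#' @param lo,hi Range to calibrate against (default `range(x)`).
#' @return List with `q` (integers), `scale`, `zp`.
#' @export
quantize_tensor <- function(x, lo = min(x), hi = max(x)) {
  if (hi <= lo) hi <- lo + 1e-8
  scale <- (hi - lo) / 255
  zp <- round(-128 - lo / scale)
  q <- pmin(127, pmax(-128, round(x / scale) + zp))
  list(q = q, scale = scale, zp = zp)
}

#' @rdname quantize_tensor
#' @param q,scale,zp Quantized codes and affine parameters.
#' @export
dequantize_tensor <- function(q, scale, zp) (q - zp) * scale

fake_quant <- function(x, lo, hi) {
  p <- quantize_tensor(x, lo, hi)
  dequantize_tensor(p$q, p$scale, p$zp)
}

# fold every conv+BN pair of the program into the conv (inference only)
fold_batchnorm <- function(model) {
  prev_out_layer <- list() # tensor name -> conv layer name
  for (st in model$program) {
    if (st$op == "conv") prev_out_layer[[st$out]] <- st$layer
    if (st$op == "bn" && !is.null(prev_out_layer[[st$input]])) {
      conv <- model$layers[[prev_out_layer[[st$input]]]]
      bn <- model$layers[[st$layer]]
      g <- bn$gamma / sqrt(bn$rvar + bn$eps)
      cout <- dim(conv$W)[4]
      for (c in seq_len(cout)) {
        conv$W[, , , c] <- conv$W[, , , c] * g[c]
      }
      b0 <- if (is.null(conv$b)) numeric(cout) else conv$b
      conv$b <- bn$beta + (b0 - bn$rmean) * g
      bn$gamma <- rep(1, cout)
      bn$beta <- numeric(cout)
      bn$rmean <- numeric(cout)
      bn$rvar <- rep(1 - bn$eps, cout)
      zero_grads(conv)
      zero_grads(bn)
    }
  }
  invisible(model)
}

clone_model <- function(model) {
  new <- build_model(model$cfg, model$widths)
  restore_params(new$layers, snapshot_params(model$layers))
  # restore_params skips NULL biases; copy any folded biases explicitly
  for (nm in names(model$layers)) {
    if (model$layers[[nm]]$type == "conv") {
      new$layers[[nm]]$b <- model$layers[[nm]]$b
      zero_grads(new$layers[[nm]])
    }
  }
  new
}

#' Post-training INT8 quantization
#'
#' Converts a trained model to simulated-INT8 inference: batch norm is
#' folded into the convolutions, every convolution weight tensor (2-D
#' convs and the ECA 1-D kernels) is stored as per-tensor affine INT8
#' codes (no FP32 conv weight tensor remains), and activation ranges are
#' calibrated as the min/max of each convolution output over a
#' calibration set; at inference, weights are dequantized from their
#' codes and every convolution output is quantize-dequantized against its
#' calibrated range.
#'
#' @param model A trained `us_model`.
#' @param calib_pairs Nonempty list of sample pairs (>= 16 images
#'   recommended) used only for activation-range calibration.
#' @return A new quantized `us_model` (`model$quant` non-NULL).
#' @export
quantize_model <- function(model, calib_pairs) {
  stopifnot(inherits(model, "us_model"))
  if (length(calib_pairs) == 0) stop("calibration set must be nonempty")
  qm <- clone_model(model)
  fold_batchnorm(qm)
  for (nm in names(qm$layers)) {
    ly <- qm$layers[[nm]]
    if (ly$type == "conv") {
      p <- quantize_tensor(ly$W)
      ly$Wq <- array(as.integer(p$q), dim(ly$W))
      ly$w_scale <- p$scale
      ly$w_zp <- p$zp
      ly$W <- NULL
    } else if (ly$type == "eca") {
      p <- quantize_tensor(ly$w)
      ly$wq <- as.integer(p$q)
      ly$w_scale <- p$scale
      ly$w_zp <- p$zp
      ly$w <- NULL
    }
  }
  # calibration pass: record conv-output ranges with quantized weights
  imgs <- pairs_to_arrays(calib_pairs)$images
  qm$quant <- list(mode = "calib",
                   act = new.env(parent = emptyenv()))
  n <- dim(imgs)[4]
  for (b in split(seq_len(n), ceiling(seq_len(n) / 4))) {
    invisible(run_program(qm, imgs[, , , b, drop = FALSE],
                          training = FALSE, quant = qm$quant))
  }
  qm$quant$mode <- "eval"
  qm
}

deq_conv_weights <- function(ly) {
  W <- dequantize_tensor(ly$Wq, ly$w_scale, ly$w_zp)
  dim(W) <- dim(ly$Wq)
  W
}

# quantized conv: dequantized-weight convolution followed by fake
# quantization of the output against the calibrated range
op_conv_quant <- function(tp, x, ly, stride, pad, quant, lname) {
  W <- deq_conv_weights(ly)
  xv <- tp_val(tp, x)
  y <- .conv2d_fwd(xv, W, ly$b, as.integer(stride), as.integer(pad))
  if (quant$mode == "calib") {
    r <- quant$act[[lname]]
    rng <- range(y)
    quant$act[[lname]] <- if (is.null(r)) rng else range(r, rng)
  } else {
    r <- quant$act[[lname]]
    y <- array(fake_quant(y, r[1], r[2]), dim(y))
  }
  tp_push(tp, y, "input") # inference only; no gradient path needed
}

#' Size of conv weight storage in bytes
#'
#' FP32 models count 4 bytes per convolution weight; quantized models 1
#' byte per INT8 code (plus the negligible per-tensor scale/zero-point).
#' Used to verify the ~4x compression of INT8 storage.
#'
#' @param model A `us_model`.
#' @return Number of bytes.
#' @export
conv_weight_bytes <- function(model) {
  total <- 0
  for (ly in model$layers) {
    if (ly$type == "conv") {
      total <- total +
        (if (is.null(ly$W)) length(ly$Wq) * 1 + 8 else length(ly$W) * 4)
    } else if (ly$type == "eca") {
      total <- total +
        (if (is.null(ly$w)) length(ly$wq) * 1 + 8 else length(ly$w) * 4)
    }
  }
  total
}

#' Efficiency report for model variants
#'
#' Parameters, FLOPs at a given input size, conv-weight storage, and
#' locally measured per-image latency for a set of model variants
#' (e.g. original / pruned / pruned+INT8). Latency is measured on the
#' current hardware and is only comparable within one report.
#'
#' @param variants Named list of `us_model`s.
#' @param input_size `c(H, W)` used for FLOPs and the latency probe.
#' @param measure_latency Time one forward pass per variant (default
#'   TRUE).
#' @return A tibble with one row per variant: `variant`, `parameters`,
#'   `params_M`, `flops_g`, `weight_bytes`, `latency_ms`
#'   (hardware-dependent; NA when not measured).
#' @export
efficiency_report <- function(variants, input_size = c(512, 512),
                              measure_latency = TRUE) {
  stopifnot(is.list(variants), length(names(variants)) == length(variants))
  rows <- lapply(names(variants), function(nm) {
    m <- variants[[nm]]
    fl <- count_flops(m, input_size)
    lat <- NA_real_
    if (measure_latency) {
      x <- array(0.5, c(input_size[1], input_size[2], m$cfg$in_channels, 1))
      lat <- 1000 * system.time(forward(m, x))[["elapsed"]]
    }
    tibble::tibble(
      variant = nm, parameters = count_parameters(m),
      params_M = count_parameters(m) / 1e6, flops_g = fl$flops_g,
      weight_bytes = conv_weight_bytes(m), latency_ms = lat
    )
  })
  dplyr::bind_rows(rows)
}

#' Write / read an efficiency report
#'
#' JSON round-trip for [efficiency_report()] tables.
#' @param report A tibble from [efficiency_report()].
#' @param path File path.
#' @export
write_efficiency_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_efficiency_report
#' @export
read_efficiency_report <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  out$latency_ms <- as.numeric(out$latency_ms) # all-NA columns read as logical
  out
}
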