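#' Adaptive ECA kernel size
#'
#' Computes the 1-D convolution kernel size used by the efficient channel
#' attention (ECA) module from the channel count: `t = (log2(C) + b) / gamma`
#' is truncated to an integer and, if even, bumped to the next odd number
#' (never below 1), so that the kernel is always odd and grows
#' logarithmically with the number of channels.
#'
#' @param C Number of channels (positive integer).
#' @param gamma,b Integers controlling the mapping (defaults 2 and 1).
#' @return An odd integer kernel size.
#' @examples
#' eca_kernel_size(64)   # 3
#' eca_kernel_size(256)  # 5
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1 || !is.finite(C) || C < 1) {
    stop("`C` must be a single integer >= 1")
  }
  if (gamma <= 0) stop("`gamma` must be positive")
  t <- (log2(C) + b) / gamma
  k <- trunc(t)
  if (k %% 2 == 0) k <- k + 1
  as.integer(max(1, k))
}

#' ECA channel attention forward pass
#'
#' Applies efficient channel attention to a feature map: global average
#' pooling over space gives one descriptor per channel, a zero-padded 1-D
#' convolution of adaptive kernel size mixes neighbouring channels, a
#' sigmoid maps the result to (0,1) weights, and each channel is rescaled
#' by its weight. The operation is shape preserving and acts as a pure
#' per-channel rescaling.
#'
#' @param U A feature map array of shape `(H, W, C)` or `(H, W, C, N)`.
#' @param weights Optional numeric kernel of odd length; defaults to the
#'   adaptive size `eca_kernel_size(C, gamma, b)` filled with zeros (a
#'   neutral 0.5 rescaling).
#' @param gamma,b ECA kernel-size parameters.
#' @return An array of the same shape as `U`, with attribute
#'   `"channel_weights"` holding the (C, N) attention weights.
#' @export
eca_forward <- function(U, weights = NULL, gamma = 2, b = 1) {
  d <- dim(U)
  squeeze <- FALSE
  if (length(d) == 3) {
    dim(U) <- c(d, 1L)
    d <- dim(U)
    squeeze <- TRUE
  }
  if (length(d) != 4) stop("`U` must have shape (H,W,C) or (H,W,C,N)")
  C <- d[3]
  if (is.null(weights)) weights <- numeric(eca_kernel_size(C, gamma, b))
  if (length(weights) %% 2 == 0) stop("ECA kernel length must be odd")
  z <- colMeans(matrix(U, d[1] * d[2], C * d[4]))
  dim(z) <- c(C, d[4])
  w <- stats::plogis(conv1d_zero_pad(z, weights))
  out <- U * rep(w, each = d[1] * d[2])
  if (squeeze) dim(out) <- d[1:3]
  attr(out, "channel_weights") <- w
  out
}

#' Architecture configuration for the residual ECA-UNet++ segmenter
#'
#' Describes the full network: a ResNet34-style encoder (3x3 stem,
#' batch-normalized basic residual blocks in four stages of 3, 4, 6 and 3
#' blocks with widths doubling per stage), ECA channel attention after
#' each encoder stage, a UNet++ decoder grid of depth `depth` with dense
#' skip connections, and one supervision head per top-row decoder node.
#'
#' @param base_width Channels of the stem / first stage (64 reproduces the
#'   ResNet34 widths 64/128/256/512; smaller values scale the whole
#'   network down proportionally).
#' @param depth Number of downsampling levels L (decoder grid has
#'   `(L+1)(L+2)/2` nodes and L supervision heads). Maximum 4.
#' @param blocks Residual blocks per encoder stage (first `depth` entries
#'   are used).
#' @param eca_after_stage Logical vector: apply ECA after each stage.
#' @param eca_gamma,eca_b ECA kernel-size parameters.
#' @param n_classes Output channels of each head (1 = binary, sigmoid).
#' @param in_channels Input image channels (3 for replicated grayscale).
#' @param decoder_widths Channels per decoder row, top (full resolution)
#'   to bottom; default `base_width/2 * 2^i` per row i.
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `us_model_config`.
#' @export
model_config <- function(base_width = 64, depth = 4,
                         blocks = c(3, 4, 6, 3),
                         eca_after_stage = rep(TRUE, depth),
                         eca_gamma = 2, eca_b = 1,
                         n_classes = 1, in_channels = 3,
                         decoder_widths = NULL, seed = 42L) {
  stopifnot(depth >= 1, depth <= 4, base_width >= 2)
  blocks <- rep_len(blocks, 4)[seq_len(depth)]
  eca_after_stage <- rep_len(eca_after_stage, depth)
  if (is.null(decoder_widths)) {
    decoder_widths <- pmax(4, base_width / 2 * 2^(seq_len(depth) - 1))
  }
  stopifnot(length(decoder_widths) == depth)
  structure(list(
    base_width = as.integer(base_width), depth = as.integer(depth),
    blocks = as.integer(blocks), eca_after_stage = eca_after_stage,
    eca_gamma = eca_gamma, eca_b = eca_b,
    n_classes = as.integer(n_classes), in_channels = as.integer(in_channels),
    decoder_widths = as.integer(decoder_widths), seed = as.integer(seed)
  ), class = "us_model_config")
}

# Explicit per-layer channel widths; pruning produces modified copies.
default_widths <- function(cfg) {
  L <- cfg$depth
  stage_out <- as.integer(cfg$base_width * 2^(seq_len(L) - 1))
  list(
    stem = cfg$base_width,
    stage_out = stage_out,
    block_inner = lapply(seq_len(L), function(s) {
      rep(stage_out[s], cfg$blocks[s])
    }),
    decoder = cfg$decoder_widths
  )
}

encoder_row_width <- function(widths, i) {
  if (i == 0) widths$stem else widths$stage_out[i]
}

# Build the step program describing the whole network. Steps reference
# named tensors; `layer` names index into model$layers.
build_program <- function(cfg, widths) {
  L <- cfg$depth
  steps <- list()
  specs <- list() # layer name -> constructor spec
  emit <- function(...) steps[[length(steps) + 1L]] <<- list(...)
  conv_spec <- function(name, k, cin, cout, bias = FALSE) {
    specs[[name]] <<- list(type = "conv", k = k, cin = cin, cout = cout,
                           bias = bias)
  }
  bn_spec <- function(name, C) specs[[name]] <<- list(type = "bn", C = C)

  # stem: 3x3 stride-1 conv + BN + ReLU at full resolution (row 0)
  conv_spec("stem.conv", 3L, cfg$in_channels, widths$stem)
  bn_spec("stem.bn", widths$stem)
  emit(op = "conv", out = ".stem.c", input = ".input", layer = "stem.conv",
       stride = 1L, pad = 1L)
  emit(op = "bn", out = ".stem.b", input = ".stem.c", layer = "stem.bn")
  emit(op = "relu", out = "x_0_0", input = ".stem.b")
  emit(op = "maxpool", out = ".pool0", input = "x_0_0")

  prev <- ".pool0"
  prev_w <- widths$stem
  for (s in seq_len(L)) {
    w_out <- widths$stage_out[s]
    for (k in seq_len(cfg$blocks[s])) {
      base <- sprintf("stage%d.block%d", s, k)
      stride <- if (s > 1 && k == 1) 2L else 1L
      w_in <- if (k == 1) prev_w else w_out
      w_mid <- widths$block_inner[[s]][k]
      conv_spec(paste0(base, ".conv1"), 3L, w_in, w_mid)
      bn_spec(paste0(base, ".bn1"), w_mid)
      conv_spec(paste0(base, ".conv2"), 3L, w_mid, w_out)
      bn_spec(paste0(base, ".bn2"), w_out)
      emit(op = "conv", out = paste0(".", base, ".c1"), input = prev,
           layer = paste0(base, ".conv1"), stride = stride, pad = 1L)
      emit(op = "bn", out = paste0(".", base, ".b1"),
           input = paste0(".", base, ".c1"), layer = paste0(base, ".bn1"))
      emit(op = "relu", out = paste0(".", base, ".r1"),
           input = paste0(".", base, ".b1"))
      emit(op = "conv", out = paste0(".", base, ".c2"),
           input = paste0(".", base, ".r1"),
           layer = paste0(base, ".conv2"), stride = 1L, pad = 1L)
      emit(op = "bn", out = paste0(".", base, ".b2"),
           input = paste0(".", base, ".c2"), layer = paste0(base, ".bn2"))
      if (stride != 1L || w_in != w_out) {
        conv_spec(paste0(base, ".proj"), 1L, w_in, w_out)
        bn_spec(paste0(base, ".projbn"), w_out)
        emit(op = "conv", out = paste0(".", base, ".pc"), input = prev,
             layer = paste0(base, ".proj"), stride = stride, pad = 0L)
        emit(op = "bn", out = paste0(".", base, ".pb"),
             input = paste0(".", base, ".pc"),
             layer = paste0(base, ".projbn"))
        short <- paste0(".", base, ".pb")
      } else {
        short <- prev
      }
      emit(op = "add", out = paste0(".", base, ".s"),
           input = c(paste0(".", base, ".b2"), short))
      emit(op = "relu", out = paste0(".", base, ".out"),
           input = paste0(".", base, ".s"))
      prev <- paste0(".", base, ".out")
    }
    out_name <- sprintf("x_%d_0", s)
    if (cfg$eca_after_stage[s]) {
      specs[[sprintf("eca%d", s)]] <- list(type = "eca", C = w_out,
                                           gamma = cfg$eca_gamma,
                                           b = cfg$eca_b)
      emit(op = "eca", out = out_name, input = prev,
           layer = sprintf("eca%d", s))
    } else {
      emit(op = "alias", out = out_name, input = prev)
    }
    prev <- out_name
    prev_w <- w_out
  }

  # UNet++ decoder grid: X[i,j] = H(concat(X[i,0..j-1], up(X[i+1,j-1])))
  dec_w <- function(i, j) {
    if (j == 0) encoder_row_width(widths, i) else widths$decoder[i + 1]
  }
  for (j in seq_len(L)) {
    for (i in 0:(L - j)) {
      node <- sprintf("x_%d_%d", i, j)
      upsrc <- sprintf("x_%d_%d", i + 1, j - 1)
      emit(op = "upsample", out = paste0(".", node, ".up"), input = upsrc)
      ins <- c(sprintf("x_%d_%d", i, 0:(j - 1)), paste0(".", node, ".up"))
      cin <- sum(vapply(0:(j - 1), function(k) dec_w(i, k), numeric(1))) +
        dec_w(i + 1, j - 1)
      cout <- widths$decoder[i + 1]
      emit(op = "concat", out = paste0(".", node, ".cat"), input = ins)
      conv_spec(paste0(node, ".conv1"), 3L, cin, cout)
      bn_spec(paste0(node, ".bn1"), cout)
      conv_spec(paste0(node, ".conv2"), 3L, cout, cout)
      bn_spec(paste0(node, ".bn2"), cout)
      emit(op = "conv", out = paste0(".", node, ".c1"),
           input = paste0(".", node, ".cat"),
           layer = paste0(node, ".conv1"), stride = 1L, pad = 1L)
      emit(op = "bn", out = paste0(".", node, ".b1"),
           input = paste0(".", node, ".c1"), layer = paste0(node, ".bn1"))
      emit(op = "relu", out = paste0(".", node, ".r1"),
           input = paste0(".", node, ".b1"))
      emit(op = "conv", out = paste0(".", node, ".c2"),
           input = paste0(".", node, ".r1"),
           layer = paste0(node, ".conv2"), stride = 1L, pad = 1L)
      emit(op = "bn", out = paste0(".", node, ".b2"),
           input = paste0(".", node, ".c2"), layer = paste0(node, ".bn2"))
      emit(op = "relu", out = node, input = paste0(".", node, ".b2"))
    }
  }

  # deep supervision: one 1x1-conv + sigmoid head per top-row node
  for (j in seq_len(L)) {
    hname <- sprintf("head%d", j)
    conv_spec(paste0(hname, ".conv"), 1L, widths$decoder[1], cfg$n_classes,
              bias = TRUE)
    emit(op = "conv", out = paste0(".", hname, ".c"),
         input = sprintf("x_0_%d", j),
         layer = paste0(hname, ".conv"), stride = 1L, pad = 0L)
    emit(op = "sigmoid", out = hname, input = paste0(".", hname, ".c"))
  }
  list(steps = steps, specs = specs)
}

#' Build a residual ECA-UNet++ segmentation model
#'
#' Instantiates the network described by a [model_config()]: all layer
#' parameters are allocated and initialized (He-normal convolutions,
#' unit-gain batch norm) under the configuration seed, and the dense
#' decoder wiring is recorded so that the graph structure can be
#' inspected with [model_grid()].
#'
#' @param cfg A [model_config()].
#' @param widths Internal: explicit per-layer channel widths (used by
#'   [prune_model()]); defaults to the widths implied by `cfg`.
#' @return An object of class `us_model`.
#' @export
build_model <- function(cfg, widths = NULL) {
  stopifnot(inherits(cfg, "us_model_config"))
  if (is.null(widths)) widths <- default_widths(cfg)
  prog <- build_program(cfg, widths)
  layers <- withr::with_seed(cfg$seed, {
    lapply(prog$specs, function(sp) {
      switch(sp$type,
        conv = new_conv_layer(sp$k, sp$k, sp$cin, sp$cout, bias = sp$bias),
        bn = new_bn_layer(sp$C),
        eca = new_eca_layer(sp$C, sp$gamma, sp$b)
      )
    })
  })
  names(layers) <- names(prog$specs)
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$widths <- widths
  model$program <- prog$steps
  model$specs <- prog$specs
  model$layers <- layers
  model$quant <- NULL
  class(model) <- "us_model"
  model
}

#' Decoder grid structure of a built model
#'
#' @param model A `us_model`.
#' @return A tibble with one row per grid node `X[i,j]` (encoder backbone
#'   column j = 0 included): columns `i`, `j`, `name`, and a list-column
#'   `inputs` of the node names feeding it.
#' @export
model_grid <- function(model) {
  L <- model$cfg$depth
  rows <- list()
  for (i in 0:L) {
    inputs <- if (i == 0) list(character(0)) else list(sprintf("x_%d_0", i - 1))
    rows[[length(rows) + 1L]] <-
      tibble::tibble(i = i, j = 0L, name = sprintf("x_%d_0", i),
                     inputs = inputs)
  }
  for (j in seq_len(L)) {
    for (i in 0:(L - j)) {
      ins <- c(sprintf("x_%d_%d", i, 0:(j - 1)), sprintf("x_%d_%d", i + 1, j - 1))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(i = i, j = j, name = sprintf("x_%d_%d", i, j),
                       inputs = list(ins))
    }
  }
  dplyr::bind_rows(rows)
}

# Execute the program on a tape. Returns list(tape, tensors = name->id).
run_program <- function(model, x, training = TRUE, quant = NULL) {
  tp <- tape_new()
  env <- new.env(parent = emptyenv())
  env$.input <- op_input(tp, x)
  get_id <- function(nm) get(nm, envir = env)
  for (st in model$program) {
    id <- switch(st$op,
      conv = {
        ly <- model$layers[[st$layer]]
        xin <- get_id(st$input)
        if (!is.null(quant)) {
          yid <- op_conv_quant(tp, xin, ly, st$stride, st$pad,
                               quant, st$layer)
        } else {
          yid <- op_conv(tp, xin, ly, st$stride, st$pad)
        }
        yid
      },
      bn = op_bn(tp, get_id(st$input), model$layers[[st$layer]],
                 training = training),
      relu = op_relu(tp, get_id(st$input)),
      sigmoid = op_sigmoid(tp, get_id(st$input)),
      add = op_add(tp, get_id(st$input[1]), get_id(st$input[2])),
      concat = op_concat(tp, vapply(st$input, get_id, integer(1))),
      maxpool = op_maxpool2(tp, get_id(st$input)),
      upsample = op_upsample2(tp, get_id(st$input)),
      alias = get_id(st$input),
      eca = {
        ly <- model$layers[[st$layer]]
        if (!is.null(quant) && is.null(ly$w)) {
          # temporary view with dequantized INT8 kernel
          tmp <- new.env(parent = emptyenv())
          tmp$type <- "eca"
          tmp$w <- dequantize_tensor(ly$wq, ly$w_scale, ly$w_zp)
          tmp$gw <- numeric(length(tmp$w))
          ly <- tmp
        }
        xin <- get_id(st$input)
        z <- op_gap(tp, xin)
        e <- op_conv1d_channels(tp, z, ly)
        w <- op_sigmoid(tp, e)
        op_scale_channels(tp, xin, w)
      },
      stop("unknown program op: ", st$op)
    )
    assign(st$out, id, envir = env)
  }
  list(tape = tp, ids = env)
}

check_input_dims <- function(model, d) {
  L <- model$cfg$depth
  need <- 2^L
  if (d[1] %% need != 0 || d[2] %% need != 0) {
    stop(sprintf(
      "input spatial size %dx%d must be divisible by %d (2^depth)",
      d[1], d[2], need))
  }
  if (d[3] != model$cfg$in_channels) {
    stop(sprintf("input has %d channels; model expects %d",
                 d[3], model$cfg$in_channels))
  }
}

#' Forward pass of a segmentation model
#'
#' @param model A `us_model`.
#' @param x Image batch, array `(H, W, C, N)` (or `(H, W, C)` for a single
#'   image) with values in `[0,1]`; H and W must be divisible by
#'   `2^depth`.
#' @param heads `"deepest"` (default) returns the final head's probability
#'   map, `"all"` a list of all deep-supervision heads.
#' @param training Use batch statistics (TRUE) or running statistics in
#'   batch norm.
#' @return Probability array `(H, W, 1, N)`, or a list of them.
#' @export
forward <- function(model, x, heads = c("deepest", "all"), training = FALSE) {
  heads <- match.arg(heads)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  check_input_dims(model, dim(x))
  run <- run_program(model, x, training = training, quant = model$quant)
  L <- model$cfg$depth
  if (heads == "deepest") {
    tp_val(run$tape, get(sprintf("head%d", L), envir = run$ids))
  } else {
    lapply(seq_len(L), function(j) {
      tp_val(run$tape, get(sprintf("head%d", j), envir = run$ids))
    })
  }
}

#' Predict probability maps for a set of images
#'
#' Runs the model in evaluation mode (running batch-norm statistics) over
#' images in small batches and returns the deepest head.
#'
#' @param model A `us_model`.
#' @param images Array `(H, W, C, N)` or a list of `(H, W, C)` arrays.
#' @param batch_size Images per forward pass.
#' @return Array `(H, W, N)` of lesion probabilities.
#' @export
predict_probs <- function(model, images, batch_size = 4L) {
  if (is.list(images)) {
    images <- abind4(images)
  }
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  out <- array(0, c(d[1], d[2], d[4]))
  idx <- split(seq_len(d[4]), ceiling(seq_len(d[4]) / batch_size))
  for (b in idx) {
    y <- forward(model, images[, , , b, drop = FALSE], training = FALSE)
    out[, , b] <- y[, , 1, ]
  }
  out
}

abind4 <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

#' Count trainable parameters
#'
#' @param model A `us_model` (or a single internal layer environment).
#' @return Integer number of trainable scalars (batch-norm running
#'   statistics excluded).
#' @export
count_parameters <- function(model) {
  layers <- if (inherits(model, "us_model")) model$layers else list(model)
  total <- 0
  for (ly in layers) {
    for (f in names(layer_param_fields(ly))) {
      n <- length(ly[[f]])
      # quantized layers store codes in Wq/wq; count them as parameters
      if (n == 0 && f == "W") n <- length(ly$Wq)
      if (n == 0 && f == "w") n <- length(ly$wq)
      total <- total + n
    }
  }
  as.integer(total)
}

#' Count FLOPs of a model at a given input size
#'
#' Multiply-accumulate operations of all convolution layers (2-D and the
#' ECA 1-D convolutions) are counted at the given spatial input size;
#' FLOPs are reported as 2 x MACs, following the usual convention for
#' "FLOPs (G)" tables.
#'
#' @param model A `us_model`.
#' @param input_size `c(H, W)` spatial size (default 512 x 512).
#' @return A list with `macs`, `flops` and `flops_g`.
#' @export
count_flops <- function(model, input_size = c(512, 512)) {
  shapes <- list(.input = c(input_size[1], input_size[2],
                            model$cfg$in_channels))
  macs <- 0
  for (st in model$program) {
    s_in <- shapes[[st$input[1]]]
    shapes[[st$out]] <- switch(st$op,
      conv = {
        sp <- model$specs[[st$layer]]
        ho <- (s_in[1] + 2 * st$pad - sp$k) %/% st$stride + 1
        wo <- (s_in[2] + 2 * st$pad - sp$k) %/% st$stride + 1
        macs <- macs + as.numeric(sp$k)^2 * sp$cin * sp$cout * ho * wo
        c(ho, wo, sp$cout)
      },
      concat = {
        cs <- sum(vapply(st$input, function(nm) shapes[[nm]][3], numeric(1)))
        c(s_in[1], s_in[2], cs)
      },
      maxpool = c(s_in[1] / 2, s_in[2] / 2, s_in[3]),
      upsample = c(s_in[1] * 2, s_in[2] * 2, s_in[3]),
      eca = {
        ly <- model$layers[[st$layer]]
        macs <- macs + length(ly$w) * s_in[3]
        s_in
      },
      s_in # relu, sigmoid, add, bn, alias: shape preserved
    )
  }
  list(macs = macs, flops = 2 * macs, flops_g = 2 * macs / 1e9)
}

#' @export
print.us_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<us_model> residual ECA-UNet++ | depth L=%d, base width %d\n",
    cfg$depth, cfg$base_width))
  cat(sprintf("  encoder stages: %s blocks, widths %s\n",
              paste(cfg$blocks, collapse = "/"),
              paste(x$widths$stage_out, collapse = "/")))
  cat(sprintf("  decoder widths (top->bottom): %s\n",
              paste(x$widths$decoder, collapse = "/")))
  cat(sprintf("  ECA after stages: %s\n",
              paste(which(cfg$eca_after_stage), collapse = ",")))
  cat(sprintf("  nodes: %d, supervision heads: %d, parameters: %s%s\n",
              (cfg$depth + 1) * (cfg$depth + 2) / 2, cfg$depth,
              format(count_parameters(x), big.mark = ","),
              if (!is.null(x$quant)) " [INT8]" else ""))
  invisible(x)
}
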