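# Compression pipeline: structured L1 pruning re-wiring, INT8
# quantization resolution, and efficiency accounting.

test_that("fraction-0 pruning is an exact no-op", {
  m <- tiny_model(base_width = 8, depth = 2, seed = 13)
  p <- prune_model(m, fraction = 0)
  expect_identical(count_parameters(p), count_parameters(m))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  expect_equal(forward(p, x), forward(m, x), tolerance = 1e-12)
})

test_that("pruning keeps round((1-f)*C) channels and reduces parameters", {
  m <- build_model(model_config(base_width = 16, depth = 3, seed = 17))
  p <- prune_model(m, fraction = 0.3)
  info <- attr(p, "prune_info")
  # independently pruned (uncoupled) groups hit the exact keep rule:
  inner <- info[grepl("inner", info$group), ]
  expect_true(all(inner$kept == pmax(1, round(0.7 * inner$original))))
  expect_identical(unname(dim(p$layers[["stem.conv"]]$W)[4]),
                   as.integer(round(0.7 * 16)))
  # coupled interfaces keep the union (>= the per-layer keep count)
  iface <- info[grepl("interface", info$group), ]
  expect_true(all(iface$kept >= pmax(1, round(0.7 * iface$original))))
  expect_true(all(iface$kept <= iface$original))
  expect_lt(count_parameters(p), count_parameters(m))
  # forward shape contract unchanged
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_equal(dim(forward(p, x)), dim(forward(m, x)))
  # ECA kernel sizes recomputed from the new channel counts
  for (s in 1:3) {
    eca <- p$layers[[sprintf("eca%d", s)]]
    expect_identical(eca$k, eca_kernel_size(eca$C))
    expect_length(eca$w, eca$k)
  }
  expect_error(prune_model(m, fraction = 1), "fraction")
})

test_that("zero-kernel channels are the ones pruned", {
  m <- tiny_model(base_width = 8, depth = 2, seed = 19)
  # stem output channel 2: zero its kernel; it has the lowest L1 norm
  m$layers[["stem.conv"]]$W[, , , 2] <- 0
  p <- prune_model(m, fraction = 1 / 8 + 1e-9)
  expect_identical(unname(dim(p$layers[["stem.conv"]]$W)[4]), 7L)
  # the surviving channels are exactly the non-zero kernels
  norms <- apply(abs(p$layers[["stem.conv"]]$W), 4, sum)
  expect_true(all(norms > 0))
})

test_that("pruning only zero channels preserves the function", {
  # ECA mixes neighbouring channels with its 1-D kernel, so exact
  # function preservation under channel removal is only defined without
  # attention; zero channel 5 of every coupled group end-to-end.
  m <- build_model(model_config(base_width = 8, depth = 2,
                                blocks = c(1, 1),
                                eca_after_stage = c(FALSE, FALSE),
                                seed = 23))
  zero_bn <- function(name) {
    bn <- m$layers[[name]]
    bn$gamma[5] <- 0
    bn$beta[5] <- 0
    bn$rmean[5] <- 0
  }
  m$layers[["stem.conv"]]$W[, , , 5] <- 0
  zero_bn("stem.bn")
  for (s in 1:2) {
    base <- sprintf("stage%d.block1", s)
    m$layers[[paste0(base, ".conv1")]]$W[, , , 5] <- 0
    zero_bn(paste0(base, ".bn1"))
    m$layers[[paste0(base, ".conv2")]]$W[, , , 5] <- 0
    zero_bn(paste0(base, ".bn2"))
    if (!is.null(m$layers[[paste0(base, ".proj")]])) {
      m$layers[[paste0(base, ".proj")]]$W[, , , 5] <- 0
      zero_bn(paste0(base, ".projbn"))
    }
  }
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y0 <- forward(m, x)
  # 0.08 drops exactly one channel from both the 8-wide (stage 1) and
  # 16-wide (stage 2) groups: the zeroed one
  p <- prune_model(m, fraction = 0.08)
  info <- attr(p, "prune_info")
  expect_true(all(info$kept == info$original - 1))
  expect_lt(count_parameters(p), count_parameters(m))
  expect_equal(forward(p, x), y0, tolerance = 1e-10)
})

test_that("INT8 round-trip error is within the affine resolution bound", {
  set.seed(29)
  w <- runif(1000, -1, 1)
  q <- quantize_tensor(w)
  wd <- dequantize_tensor(q$q, q$scale, q$zp)
  expect_lt(max(abs(wd - w)), 1 / 127)
  expect_true(all(q$q >= -128 & q$q <= 127))
  # identical input gives identical scales (determinism)
  q2 <- quantize_tensor(w)
  expect_identical(q$scale, q2$scale)
  expect_identical(q$zp, q2$zp)
})

test_that("quantization removes FP32 conv weights and stays close in output", {
  pcfg <- phantom_config(image_size = 32, seed = 71)
  calib <- phantom_pairs(pcfg, 16)
  m <- tiny_model(base_width = 8, depth = 2, seed = 31)
  qm <- quantize_model(m, calib)
  for (nm in names(qm$layers)) {
    ly <- qm$layers[[nm]]
    if (ly$type == "conv") {
      expect_null(ly$W)
      expect_true(is.integer(ly$Wq))
    }
    if (ly$type == "eca") expect_null(ly$w)
  }
  # conv weight storage shrinks to ~1/4 of FP32... relative to a 4-byte
  # baseline; our FP arrays are counted at 4 bytes/weight
  expect_lt(conv_weight_bytes(qm) / conv_weight_bytes(m), 0.3)
  # identical calibration set twice gives identical activation ranges
  qm2 <- quantize_model(m, calib)
  for (nm in ls(qm$quant$act)) {
    expect_identical(qm$quant$act[[nm]], qm2$quant$act[[nm]])
  }
  # outputs stay within a small tolerance of FP32 on calibration data
  x <- ultraseg:::pairs_to_arrays(calib[1:4])$images
  y_fp <- forward(m, x)
  y_q <- forward(qm, x)
  expect_lt(mean(abs(y_fp - y_q)), 0.05)
  expect_error(quantize_model(m, list()), "nonempty")
})

test_that("quantized checkpoints round-trip through disk", {
  pcfg <- phantom_config(image_size = 32, seed = 73)
  calib <- phantom_pairs(pcfg, 8)
  m <- tiny_model(base_width = 4, depth = 2, seed = 37)
  qm <- quantize_model(m, calib)
  x <- ultraseg:::pairs_to_arrays(calib[1:2])$images
  y1 <- forward(qm, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(qm, path)
  qm2 <- load_checkpoint(path)
  expect_equal(forward(qm2, x), y1, tolerance = 1e-14)
})

test_that("efficiency report compares variants and round-trips as JSON", {
  m <- tiny_model(base_width = 8, depth = 2, seed = 41)
  p <- prune_model(m, 0.3)
  rep <- efficiency_report(list(original = m, pruned = p),
                           input_size = c(32, 32), measure_latency = FALSE)
  expect_equal(rep$variant, c("original", "pruned"))
  expect_lt(rep$parameters[2], rep$parameters[1])
  expect_lt(rep$flops_g[2], rep$flops_g[1])
  path <- withr::local_tempfile(fileext = ".json")
  write_efficiency_report(rep, path)
  back <- read_efficiency_report(path)
  expect_equal(as.data.frame(back), as.data.frame(rep), tolerance = 1e-12)
})
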