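# Architecture contracts: adaptive ECA kernel rule, attention semantics,
# decoder grid wiring, forward shapes, and parameter/FLOP accounting.

test_that("eca_kernel_size matches direct evaluation of the mapping", {
  # brute-force the rule for every power of two 2^1 .. 2^12
  for (e in 1:12) {
    C <- 2^e
    t <- (log2(C) + 1) / 2
    k <- trunc(t)
    if (k %% 2 == 0) k <- k + 1
    k <- max(1, k)
    expect_identical(eca_kernel_size(C), as.integer(k))
    expect_identical(eca_kernel_size(C) %% 2L, 1L)
  }
  expect_identical(eca_kernel_size(64), 3L)
  expect_identical(eca_kernel_size(256), 5L)
  expect_identical(eca_kernel_size(2), 1L)
  expect_error(eca_kernel_size(0), ">= 1")
})

test_that("eca_forward is shape-preserving pure channel reweighting", {
  set.seed(3)
  U <- array(rnorm(8 * 32 * 32), c(32, 32, 8))
  # zero kernel: sigmoid(0) = 0.5 exactly
  out0 <- eca_forward(U, weights = numeric(3))
  expect_equal(dim(out0), dim(U))
  expect_equal(out0, U * 0.5, ignore_attr = TRUE)
  # random kernel: per-channel constant ratio in (0,1)
  w <- rnorm(3)
  out <- eca_forward(U, weights = w)
  expect_equal(dim(out), dim(U))
  for (c in 1:8) {
    r <- out[, , c] / U[, , c]
    expect_lt(diff(range(r)), 1e-12)
    expect_gt(r[1], 0)
    expect_lt(r[1], 1)
  }
  # closed form with constant input: GAP gives a constant channel vector,
  # interior channels see the full kernel sum
  Uc <- array(2, c(4, 4, 5))
  wc <- c(0.1, 0.2, 0.3)
  outc <- eca_forward(Uc, weights = wc)
  expect_equal(outc[1, 1, 3], 2 * stats::plogis(2 * sum(wc)))
  # edge channel: zero padding drops one tap
  expect_equal(outc[1, 1, 1], 2 * stats::plogis(2 * (wc[2] + wc[3])))
  # batched input keeps shape
  Ub <- array(rnorm(8 * 16 * 16 * 2), c(16, 16, 8, 2))
  expect_equal(dim(eca_forward(Ub, weights = w)), dim(Ub))
})

test_that("decoder grid wiring follows the dense-skip recurrence", {
  for (L in 1:4) {
    cfg <- model_config(base_width = 4, depth = L, blocks = rep(1, 4),
                        seed = 2)
    m <- build_model(cfg)
    g <- model_grid(m)
    expect_equal(nrow(g), (L + 1) * (L + 2) / 2)
    for (r in seq_len(nrow(g))) {
      j <- g$j[r]
      if (j > 0) {
        ins <- g$inputs[[r]]
        expect_length(ins, j + 1)
        i <- g$i[r]
        expect_equal(ins, c(sprintf("x_%d_%d", i, 0:(j - 1)),
                            sprintf("x_%d_%d", i + 1, j - 1)))
      }
    }
    # L supervision heads exist
    expect_length(grep("^head\\d+\\.conv$", names(m$layers)), L)
  }
})

test_that("forward emits full-resolution probability maps per head", {
  m <- tiny_model(base_width = 4, depth = 2, seed = 1)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  outs <- forward(m, x, heads = "all")
  expect_length(outs, 2)
  for (o in outs) {
    expect_equal(dim(o), c(32L, 32L, 1L, 2L))
    expect_true(all(o > 0 & o < 1))
  }
  deepest <- forward(m, x)
  expect_equal(deepest, outs[[2]])
  # indivisible spatial size names the required multiple
  expect_error(forward(m, array(0.5, c(30, 30, 3, 1))), "divisible by 4")
  # zero-weight heads output exactly 0.5 (sigmoid(0))
  for (j in 1:2) {
    hly <- m$layers[[sprintf("head%d.conv", j)]]
    hly$W[] <- 0
    hly$b[] <- 0
  }
  outs0 <- forward(m, x, heads = "all")
  for (o in outs0) expect_true(all(o == 0.5))
})

test_that("parameter counting matches closed-form layer arithmetic", {
  # single 3x3 conv 3->16 with bias: 3*16*9 + 16 = 448
  ly <- withr::with_seed(1, ultraseg:::new_conv_layer(3, 3, 3, 16,
                                                      bias = TRUE))
  expect_identical(count_parameters(ly), 448L)
  # one ECA module with k = 3 has exactly 3 parameters (no bias)
  eca <- withr::with_seed(1, ultraseg:::new_eca_layer(64))
  expect_identical(count_parameters(eca), 3L)
  # ECA-enabled model has exactly sum(k_s) more parameters than without
  cfg_on <- model_config(base_width = 8, depth = 3, seed = 5)
  cfg_off <- model_config(base_width = 8, depth = 3,
                          eca_after_stage = rep(FALSE, 3), seed = 5)
  m_on <- build_model(cfg_on)
  m_off <- build_model(cfg_off)
  ks <- vapply(1:3, function(s) m_on$layers[[sprintf("eca%d", s)]]$k,
               integer(1))
  expect_identical(count_parameters(m_on) - count_parameters(m_off),
                   as.integer(sum(ks)))
  # parameters strictly decrease with width
  m_small <- build_model(model_config(base_width = 4, depth = 3, seed = 5))
  expect_lt(count_parameters(m_small), count_parameters(m_on))
})

test_that("FLOP counting matches hand arithmetic on a depth-1 model", {
  cfg <- model_config(base_width = 4, depth = 1, blocks = 1,
                      eca_after_stage = FALSE, seed = 1)
  m <- build_model(cfg)
  fl <- count_flops(m, c(16, 16))
  # stem 3->4 @16^2; block conv1/conv2 4->4 @8^2; decoder node
  # conv1 (4+4)->4 and conv2 4->4 @16^2; head 1x1 4->1 @16^2
  macs <- 9 * 3 * 4 * 256 + 2 * (9 * 4 * 4 * 64) +
    9 * 8 * 4 * 256 + 9 * 4 * 4 * 256 + 4 * 1 * 256
  expect_equal(fl$macs, macs)
  expect_equal(fl$flops, 2 * macs)
  expect_equal(fl$flops_g, 2 * macs / 1e9)
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model(seed = 9)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y1 <- forward(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(forward(m2, x), y1, tolerance = 1e-14)
})
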