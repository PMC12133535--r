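# Shared fixtures. Everything is generated in code; the expensive
# trained benchmark model is built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

tiny_model <- function(base_width = 4, depth = 2, seed = 11L, ...) {
  build_model(model_config(base_width = base_width, depth = depth,
                           blocks = c(1, 1, 1, 1), seed = seed, ...))
}

random_mask <- function(n = 16, p = 0.4) {
  matrix((stats::runif(n * n) < p) * 1, n, n)
}

# Desk-scale phantom benchmark: the standing conditions used by the
# training, ablation and compression tests (sizes documented in the
# methods vignette): 80x80 phantoms at default difficulty, 200 train /
# 20 val / 50 test, cosine schedule over 8 epochs.
bench_phantom_config <- function(size = 80, seed = 100L) {
  phantom_config(image_size = size, seed = seed)
}

bench_data <- function() {
  if (is.null(.fixture_env$data)) {
    pcfg <- bench_phantom_config()
    .fixture_env$data <- list(
      train = phantom_pairs(pcfg, 200),
      val = phantom_pairs(pcfg, 20, offset = 200),
      test = phantom_pairs(pcfg, 50, offset = 220)
    )
  }
  .fixture_env$data
}

bench_train_config <- function(seed = 1L) {
  train_config(batch_size = 8, max_epochs = 8, patience = 7, seed = seed)
}

# Train the full-depth benchmark model once; reused by the training,
# pruning and quantization acceptance tests.
bench_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    d <- bench_data()
    model <- build_model(model_config(base_width = 8, depth = 4, seed = 1L))
    .fixture_env$fit <- train_segmenter(model, d$train, d$val,
                                        bench_train_config())
  }
  .fixture_env$fit
}

# Test-set Dice of a model under the benchmark conditions
bench_test_dice <- function(model) {
  d <- bench_data()
  probs <- predict_probs(model, lapply(d$test, function(p) p$image))
  mean(vapply(seq_along(d$test), function(i) {
    suppressWarnings(dice((probs[, , i] > 0.5) * 1, d$test[[i]]$mask))
  }, numeric(1)))
}

expect_same_array <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
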