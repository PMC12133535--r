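# Training protocol: composite loss closed forms, cosine schedule,
# early-stopping bookkeeping, determinism, and single-sample capacity.

test_that("composite loss matches closed forms", {
  cfg <- train_config()
  # prediction == target (clipped hard labels): loss ~ 0
  t0 <- array(c(rep(1, 32), rep(0, 32)), c(8, 8, 1, 1))
  p0 <- pmin(pmax(t0, 1e-7), 1 - 1e-7)
  expect_lt(as.numeric(composite_loss(p0, t0, cfg)), 0.01)
  # prediction 0.5 everywhere, half-foreground target: BCE term = ln 2
  ph <- array(0.5, c(8, 8, 1, 1))
  l <- composite_loss(ph, t0, cfg)
  comps <- attr(l, "components")
  expect_equal(unname(comps["bce1"]), log(2), tolerance = 1e-12)
  # deep supervision over identical heads equals the single-head loss
  set.seed(4)
  p <- array(runif(8 * 8), c(8, 8, 1, 1))
  l1 <- composite_loss(list(p, p, p), t0, cfg)
  l2 <- composite_loss(list(p, p, p), t0,
                       train_config(deep_supervision = FALSE))
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-12)
  # non-binary target rejected
  expect_error(composite_loss(p, array(0.3, dim(p)), cfg), "binary")
  # numeric loss agrees with the tape-side loss used in training
  tp <- ultraseg:::tape_new()
  pid <- ultraseg:::op_input(tp, p)
  lid <- ultraseg:::op_bce_dice(tp, pid, t0, cfg$bce_w, cfg$dice_w)
  expect_equal(ultraseg:::tp_val(tp, lid),
               as.numeric(composite_loss(p, t0, cfg)), tolerance = 1e-12)
})

test_that("cosine schedule hits its endpoints and midpoint", {
  cfg <- train_config(lr0 = 0.001, max_epochs = 200)
  expect_equal(cosine_lr(0, cfg), 0.001)
  expect_equal(cosine_lr(200, cfg), 0)
  expect_equal(cosine_lr(100, cfg), 0.0005)
  cfg2 <- train_config(lr0 = 0.01, lr_min = 0.001, max_epochs = 50)
  expect_equal(cosine_lr(50, cfg2), 0.001)
  expect_error(cosine_lr(-1, cfg), "epoch")
  # schedule is monotone non-increasing
  lrs <- vapply(0:200, cosine_lr, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
})

test_that("early stopping fires after exactly `patience` flat epochs", {
  # a constant validation-Dice sequence: first epoch sets the best,
  # then exactly `patience` non-improving epochs trigger the stop
  tr <- early_stopping_trace(rep(0.8, 50), patience = 20)
  expect_equal(tr$stopped_epoch, 21)
  expect_equal(tr$best_epoch, 1)
  expect_equal(tr$stopped_by, "early_stopping")
  # sub-min_delta gains do not count as improvement
  tr2 <- early_stopping_trace(0.5 + (1:50) * 1e-6, patience = 5)
  expect_equal(tr2$stopped_epoch, 6)
  # improvements reset the counter; never exceeds the sequence length
  seq3 <- c(0.5, 0.5, 0.5, 0.6, 0.6, 0.6, 0.6)
  tr3 <- early_stopping_trace(seq3, patience = 3)
  expect_equal(tr3$stopped_epoch, 7)
  expect_equal(tr3$best_epoch, 4)
  tr4 <- early_stopping_trace(seq(0.1, 0.9, length.out = 30), patience = 5)
  expect_equal(tr4$stopped_by, "max_epochs")
  expect_equal(tr4$stopped_epoch, 30)
})

test_that("the training loop applies the early-stopping protocol online", {
  pcfg <- phantom_config(image_size = 32, seed = 33)
  pairs <- phantom_pairs(pcfg, 4)
  m <- tiny_model(base_width = 4, depth = 2, seed = 21)
  cfg <- train_config(batch_size = 4, max_epochs = 8, patience = 2,
                      seed = 2)
  fit <- train_segmenter(m, pairs, pairs, cfg)
  # the loop's decisions replay exactly from its own history
  tr <- early_stopping_trace(fit$history$val_dice, cfg$patience,
                             cfg$min_delta)
  expect_equal(fit$stopped_epoch, tr$stopped_epoch)
  expect_equal(fit$best_epoch, tr$best_epoch)
  expect_equal(fit$stopped_by, tr$stopped_by)
  expect_lte(fit$stopped_epoch, cfg$max_epochs)
  # checkpointed Dice equals the max of the history
  expect_equal(fit$best_val_dice, max(fit$history$val_dice),
               tolerance = cfg$min_delta)
})

test_that("training is deterministic under a fixed seed", {
  pcfg <- phantom_config(image_size = 32, seed = 44)
  pairs <- phantom_pairs(pcfg, 6)
  run <- function() {
    m <- tiny_model(base_width = 4, depth = 2, seed = 5)
    train_segmenter(m, pairs[1:4], pairs[5:6],
                    train_config(batch_size = 2, max_epochs = 2,
                                 patience = 1, seed = 9))
  }
  f1 <- run()
  f2 <- run()
  expect_equal(f1$history, f2$history, tolerance = 1e-14)
})

test_that("a two-head model overfits one phantom (capacity sanity)", {
  # scaled-down analogue of the one-sample overfit check run by the
  # acceptance suite on the full-depth model
  pcfg <- phantom_config(image_size = 32, seed = 55)
  pair <- phantom_pairs(pcfg, 1)
  m <- tiny_model(base_width = 8, depth = 2, seed = 6)
  cfg <- train_config(batch_size = 1, max_epochs = 300, patience = 299,
                      seed = 3)
  fit <- train_segmenter(m, pair, pair, cfg)
  expect_gt(max(fit$history$val_dice), 0.95)
})

test_that("tidy/glance/autoplot work on fits", {
  pcfg <- phantom_config(image_size = 32, seed = 66)
  pairs <- phantom_pairs(pcfg, 2)
  m <- tiny_model(base_width = 4, depth = 2, seed = 7)
  fit <- train_segmenter(m, pairs, pairs,
                         train_config(batch_size = 2, max_epochs = 2,
                                      patience = 1, seed = 1))
  td <- tidy(fit)
  expect_true(all(c("epoch", "lr", "train_loss", "val_dice") %in% names(td)))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
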