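test_that("learning-rate schedules follow their stated recurrences", {
  cfg <- train_config(schedule_mode = "epoch_decay")
  expect_equal(lr_at_epoch(cfg, 0), 6e-5)
  expect_equal(lr_at_epoch(cfg, 1), 4.8e-5)
  lrs <- vapply(0:20, function(e) lr_at_epoch(cfg, e), numeric(1))
  expect_equal(lrs[-1] / lrs[-21], rep(0.8, 20))

  # plateau mode: strictly improving validation loss never decays
  pcfg <- train_config(schedule_mode = "plateau", plateau_patience = 2L)
  improving <- seq(1, 0.1, length.out = 12)
  expect_equal(lr_at_epoch(pcfg, 12, improving), 6e-5)
  # a stalled series decays once per patience window
  stalled <- c(1, 0.5, rep(0.5, 6))
  expect_equal(lr_at_epoch(pcfg, 8, stalled), 6e-5 * 0.8^3)
  expect_equal(lr_at_epoch(pcfg, 0, stalled), 6e-5)
})

test_that("loss smoothing implements the EMA recursion", {
  expect_equal(smooth_losses(rep(3.5, 10), 0.2), rep(3.5, 10))
  x <- c(2, 1, 4, 0.5)
  expect_equal(smooth_losses(x, 1), x)
  expect_equal(smooth_losses(c(1, 0, 0), 0.5), c(1, 0.5, 0.25))
  expect_error(smooth_losses(numeric(0), 0.5), "empty")
  expect_error(smooth_losses(c(1, 2), 0), "alpha")
})

test_that("hybrid loss has the analytic uniform and saturated limits", {
  H <- 6L; W <- 6L
  mask <- matrix(sample(0:2, H * W, TRUE), H, W)
  unif <- array(0, dim = c(H, W, 3))
  l <- hybrid_loss(unif, mask, loss_weights = c(1, 0))
  expect_equal(as.numeric(l), log(3), tolerance = 1e-12)

  # saturated correct logits drive both components to zero
  sat <- array(-1e4, dim = c(H, W, 3))
  for (k in 0:2) sat[, , k + 1][mask == k] <- 1e4
  ls <- hybrid_loss(sat, mask)
  expect_lt(as.numeric(ls), 1e-6)
  expect_lt(attr(ls, "ce"), 1e-7)
  expect_lt(attr(ls, "dice"), 1e-5)

  expect_error(hybrid_loss(unif, matrix(3L, H, W)), "labels outside")
})

test_that("hybrid loss equals a hand-rolled CE + soft-Dice computation", {
  set.seed(31)
  for (rep in 1:5) {
    K <- sample(2:3, 1)
    z <- array(rnorm(4 * 4 * K), dim = c(4, 4, K))
    mask <- matrix(sample(0:(K - 1), 16, TRUE), 4, 4)
    w <- runif(2, 0.2, 2)
    got <- hybrid_loss(z, mask, loss_weights = w)
    # independent oracle: direct per-pixel formulas
    zm <- matrix(z, 16, K)
    p <- exp(zm) / rowSums(exp(zm))
    ce <- -mean(log(p[cbind(1:16, as.integer(mask) + 1L)]))
    y <- matrix(0, 16, K); y[cbind(1:16, as.integer(mask) + 1L)] <- 1
    dices <- vapply(1:K, function(k) {
      (2 * sum(p[, k] * y[, k]) + 1e-7) / (sum(p[, k]) + sum(y[, k]) + 1e-7)
    }, numeric(1))
    want <- w[1] * ce + w[2] * (1 - mean(dices))
    expect_equal(as.numeric(got), want, tolerance = 1e-9)
  }
})

test_that("one small gradient step strictly decreases the loss", {
  m <- build_model(model_config("tiny"), seed = 2)
  s <- generate_sample(easy_train_spec(), seed = 400)
  cfg <- train_config(initial_lr = 1e-4, epochs = 1L, batch_size = 1L,
                      weight_decay = 0, seed = 1)
  l0 <- as.numeric(hybrid_loss(model_forward(m, s$image), s$mask))
  res <- train_model(m, list(s), list(s), cfg)
  l1 <- as.numeric(hybrid_loss(model_forward(res$model, s$image), s$mask))
  expect_lt(l1, l0)
})

test_that("k-fold assignment is balanced, exhaustive and seeded", {
  f <- kfold_assign(23, 5, seed = 3)
  expect_length(f, 23)
  expect_setequal(unique(f), 1:5)
  expect_lte(diff(range(table(f))), 1)
  expect_identical(f, kfold_assign(23, 5, seed = 3))
  expect_false(identical(f, kfold_assign(23, 5, seed = 4)))
  expect_error(kfold_assign(3, 5), "k <= n")
})

test_that("short training runs are reproducible and fully book-kept", {
  train <- lapply(1:4, function(i) generate_sample(easy_train_spec(), seed = 500 + i))
  val <- lapply(1:2, function(i) generate_sample(easy_train_spec(), seed = 600 + i))
  m <- build_model(model_config("tiny"), seed = 3)
  cfg <- train_config(initial_lr = 5e-4, epochs = 2L, batch_size = 2L, seed = 11)
  r1 <- train_model(m, train, val, cfg)
  r2 <- train_model(m, train, val, cfg)
  expect_identical(r1$history$batches, r2$history$batches)
  expect_identical(r1$model$params, r2$model$params)

  b <- r1$history$batches
  e <- r1$history$epochs
  expect_identical(nrow(b), 4L)            # 2 epochs x 2 batches
  expect_identical(nrow(e), 2L)
  expect_true(all(c("train_loss", "val_loss", "smoothed_train_loss",
                    "smoothed_val_loss", "lr") %in% names(b)))
  expect_true(all(c("lr", "precision", "miou") %in% names(e)))
  # smoothed series match the exported EMA on the raw series
  expect_equal(b$smoothed_train_loss, smooth_losses(b$train_loss, cfg$smoothing_alpha))
  expect_equal(b$smoothed_val_loss, smooth_losses(b$val_loss, cfg$smoothing_alpha))
  expect_true(all(e$precision >= 0 & e$precision <= 1))
  expect_true(all(e$miou >= 0 & e$miou <= 1))
})

test_that("epoch-decay mode shrinks the recorded learning rate by 0.8 per epoch", {
  train <- lapply(1:2, function(i) generate_sample(easy_train_spec(), seed = 700 + i))
  m <- build_model(model_config("tiny"), seed = 4)
  cfg <- train_config(schedule_mode = "epoch_decay", initial_lr = 6e-5,
                      epochs = 3L, batch_size = 2L, seed = 1)
  r <- train_model(m, train, train, cfg)
  expect_equal(r$history$epochs$lr, 6e-5 * 0.8^(0:2))
})
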