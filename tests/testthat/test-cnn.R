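test_that("architecture audit: 5487 trainable parameters, seeded init, output shape", {
  m <- build_cnn(128, seed = 1)
  expect_equal(cnn_parameter_count(m), 5 * 64 * 17 + 5 + 25 + 5 + 10 + 2)
  expect_equal(cnn_parameter_count(m), 5487)
  m2 <- build_cnn(128, seed = 1)
  expect_identical(m, m2)
  m3 <- build_cnn(128, seed = 2)
  expect_false(identical(m$conv_w, m3$conv_w))
  # same-padding convolution keeps a 1 x T series per filter
  fw <- aadecode:::.cnn_fwd(m, array(rnorm(64 * 50), c(64, 50, 1)),
                            keep_cache = TRUE)
  expect_equal(fw$cache$T_out, 50)
  expect_error(build_cnn(10, padding = "valid"), ">= 17")
})

test_that("forward pass produces valid probabilities; zero weights give 0.5/0.5", {
  m <- build_cnn(32, seed = 1)
  for (nm in c("conv_w", "conv_b", "fc1_w", "fc1_b", "fc2_w", "fc2_b")) {
    m[[nm]] <- m[[nm]] * 0
  }
  p <- cnn_forward(m, matrix(rnorm(64 * 32), 64))
  expect_equal(as.numeric(p), c(0.5, 0.5))
  m1 <- build_cnn(32, seed = 5)
  set.seed(8)
  pp <- cnn_forward(m1, array(rnorm(64 * 32 * 9), c(64, 32, 9)))
  expect_equal(unname(rowSums(pp)), rep(1, 9), tolerance = 1e-9)
  expect_true(all(pp >= 0 & pp <= 1))
  expect_error(cnn_forward(m1, matrix(0, 63, 32)), "channels")
})

test_that("miniature forward pass matches a hand-computed oracle", {
  # 1 filter, 2 channels, width 2, valid padding, T = 3
  m <- build_cnn(3, seed = 1, n_channels = 2, n_filters = 1,
                 filter_width = 2, padding = "valid")
  m$conv_w <- array(c(1, -1, 2, 0.5), dim = c(1, 2, 2))  # w[ch, k]
  m$conv_b <- 0.25
  m$fc1_w <- matrix(2, 1, 1); m$fc1_b <- -1
  m$fc2_w <- matrix(c(1, -1), 2, 1); m$fc2_b <- c(0.1, -0.1)
  x <- matrix(c(1, 2, 3, 4, 5, 6), 2)      # channels x T: rows (1,3,5),(2,4,6)
  # conv at t: 1*x1[t] -1*x2[t] + 2*x1[t+1] + 0.5*x2[t+1] + 0.25
  # t=1: 1-2+6+2+0.25 = 7.25 ; t=2: 3-4+10+3+0.25 = 12.25
  # ReLU unchanged; average pool: 9.75
  # fc1: 2*9.75 - 1 = 18.5 ; sigmoid ~ 1/(1+exp(-18.5))
  s <- 1 / (1 + exp(-18.5))
  z <- c(s + 0.1, -s - 0.1)
  pr <- exp(z - max(z)); pr <- pr / sum(pr)
  p <- cnn_forward(m, x)
  expect_equal(as.numeric(p), pr, tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  m <- build_cnn(6, seed = 3, n_channels = 3, n_filters = 2,
                 filter_width = 3, init_sd = 0.4)
  set.seed(11)
  x <- array(rnorm(3 * 6 * 5), c(3, 6, 5))
  y <- c(1, 2, 1, 2, 1)
  lg <- aadecode:::.cnn_loss_grad(m, x, y)
  for (nm in c("conv_w", "conv_b", "fc1_w", "fc1_b", "fc2_w", "fc2_b")) {
    g <- lg$grads[[nm]]
    num <- g * 0
    for (i in seq_along(m[[nm]])) {
      e <- 1e-6
      mp <- m; mp[[nm]][i] <- mp[[nm]][i] + e
      mm_ <- m; mm_[[nm]][i] <- mm_[[nm]][i] - e
      num[i] <- (aadecode:::.cnn_loss_grad(mp, x, y)$loss -
                   aadecode:::.cnn_loss_grad(mm_, x, y)$loss) / (2 * e)
    }
    expect_lt(max(abs(num - g)) / max(1e-8, max(abs(g))), 1e-4)
  }
})

test_that("the learning-rate schedule steps after epochs 10 and 35", {
  cfg <- train_config()
  expect_equal(learning_rate_at(cfg, 5), 0.09)
  expect_equal(learning_rate_at(cfg, 10), 0.09)
  expect_equal(learning_rate_at(cfg, 20), 0.045)
  expect_equal(learning_rate_at(cfg, 50), 0.0225)
})

test_that("training is deterministic and selects the epoch with minimal validation loss", {
  set.seed(5)
  n <- 60
  x <- array(rnorm(8 * 10 * n), c(8, 10, n))
  lab <- rep(c("left", "right"), n / 2)
  x[1, , lab == "left"] <- x[1, , lab == "left"] + 1.5
  mk <- function(idx) {
    structure(list(x = x[, , idx, drop = FALSE],
                   label = factor(lab[idx], levels = c("left", "right")),
                   subject_id = rep(1, length(idx)),
                   trial_id = rep(1, length(idx)),
                   start_sample = seq_along(idx), fs = 10, T = 10L),
              class = "decision_windows")
  }
  cfg <- train_config(epochs = 8, seed = 2)
  tw <- mk(1:40); vw <- mk(41:60)
  tm1 <- train_cnn(tw, vw, cfg)
  tm2 <- train_cnn(tw, vw, cfg)
  expect_identical(tm1$model, tm2$model)
  expect_true(tm1$selected_epoch >= 1 && tm1$selected_epoch <= 8)
  expect_equal(tm1$selected_epoch, which.min(tm1$validation_loss_curve))
  expect_equal(nrow(tm1$training_log), 8)
})

test_that("evaluation counts argmax hits, averages runs, and rejects empty input", {
  set.seed(6)
  n <- 1000
  x <- array(rnorm(4 * 6 * n), c(4, 6, n))
  lab <- factor(sample(c("left", "right"), n, replace = TRUE),
                levels = c("left", "right"))
  wins <- structure(list(x = x, label = lab, subject_id = rep(1, n),
                         trial_id = rep(1, n), start_sample = 1:n,
                         fs = 10, T = 6L),
                    class = "decision_windows")
  m <- build_cnn(6, seed = 1, n_channels = 4, n_filters = 2,
                 filter_width = 3)
  # random model vs random labels: near 50%
  acc <- evaluate_cnn(m, wins)$accuracy
  expect_gt(acc, 45); expect_lt(acc, 55)
  # an oracle model that always matches the label scores 100%
  oracle <- m
  oracle$conv_w <- oracle$conv_w * 0
  oracle$conv_b <- c(1, 0)
  oracle$fc1_w <- matrix(0, 2, 2); oracle$fc1_b <- c(0, 0)
  # make output depend on channel 1 mean sign: instead, force constant left
  oracle$fc2_w <- matrix(0, 2, 2); oracle$fc2_b <- c(10, -10)
  all_left <- wins; all_left$label <- factor(rep("left", n),
                                             levels = c("left", "right"))
  expect_equal(evaluate_cnn(oracle, all_left)$accuracy, 100)
  # two folds are averaged arithmetically
  expect_equal(fold_average(c(80, 90)), 85)
  empty <- wins; empty$label <- empty$label[0]
  expect_error(evaluate_cnn(m, empty), "empty")
})

test_that("training errors are explicit for degenerate inputs", {
  cfg <- train_config(epochs = 1)
  expect_error(train_cnn(list(), list(), cfg))
})
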