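test_that("cyclic learning rate follows the triangular schedule", {
  cfg <- training_config()                       # triangular2, step 2000
  expect_equal(cyclic_lr(0, cfg), 5e-5)
  tri <- training_config(lr_policy = "triangular")
  expect_equal(cyclic_lr(2000, tri), 5e-4)       # first peak
  expect_equal(cyclic_lr(4000, tri), 5e-5)       # back to base
  expect_equal(cyclic_lr(6000, tri), 5e-4)       # second peak, no decay
  # triangular2: second peak at half amplitude
  expect_equal(cyclic_lr(6000, cfg), 5e-5 + (5e-4 - 5e-5) / 2)
  expect_equal(cyclic_lr(2000, cfg), 5e-4)       # first peak undamped
  # piecewise-linear midpoints
  expect_equal(cyclic_lr(1000, tri), (5e-5 + 5e-4) / 2)
})

test_that("class weights equalize the class loss contributions", {
  expect_equal(unname(class_weights(c(0, 0, 1, 1))), c(1, 1))
  w <- class_weights(c(rep("correct", 85), rep("incorrect", 35)))
  expect_equal(unname(w), c(120 / 170, 120 / 70))
  expect_equal(unname(w["negative"] * 85), unname(w["positive"] * 35))
  w2 <- class_weights(c(rep(0, 99), 1))
  expect_equal(unname(w2["positive"] / w2["negative"]), 99)
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("dense parameter count matches the closed form", {
  # input 3, hidden [2]: 3*2+2 + (2*1+1) = 11
  expect_equal(count_parameters(network_spec(3, 2))$dense, 11)
  p <- count_parameters(network_spec())   # 198 -> 192-128-64-32 -> 1
  widths <- c(198, 192, 128, 64, 32, 1)
  expect_equal(p$dense, sum(widths[-6] * widths[-1] + widths[-1]))
  expect_equal(p$batchnorm, 2 * (192 + 128 + 64 + 32))
})

test_that("default configuration echoes the documented values", {
  spec <- network_spec()
  expect_equal(spec$hidden_sizes, c(192L, 128L, 64L, 32L))
  expect_equal(spec$dropout_rate, 0.25)
  expect_equal(spec$bn_momentum, 0.8)
  cfg <- training_config()
  expect_equal(cfg$epochs, 1000L)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$step_size, 2000L)
  expect_equal(prediction_config()$cutoff, 0.2)
  expect_error(network_spec(dropout_rate = 1), "dropout")
  expect_error(training_config(base_lr = 1e-3, max_lr = 1e-4), "base_lr")
})

test_that("batch-norm running statistics follow the momentum contract", {
  # two hand-fed batches through a 1-hidden-layer net with known activations
  spec <- network_spec(input_dim = 2, hidden_sizes = 2, dropout_rate = 0,
                       bn_momentum = 0.8)
  net <- condylecast:::init_network(spec, 1)
  # identity weights, zero bias: activations = relu(X)
  net$hidden[[1]]$W <- diag(2)
  net$hidden[[1]]$b <- c(0, 0)
  X1 <- rbind(c(1, 2), c(3, 6))        # batch mean (2,4), biased var (1,4)
  f1 <- condylecast:::forward_pass(net, X1, spec, training = TRUE)
  expect_equal(f1$net$hidden[[1]]$run_mean, 0.8 * c(0, 0) + 0.2 * c(2, 4))
  expect_equal(f1$net$hidden[[1]]$run_var, 0.8 * c(1, 1) + 0.2 * c(1, 4))
  X2 <- rbind(c(5, 0), c(7, 2))        # mean (6,1), var (1,1)
  f2 <- condylecast:::forward_pass(f1$net, X2, spec, training = TRUE)
  expect_equal(f2$net$hidden[[1]]$run_mean,
               0.8 * f1$net$hidden[[1]]$run_mean + 0.2 * c(6, 1))
  expect_equal(f2$net$hidden[[1]]$run_var,
               0.8 * f1$net$hidden[[1]]$run_var + 0.2 * c(1, 1))
  # inference mode uses the running statistics, not the batch's
  fe <- condylecast:::forward_pass(f2$net, X1, spec, training = FALSE)
  expect_identical(fe$net$hidden[[1]]$run_mean, f2$net$hidden[[1]]$run_mean)
})

test_that("a separable two-blob problem is learned to >= 0.99 training accuracy", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100 * 10, 0), 100), matrix(rnorm(100 * 10, 3), 100))
  y <- rep(c(0, 1), each = 100)
  spec <- network_spec(input_dim = 10, hidden_sizes = c(16, 8))
  # schedule scaled to the problem: 50 epochs x 7 batches = 350 iterations
  cfg <- training_config(base_lr = 5e-4, max_lr = 5e-3, step_size = 100,
                         epochs = 50, rng_seed = 7)
  m <- train_classifier(X, y, spec, cfg)
  pred <- predict_seating(m, X, prediction_config(0.5))
  expect_gte(mean((pred$confidence >= 0.5) == (y == 1)), 0.99)
  expect_length(m$loss_trace, 50)
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
})

test_that("training is reproducible from the seed", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rep(c(0, 1), 30)
  spec <- network_spec(input_dim = 5, hidden_sizes = c(8, 4))
  cfg <- training_config(epochs = 10, rng_seed = 3)
  m1 <- train_classifier(X, y, spec, cfg)
  m2 <- train_classifier(X, y, spec, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$net, m2$net)
  m3 <- train_classifier(X, y, spec, training_config(epochs = 10, rng_seed = 4))
  expect_false(identical(m1$loss_trace, m3$loss_trace))
})

test_that("training rejects malformed inputs", {
  X <- matrix(rnorm(40), 10, 4)
  spec <- network_spec(input_dim = 5, hidden_sizes = 3)
  expect_error(train_classifier(X, rep(c(0, 1), 5), spec,
                                training_config(epochs = 1)), "width")
  expect_error(train_classifier(X, rep(1, 10),
                                network_spec(input_dim = 4, hidden_sizes = 3),
                                training_config(epochs = 1)), "both classes")
})

test_that("prediction thresholds at the inclusive cutoff and is monotone", {
  set.seed(4)
  X <- rbind(matrix(rnorm(30 * 6, -1), 30), matrix(rnorm(30 * 6, 1), 30))
  y <- rep(c(0, 1), each = 30)
  spec <- network_spec(input_dim = 6, hidden_sizes = 4, dropout_rate = 0)
  m <- train_classifier(X, y, spec,
                        training_config(base_lr = 1e-3, max_lr = 1e-2,
                                        step_size = 50, epochs = 20,
                                        rng_seed = 5))
  pred <- predict_seating(m, X)
  expect_true(all(pred$confidence > 0 & pred$confidence < 1))
  # boundary: confidence exactly at cutoff is incorrect (>=)
  expect_equal(ifelse(pred$confidence >= 0.2, "incorrect", "correct"),
               pred$label)
  # raising the cutoff never flips correct -> incorrect
  lo <- predict_seating(m, X, prediction_config(0.2))
  hi <- predict_seating(m, X, prediction_config(0.6))
  expect_true(all(!(lo$label == "correct" & hi$label == "incorrect")))
  expect_error(predict_seating(m, X[, 1:3]), "width")
})

test_that("a trained classifier survives a save/load round-trip", {
  set.seed(6)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rep(c(0, 1), 20)
  m <- train_classifier(X, y, network_spec(input_dim = 5, hidden_sizes = 4),
                        training_config(epochs = 5, rng_seed = 8))
  f <- tempfile(fileext = ".json")
  save_classifier(m, f)
  m2 <- load_classifier(f)
  expect_equal(predict_seating(m2, X)$confidence,
               predict_seating(m, X)$confidence)
})
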