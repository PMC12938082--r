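# small deterministic feature-map fixtures
fake_fmaps <- function(n, shape = c(64L, 8L, 32L), centers, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    array(rnorm(prod(shape), mean = centers[i]), dim = shape)
  }))
}

test_that("the bundled backbone is deterministic, frozen and well-shaped", {
  bb <- tiny_backbone()
  img <- with_seed(4, array(runif(256 * 256 * 3), c(256, 256, 3)))
  f1 <- extract_feature_map(img, bb)
  f2 <- extract_feature_map(img, bb)
  expect_identical(f1, f2)
  expect_equal(dim(f1), bb$spec$feature_map_shape)
  # a globally rescaled image yields different features
  f_half <- extract_feature_map(img * 0.5, bb)
  expect_false(isTRUE(all.equal(f1, f_half)))
  expect_error(extract_feature_map(matrix(1, 10, 10), bb), "array")
  expect_error(backbone_spec(trainable_top_layers = -1), ">= 0")
})

test_that("sequence reshaping matches the nested-loop oracle", {
  for (C in c(64L, 128L)) {
    fmap <- with_seed(C, array(rnorm(7 * 7 * C), c(7, 7, C)))
    got <- sequence_from_feature_map(fmap)
    expect_equal(dim(got), c(9L, 64L))
    expect_equal(got, sequence_bruteforce(fmap))
  }
  # constant map -> every output equals the constant
  const <- array(2.5, c(7, 7, 128))
  expect_true(all(sequence_from_feature_map(const) == 2.5))
  expect_error(sequence_from_feature_map(array(1, c(7, 7, 32)), pad = FALSE),
               "channels")
  padded <- sequence_from_feature_map(array(1, c(7, 7, 32)), pad = TRUE)
  expect_equal(dim(padded), c(9L, 64L))
})

test_that("a linear SVM fits linearly separable features perfectly", {
  n <- 24
  labs <- rep(c("a", "b"), each = n / 2)
  fm <- fake_fmaps(n, centers = ifelse(labs == "a", -1, 1), seed = 2)
  m <- train_model(fm, labs, kind = "cnn_svm")
  pred <- predict(m, fm)
  expect_equal(pred$labels, labs)
  expect_null(pred$probabilities)
  expect_false(is.null(pred$margins))
})

test_that("training validates inputs and the frozen-backbone contract", {
  fm <- fake_fmaps(6, centers = rep(0, 6), seed = 3)
  expect_error(train_model(fm, rep("a", 6), kind = "cnn_svm"),
               "two classes")
  expect_error(train_model(fm, rep(c("a", "b"), 3), kind = "cnn"),
               "validation")
  bb <- tiny_backbone()
  bb$spec$trainable_top_layers <- 5L
  expect_error(train_model(fm, rep(c("a", "b"), 3), fm[1:2], c("a", "b"),
                           kind = "cnn_svm", backbone = bb),
               "frozen")
})

test_that("backbone weights are untouched by training", {
  bb <- tiny_backbone()
  hash_before <- lungcycler:::backbone_weight_hash(bb)
  labs <- rep(c("a", "b"), each = 6)
  fm <- fake_fmaps(12, centers = ifelse(labs == "a", -1, 1), seed = 6)
  m <- train_model(fm, labs, fm[c(1, 12)], labs[c(1, 12)], kind = "cnn",
                   config = train_config(epochs = 5, patience = 2,
                                         seed = 1),
                   backbone = bb)
  expect_identical(lungcycler:::backbone_weight_hash(bb), hash_before)
  expect_identical(m$backbone_hash, hash_before)
})

test_that("early stopping halts within budget and restores the best epoch", {
  labs <- rep(c("a", "b"), each = 10)
  fm <- fake_fmaps(20, centers = ifelse(labs == "a", -2, 2), seed = 4)
  cfg <- train_config(epochs = 100, patience = 15, seed = 2)
  m <- train_model(fm, labs, fm[c(1, 20)], labs[c(1, 20)], kind = "cnn",
                   config = cfg)
  h <- m$history$history
  expect_lte(nrow(h), 100L)
  best <- m$history$best_epoch
  # stopped exactly patience epochs after the best epoch (or hit the cap)
  expect_true(nrow(h) == best + 15L || nrow(h) == 100L)
  expect_equal(m$history$best_val_loss, min(h$val_loss), tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  labs <- rep(c("a", "b"), each = 8)
  fm <- fake_fmaps(16, centers = ifelse(labs == "a", -1, 1), seed = 5)
  cfg <- train_config(epochs = 10, patience = 5, seed = 77)
  m1 <- train_model(fm, labs, fm[c(1, 16)], labs[c(1, 16)], kind = "cnn",
                    config = cfg)
  m2 <- train_model(fm, labs, fm[c(1, 16)], labs[c(1, 16)], kind = "cnn",
                    config = cfg)
  expect_identical(m1$fit$params, m2$fit$params)
  expect_identical(m1$history$history, m2$history$history)
})

test_that("softmax predictions are normalized and label-consistent", {
  labs <- rep(c("a", "b", "c"), each = 8)
  fm <- fake_fmaps(24, centers = match(labs, c("a", "b", "c")) - 2, seed = 8)
  m <- train_model(fm, labs, fm[c(1, 9, 17)], labs[c(1, 9, 17)],
                   kind = "cnn",
                   config = train_config(epochs = 30, patience = 10,
                                         seed = 3))
  p <- predict(m, fm)
  expect_equal(rowSums(p$probabilities), rep(1, 24), tolerance = 1e-6)
  expect_equal(p$labels,
               m$classes[max.col(p$probabilities, ties.method = "first")])
  # converged separable run classifies its training set
  expect_gte(mean(p$labels == labs), 0.95)
})

test_that("the CNN-LSTM head trains on sequences and predicts probabilities", {
  labs <- rep(c("a", "b"), each = 8)
  fm <- fake_fmaps(16, shape = c(7L, 7L, 64L),
                   centers = ifelse(labs == "a", -1, 1), seed = 9)
  cfg <- train_config(epochs = 15, patience = 6, lstm_units = 16,
                      fc_units = 32, seed = 11)
  m <- train_model(fm, labs, fm[c(1, 16)], labs[c(1, 16)],
                   kind = "cnn_lstm", config = cfg)
  p <- predict(m, fm)
  expect_equal(rowSums(p$probabilities), rep(1, 16), tolerance = 1e-6)
  expect_gte(mean(p$labels == labs), 0.9)
})

test_that("BiLSTM backpropagation matches numerical gradients", {
  m <- lungcycler:::bilstm_model(D = 3, K = 2, H = 4, fc_units = 5,
                                 l2 = 1e-3, dropout = 0)
  params <- with_seed(13, m$init())
  X <- with_seed(14, array(rnorm(2 * 9 * 3), c(2, 9, 3)))
  Y <- lungcycler:::onehot(c(1L, 2L), 2L)
  lg <- m$loss_grad(params, X, Y, train = FALSE)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- with_seed(15, sample(length(params[[nm]]),
                                min(5, length(params[[nm]]))))
    for (i in idx) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- m$loss_grad(p2, X, Y, train = FALSE)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- m$loss_grad(p2, X, Y, train = FALSE)$loss
      num <- (up - dn) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training logs serialize to JSON", {
  labs <- rep(c("a", "b"), each = 6)
  fm <- fake_fmaps(12, centers = ifelse(labs == "a", -1, 1), seed = 10)
  m <- train_model(fm, labs, fm[c(1, 12)], labs[c(1, 12)], kind = "cnn",
                   config = train_config(epochs = 5, patience = 2, seed = 1))
  f <- tempfile(fileext = ".json")
  write_training_log(m, f)
  log <- jsonlite::read_json(f)
  expect_equal(log$kind, "cnn")
  expect_equal(length(log$epochs), nrow(m$history$history))
  unlink(f)
})
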