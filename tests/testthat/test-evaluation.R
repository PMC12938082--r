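test_that("split configuration validates its proportions", {
  expect_error(split_config(0.8, 0.1, 0.2), "sum to 1")
  expect_error(split_config(1.0, 0.0, 0.0), "in \\(0, 1\\)")
  expect_error(split_config(n_repeats = 0), "n_repeats")
})

test_that("stratified splits hit the 80/10/10 arithmetic exactly", {
  labels <- rep(lung_sound_classes(), each = 100)
  sp <- split_dataset(labels, split_config(seed = 3))
  expect_length(sp$train, 320L)
  expect_length(sp$val, 40L)
  expect_length(sp$test, 40L)
  # stratification: exactly 10 test items per class
  expect_equal(unname(table(labels[sp$test])), array(rep(10L, 4)))
  expect_equal(unname(table(labels[sp$val])), array(rep(10L, 4)))
  # disjoint and exhaustive
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_idx), seq_along(labels))
  expect_equal(anyDuplicated(all_idx), 0L)
})

test_that("splits are reproducible and differ across repeats", {
  labels <- rep(c("x", "y"), each = 30)
  cfg <- split_config(seed = 12, n_repeats = 5)
  a <- split_dataset(labels, cfg, repeat_index = 2)
  b <- split_dataset(labels, cfg, repeat_index = 2)
  expect_identical(a, b)
  c_ <- split_dataset(labels, cfg, repeat_index = 3)
  expect_false(identical(a$test, c_$test))
})

test_that("infeasible class sizes raise an error", {
  labels <- c(rep("big", 50), rep("small", 3))
  expect_error(split_dataset(labels, split_config(seed = 1)), "too few")
})

test_that("subject-level splits keep whole subjects together", {
  labels <- rep(c("x", "y"), each = 30)
  subjects <- rep(1:20, each = 3)
  sp <- split_dataset(labels, split_config(unit = "subject", seed = 4),
                      subjects = subjects)
  for (part in sp) {
    expect_true(all(table(subjects) [unique(subjects[part])] ==
                      table(subjects[part])))
  }
  expect_equal(sort(unname(unlist(sp))), seq_along(labels))
})

test_that("confusion matrices count labels like a tally loop", {
  classes <- c("a", "b", "c")
  truth <- c("a", "a", "b", "c", "c", "c")
  pred <- c("a", "b", "b", "c", "a", "c")
  cm <- confusion_matrix(truth, pred, classes)
  expect_equal(unclass(cm)["a", "b"], 1L)
  expect_equal(sum(cm), 6)
  expect_equal(rowSums(cm), c(a = 2, b = 1, c = 3))
  # diagonal when all correct
  cm2 <- confusion_matrix(truth, truth, classes)
  expect_true(all(cm2[upper.tri(cm2) | lower.tri(cm2)] == 0))
  # permuting class order permutes rows and columns consistently
  cm3 <- confusion_matrix(truth, pred, rev(classes))
  expect_equal(unclass(cm3)[rev(classes), rev(classes)],
               unclass(cm)[rev(classes), rev(classes)])
  # random labels against a counting oracle
  set.seed(10)
  t2 <- sample(classes, 200, replace = TRUE)
  p2 <- sample(classes, 200, replace = TRUE)
  cm4 <- confusion_matrix(t2, p2, classes)
  for (i in classes) for (j in classes) {
    expect_equal(unclass(cm4)[i, j], sum(t2 == i & p2 == j))
  }
  expect_error(confusion_matrix(c("a", "z"), c("a", "a"), classes),
               "outside")
  expect_error(confusion_matrix("a", c("a", "b"), classes), "equal length")
})

test_that("metrics reproduce the hand-worked confusion-matrix example", {
  # 4-class matrix: diagonal 10, 9, 10, 10 with one rhonchi -> normal error
  classes <- c("normal", "rhonchi", "fine_crackle", "coarse_crackle")
  cm <- matrix(0L, 4, 4, dimnames = list(classes, classes))
  diag(cm) <- c(10L, 9L, 10L, 10L)
  cm["rhonchi", "normal"] <- 1L
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 39 / 40)
  expect_equal(m$classwise$recall[m$classwise$class == "rhonchi"], 0.9)
  expect_equal(m$classwise$precision[m$classwise$class == "normal"], 10 / 11)
  perfect <- compute_metrics(diag(5L, 3))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$classwise$f1 == 1))
})

test_that("zero-denominator metrics degrade to 0 with a warning", {
  cm <- matrix(c(5L, 0L, 3L, 0L), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_warning(expect_warning(m <- compute_metrics(cm), "recall"), "F1")
  expect_equal(m$classwise$recall[2], 0)
  expect_error(compute_metrics(matrix(0L, 2, 2)), "empty")
  expect_warning(expect_equal(f1_score(0, 0), 0), "zero denominator")
  expect_equal(f1_score(0.5, 1), 2 * 0.5 * 1 / 1.5)
})

test_that("accuracy equals micro-averaged recall for single-label data", {
  set.seed(6)
  truth <- sample(letters[1:4], 120, replace = TRUE)
  pred <- ifelse(runif(120) < 0.7, truth,
                 sample(letters[1:4], 120, replace = TRUE))
  cm <- confusion_matrix(truth, pred, letters[1:4])
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, mean(truth == pred))
  micro_recall <- sum(diag(unclass(cm))) / sum(cm)
  expect_equal(m$accuracy, micro_recall)
})

test_that("repeat_experiment aggregates consistently", {
  # small separable synthetic feature corpus, no audio involved
  labs <- rep(c("a", "b"), each = 20)
  feats <- with_seed(21, lapply(seq_along(labs), function(i) {
    array(rnorm(64 * 8 * 32, mean = ifelse(labs[i] == "a", -1, 1)),
          c(64, 8, 32))
  }))
  corpus <- list(features = feats, labels = labs)
  rep1 <- repeat_experiment(corpus, kind = "cnn_svm",
                            split = split_config(n_repeats = 1, seed = 5))
  expect_equal(rep1$std_accuracy, 0)
  expect_equal(rep1$representative_repeat, 1L)
  rep3 <- repeat_experiment(corpus, kind = "cnn_svm",
                            split = split_config(n_repeats = 3, seed = 5))
  expect_equal(rep3$mean_accuracy, mean(rep3$per_repeat_accuracy))
  expect_equal(rep3$std_accuracy, sd(rep3$per_repeat_accuracy))
  expect_equal(rep3$representative_repeat,
               which.min(abs(rep3$per_repeat_accuracy -
                               rep3$mean_accuracy)))
  expect_equal(sum(rep3$confusion), 4)  # 10% of 40
  # mean of {0.9, 1.0} with a tie: lower repeat index wins
  accs <- c(0.9, 1.0)
  expect_equal(which.min(abs(accs - mean(accs))), 1L)
})

test_that("evaluation reports serialize to JSON and CSV", {
  labs <- rep(c("a", "b"), each = 15)
  feats <- with_seed(22, lapply(seq_along(labs), function(i) {
    array(rnorm(64 * 8 * 32, mean = ifelse(labs[i] == "a", -1, 1)),
          c(64, 8, 32))
  }))
  rep_ <- repeat_experiment(list(features = feats, labels = labs),
                            kind = "cnn_svm",
                            split = split_config(n_repeats = 2, seed = 8))
  dir <- tempfile()
  paths <- write_eval_report(rep_, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths["json"])
  expect_equal(js$kind, "cnn_svm")
  expect_length(js$per_repeat_accuracy, 2L)
  unlink(dir, recursive = TRUE)
})
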