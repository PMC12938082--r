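#' Split configuration for repeated evaluation
#'
#' The evaluation protocol: stratified 80/10/10 train/validation/test
#' splits at the respiratory-cycle level, repeated (default 10 times) with
#' different random partitions, reporting mean and standard deviation of
#' test accuracy over the repeats.
#'
#' @param train_frac,val_frac,test_frac proportions in (0,1) summing to 1.
#' @param n_repeats number of repeated random partitions (default 10).
#' @param unit splitting unit; `"cycle"` (the protocol default) or
#'   `"subject"` (leakage-safe alternative when a `subject` grouping is
#'   available).
#' @param seed master seed; each repeat derives its own partition seed.
#' @return an object of class `split_config`.
#' @export
split_config <- function(train_frac = 0.8, val_frac = 0.1, test_frac = 0.1,
                         n_repeats = 10, unit = c("cycle", "subject"),
                         seed = 1) {
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || any(fr >= 1)) stop("fractions must be in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, n_repeats = as.integer(n_repeats),
                 unit = match.arg(unit), seed = seed),
            class = "split_config")
}

# Largest-remainder apportionment of n items to the three fractions.
apportion <- function(n, fracs) {
  ideal <- n * fracs
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits item indices into disjoint, exhaustive train/validation/test sets,
#' stratified per class with largest-remainder rounding, deterministically
#' per `(seed, repeat_index)`.
#'
#' @param labels character/factor label per item.
#' @param config a [split_config()].
#' @param repeat_index which repetition's partition to produce (1-based).
#' @param subjects optional grouping vector for `unit = "subject"`; whole
#'   subjects are then assigned to one part.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, config = split_config(),
                          repeat_index = 1L, subjects = NULL) {
  labels <- as.character(labels)
  fr <- c(config$train_frac, config$val_frac, config$test_frac)
  rep_seed <- derive_seeds(config$seed, config$n_repeats)[repeat_index]
  unit_lab <- labels
  unit_ids <- seq_along(labels)
  if (config$unit == "subject") {
    if (is.null(subjects)) stop("unit = 'subject' requires `subjects`")
    unit_ids <- unique(subjects)
    unit_lab <- labels[match(unit_ids, subjects)]
  }
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(rep_seed, {
    for (cl in sort(unique(unit_lab))) {
      members <- unit_ids[unit_lab == cl]
      counts <- apportion(length(members), fr)
      if (any(counts == 0L))
        stop(sprintf(
          "class '%s' has %d items: too few for fractions %.2f/%.2f/%.2f",
          cl, length(members), fr[1], fr[2], fr[3]))
      shuffled <- sample(members)
      parts$train <- c(parts$train, shuffled[seq_len(counts[1])])
      parts$val <- c(parts$val,
                     shuffled[counts[1] + seq_len(counts[2])])
      parts$test <- c(parts$test,
                      shuffled[counts[1] + counts[2] + seq_len(counts[3])])
    }
  })
  if (config$unit == "subject") {
    parts <- lapply(parts, function(u) which(subjects %in% u))
  }
  lapply(parts, sort)
}

#' Confusion matrix
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param class_order class labels defining row/column order (rows = true,
#'   columns = predicted). Labels outside `class_order` are an error.
#' @return a K x K integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_order) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(bad) > 0)
    stop("labels outside class_order: ", paste(bad, collapse = ", "))
  K <- length(class_order)
  cm <- matrix(0L, K, K, dimnames = list(true = class_order,
                                         predicted = class_order))
  ti <- match(true_labels, class_order)
  pi_ <- match(predicted_labels, class_order)
  for (i in seq_along(ti)) cm[ti[i], pi_[i]] <- cm[ti[i], pi_[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * precision * recall / (precision + recall)`; a zero
#' denominator yields 0 with a warning (consistent with [compute_metrics()]).
#'
#' @param precision,recall numeric vectors in \[0, 1\].
#' @return numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  den <- precision + recall
  out <- numeric(length(den))
  zero <- den == 0
  if (any(zero))
    warning("zero denominator in F1; reporting 0", call. = FALSE)
  out[!zero] <- 2 * precision[!zero] * recall[!zero] / den[!zero]
  out
}

#' Accuracy and one-vs-rest precision/recall/F1 from a confusion matrix
#'
#' Multiclass accuracy is `trace/total`; per-class precision, recall and F1
#' follow the standard one-vs-rest reduction:
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2*precision*recall/(precision+recall)`. A zero denominator yields
#' 0 with a warning.
#'
#' @param cm a [confusion_matrix()] (rows = true, columns = predicted).
#' @return list with `accuracy` and `classwise` (data.frame `class`,
#'   `precision`, `recall`, `f1`, `support`).
#' @export
compute_metrics <- function(cm) {
  cm <- unclass(cm)
  if (length(cm) == 0L || sum(cm) == 0) stop("empty confusion matrix")
  if (any(cm < 0)) stop("confusion matrix entries must be >= 0")
  K <- nrow(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    zero <- den == 0
    if (any(zero))
      warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
    out[!zero] <- num[!zero] / den[!zero]
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- f1_score(precision, recall)
  list(accuracy = sum(tp) / total,
       classwise = data.frame(
         class = if (!is.null(rownames(cm))) rownames(cm)
                 else as.character(seq_len(K)),
         precision = precision, recall = recall, f1 = f1,
         support = rowSums(cm), row.names = NULL,
         stringsAsFactors = FALSE))
}

#' Run the full repeated-split classification experiment
#'
#' For each of `n_repeats` random stratified partitions: train the chosen
#' classifier on the training part (with the validation part driving early
#' stopping), predict the test part, and record the test accuracy. The
#' report aggregates mean and sample standard deviation over repeats;
#' class-wise metrics and the confusion matrix come from the representative
#' repeat whose accuracy is closest to the mean (ties broken by the lower
#' repeat index). Feature extraction is deterministic for the frozen
#' backbone, so features are computed once and shared across repeats.
#'
#' @param corpus a [generate_corpus()] result, or a list with `features`
#'   (list of feature maps) and `labels` (as produced by
#'   [featurize_corpus()]).
#' @param representation which time-frequency representation to classify
#'   (ignored when `corpus` already carries features).
#' @param kind classifier configuration (see [train_model()]).
#' @param split a [split_config()].
#' @param config a [train_config()]; each repeat derives its own training
#'   seed from `split$seed`.
#' @param backbone a [tiny_backbone()].
#' @param ... passed to [compute_representation()].
#' @return an object of class `eval_report`.
#' @export
repeat_experiment <- function(corpus, representation = "gammatonegram",
                              kind = "cnn", split = split_config(),
                              config = train_config(),
                              backbone = tiny_backbone(), ...) {
  if (!is.null(corpus$features)) {
    features <- corpus$features
    labels <- as.character(corpus$labels)
  } else {
    fz <- featurize_corpus(corpus, representation = representation,
                           backbone = backbone, ...)
    features <- fz$features
    labels <- fz$labels
  }
  classes <- sort(unique(labels))
  train_seeds <- derive_seeds(split$seed + 1L, split$n_repeats)
  repeats <- vector("list", split$n_repeats)
  for (r in seq_len(split$n_repeats)) {
    repeats[[r]] <- tryCatch({
      parts <- split_dataset(labels, split, repeat_index = r)
      cfg <- config
      cfg$seed <- train_seeds[r]
      model <- train_model(features[parts$train], labels[parts$train],
                           features[parts$val], labels[parts$val],
                           kind = kind, config = cfg, backbone = backbone)
      pred <- predict(model, features[parts$test])
      cm <- confusion_matrix(labels[parts$test], pred$labels, classes)
      list(accuracy = compute_metrics(cm)$accuracy, cm = cm,
           n_test = length(parts$test))
    }, error = function(e) {
      warning("repeat ", r, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  ok <- !vapply(repeats, is.null, logical(1))
  if (!any(ok)) stop("all repeats failed")
  acc <- vapply(repeats[ok], `[[`, numeric(1), "accuracy")
  mean_acc <- mean(acc)
  std_acc <- if (length(acc) > 1L) stats::sd(acc) else 0
  rep_idx <- which.min(abs(acc - mean_acc))  # first index wins ties
  cm <- repeats[ok][[rep_idx]]$cm
  structure(list(per_repeat_accuracy = acc,
                 mean_accuracy = mean_acc,
                 std_accuracy = std_acc,
                 representative_repeat = which(ok)[rep_idx],
                 classwise = compute_metrics(cm)$classwise,
                 confusion = cm,
                 failed_repeats = which(!ok),
                 representation = representation, kind = kind,
                 split = split),
            class = "eval_report")
}

#' Featurize a corpus into frozen backbone feature maps
#'
#' Computes the chosen time-frequency representation of each recording,
#' converts it to a 256 x 256 x 3 model input and extracts the backbone
#' feature map.
#'
#' @inheritParams repeat_experiment
#' @param corpus a `lung_corpus`.
#' @return list with `features` (list of feature maps) and `labels`.
#' @export
featurize_corpus <- function(corpus, representation = "gammatonegram",
                             backbone = tiny_backbone(), ...) {
  features <- lapply(corpus$recordings, function(rec) {
    img <- compute_representation(rec$audio, representation, ...)
    extract_feature_map(to_model_input(img), backbone)
  })
  list(features = features, labels = as.character(corpus$labels))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s + %s, %d repeats>\n",
              x$representation, x$kind, length(x$per_repeat_accuracy)))
  cat(sprintf("  test accuracy: %.1f%% +/- %.1f%%\n",
              100 * x$mean_accuracy, 100 * x$std_accuracy))
  cat("  class-wise (representative repeat ", x$representative_repeat,
      "):\n", sep = "")
  cw <- x$classwise
  for (i in seq_len(nrow(cw)))
    cat(sprintf("    %-15s P=%.2f R=%.2f F1=%.2f (n=%d)\n", cw$class[i],
                cw$precision[i], cw$recall[i], cw$f1[i], cw$support[i]))
  if (length(x$failed_repeats) > 0)
    cat("  failed repeats:", paste(x$failed_repeats, collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report as JSON and CSV tables
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if missing).
#' @param stem base file name.
#' @return paths written, invisibly.
#' @export
write_eval_report <- function(report, dir, stem = "eval") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(representation = report$representation, kind = report$kind,
         per_repeat_accuracy = report$per_repeat_accuracy,
         mean_accuracy_percent = round(100 * report$mean_accuracy, 1),
         std_accuracy_percent = round(100 * report$std_accuracy, 1),
         representative_repeat = report$representative_repeat,
         classwise = report$classwise,
         confusion = unclass(report$confusion)),
    json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cw_csv <- file.path(dir, paste0(stem, "_classwise.csv"))
  utils::write.csv(report$classwise, cw_csv, row.names = FALSE)
  cm_csv <- file.path(dir, paste0(stem, "_confusion.csv"))
  utils::write.csv(as.data.frame(unclass(report$confusion)), cm_csv)
  invisible(c(json = json, classwise = cw_csv, confusion = cm_csv))
}
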