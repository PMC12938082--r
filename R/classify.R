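#' Training configuration
#'
#' Defaults follow the pipeline's training protocol: up to 100 epochs with
#' early stopping (patience 15, best-validation-loss weights restored),
#' batch size 16, categorical cross-entropy minimized by Adam from an
#' initial learning rate of 0.001, reduced on validation-loss plateau
#' (factor 0.5, patience 5, floor 1e-5).
#'
#' @param epochs maximum epochs (default 100).
#' @param patience early-stopping patience in epochs (default 15; must be
#'   less than `epochs`).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate initial Adam learning rate (default 0.001).
#' @param lr_factor,lr_patience,lr_min reduce-on-plateau schedule.
#' @param l2 L2 penalty on the CNN-LSTM fully connected layers (default
#'   1e-4; the plain softmax head uses no regularisation).
#' @param dropout dropout rate on the CNN-LSTM FC layer (default 0.5).
#' @param lstm_units BiLSTM hidden units per direction (default 256).
#' @param fc_units fully connected layer width (default 512).
#' @param svm_cost linear-SVM regularisation C (default 1).
#' @param seed seed for weight init, shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100, patience = 15, batch_size = 16,
                         learning_rate = 0.001, lr_factor = 0.5,
                         lr_patience = 5, lr_min = 1e-5, l2 = 1e-4,
                         dropout = 0.5, lstm_units = 256, fc_units = 512,
                         svm_cost = 1, seed = 1) {
  if (patience >= epochs) stop("patience must be < epochs")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = epochs, patience = patience,
                 batch_size = batch_size, learning_rate = learning_rate,
                 lr_factor = lr_factor, lr_patience = lr_patience,
                 lr_min = lr_min, l2 = l2, dropout = dropout,
                 lstm_units = lstm_units, fc_units = fc_units,
                 svm_cost = svm_cost, seed = seed),
            class = "train_config")
}

# Feature maps for a list of 256x256x3 model inputs.
featurize_images <- function(images, backbone = tiny_backbone()) {
  lapply(images, extract_feature_map, backbone = backbone)
}

fmaps_to_matrix <- function(fmaps) {
  do.call(rbind, lapply(fmaps, as.vector))
}

fmaps_to_sequences <- function(fmaps, pad = TRUE) {
  n <- length(fmaps)
  seqs <- lapply(fmaps, sequence_from_feature_map, pad = pad)
  out <- array(0, c(n, 9L, 64L))
  for (i in seq_len(n)) out[i, , ] <- seqs[[i]]
  out
}

fmaps_to_gap <- function(fmaps) {
  do.call(rbind, lapply(fmaps, global_avg_pool))
}

# Per-feature standardization fitted on the training set; max- and
# mean-pooled backbone channels live on very different scales, and the
# heads' optimizers expect comparably scaled inputs.
fit_standardizer <- function(X) {
  list(mu = colMeans(X),
       sd = pmax(apply(X, 2L, stats::sd), 1e-8))
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2L, st$mu), 2L, st$sd, "/")
}

#' Train a lung-sound classifier on frozen backbone features
#'
#' Implements the three classifier configurations over convolutional
#' feature maps:
#' * `"cnn"` -- a new softmax classification head on the frozen backbone's
#'   flattened feature map, trained with early stopping that restores the
#'   weights at minimum validation loss;
#' * `"cnn_lstm"` -- feature maps reshaped by [sequence_from_feature_map()]
#'   into 9 x 64 sequences, a bidirectional LSTM (256 units per direction),
#'   a 512-unit fully connected layer with L2 regularisation and 0.5
#'   dropout, and a 4-way softmax;
#' * `"cnn_svm"` -- globally average-pooled frozen features classified by a
#'   linear SVM (zero trainable backbone parameters).
#'
#' @param train_features list of `(H, W, C)` feature maps (see
#'   [extract_feature_map()]), one per training image.
#' @param train_labels factor or character labels, one per feature map; at
#'   least two classes must be present.
#' @param val_features,val_labels validation set (required for `"cnn"` and
#'   `"cnn_lstm"`; ignored by `"cnn_svm"`).
#' @param kind classifier configuration.
#' @param config a [train_config()].
#' @param backbone the [tiny_backbone()] the features came from (recorded,
#'   and used to verify the frozen-weights contract).
#' @return an object of class `lungsound_model` with elements `kind`,
#'   `classes`, `fit`, `history` (per-epoch train/validation loss and
#'   accuracy plus learning-rate events, for the trained heads) and
#'   `backbone_hash`.
#' @export
train_model <- function(train_features, train_labels,
                        val_features = NULL, val_labels = NULL,
                        kind = c("cnn", "cnn_lstm", "cnn_svm"),
                        config = train_config(),
                        backbone = tiny_backbone()) {
  kind <- match.arg(kind)
  if (length(train_features) == 0L) stop("empty training set")
  classes <- sort(unique(as.character(train_labels)))
  if (length(classes) < 2L)
    stop("training set must contain at least two classes")
  y <- match(as.character(train_labels), classes)
  needs_val <- kind %in% c("cnn", "cnn_lstm")
  if (needs_val && (is.null(val_features) || is.null(val_labels)))
    stop(kind, " training requires a validation set for early stopping")
  K <- length(classes)
  if (backbone$spec$trainable_top_layers > 0L)
    stop("the bundled backbone is frozen; trainable_top_layers must be 0")
  fit <- NULL; history <- NULL
  if (kind == "cnn") {
    X <- fmaps_to_matrix(train_features)
    st <- fit_standardizer(X)
    X <- apply_standardizer(X, st)
    Xv <- apply_standardizer(fmaps_to_matrix(val_features), st)
    yv <- match(as.character(val_labels), classes)
    model <- softmax_head_model(ncol(X), K, l2 = 0)
    res <- with_seed(config$seed, train_nn(model, X, y, Xv, yv, K, config))
    fit <- list(params = res$params, standardizer = st, input = "flat")
    history <- res[c("history", "lr_events", "best_epoch", "best_val_loss")]
  } else if (kind == "cnn_lstm") {
    X <- fmaps_to_sequences(train_features)
    n <- dim(X)[1]
    st <- fit_standardizer(matrix(X, n))
    X <- array(apply_standardizer(matrix(X, n), st), dim(X))
    Xv <- fmaps_to_sequences(val_features)
    Xv <- array(apply_standardizer(matrix(Xv, dim(Xv)[1]), st), dim(Xv))
    yv <- match(as.character(val_labels), classes)
    model <- bilstm_model(D = 64L, K = K, H = config$lstm_units,
                          fc_units = config$fc_units, l2 = config$l2,
                          dropout = config$dropout)
    res <- with_seed(config$seed, train_nn(model, X, y, Xv, yv, K, config))
    fit <- list(params = res$params, standardizer = st, input = "sequence",
                H = config$lstm_units, fc_units = config$fc_units)
    history <- res[c("history", "lr_events", "best_epoch", "best_val_loss")]
  } else {
    X <- fmaps_to_gap(train_features)
    st <- fit_standardizer(X)
    fit <- list(svm = e1071::svm(apply_standardizer(X, st),
                                 factor(classes[y], levels = classes),
                                 kernel = "linear", cost = config$svm_cost,
                                 scale = FALSE, probability = FALSE),
                standardizer = st, input = "gap")
  }
  structure(list(kind = kind, classes = classes, fit = fit,
                 history = history, config = config,
                 backbone_spec = backbone$spec,
                 backbone_hash = backbone_weight_hash(backbone)),
            class = "lungsound_model")
}

#' @export
print.lungsound_model <- function(x, ...) {
  cat(sprintf("<lungsound_model [%s]: %d classes (%s)>\n", x$kind,
              length(x$classes), paste(x$classes, collapse = ", ")))
  if (!is.null(x$history))
    cat(sprintf("  best epoch %d, val loss %.4f (of %d epochs run)\n",
                x$history$best_epoch, x$history$best_val_loss,
                nrow(x$history$history)))
  invisible(x)
}

#' Predict lung-sound classes from feature maps
#'
#' @param object a trained [train_model()] result.
#' @param features list of `(H, W, C)` feature maps.
#' @param ... unused.
#' @return list with `labels` (character), `probabilities` (n x K matrix
#'   summing to 1 per row for the softmax kinds) and, for `"cnn_svm"`,
#'   `margins` (one-vs-one decision values) while `probabilities` is `NULL`.
#' @export
predict.lungsound_model <- function(object, features, ...) {
  if (is.null(object$fit)) stop("model has not been trained")
  K <- length(object$classes)
  if (object$kind == "cnn") {
    X <- apply_standardizer(fmaps_to_matrix(features), object$fit$standardizer)
    model <- softmax_head_model(ncol(X), K)
    p <- model$predict(object$fit$params, X)
    colnames(p) <- object$classes
    list(labels = object$classes[max.col(p, ties.method = "first")],
         probabilities = p)
  } else if (object$kind == "cnn_lstm") {
    X <- fmaps_to_sequences(features)
    X <- array(apply_standardizer(matrix(X, dim(X)[1]),
                                  object$fit$standardizer), dim(X))
    model <- bilstm_model(D = 64L, K = K, H = object$fit$H,
                          fc_units = object$fit$fc_units)
    p <- model$predict(object$fit$params, X)
    colnames(p) <- object$classes
    list(labels = object$classes[max.col(p, ties.method = "first")],
         probabilities = p)
  } else {
    X <- apply_standardizer(fmaps_to_gap(features), object$fit$standardizer)
    pred <- predict(object$fit$svm, X, decision.values = TRUE)
    list(labels = as.character(pred), probabilities = NULL,
         margins = attr(pred, "decision.values"))
  }
}

#' Write a training log as JSON
#'
#' Per-epoch train/validation loss and accuracy plus learning-rate events,
#' mirroring the information a deep-learning framework's CSV logger keeps.
#'
#' @param model a `lungsound_model` with a training history.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  jsonlite::write_json(
    list(kind = model$kind,
         best_epoch = model$history$best_epoch,
         best_val_loss = model$history$best_val_loss,
         epochs = model$history$history,
         lr_events = model$history$lr_events),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
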