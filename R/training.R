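#' One-hot encode rhythm class labels
#'
#' Class order is fixed as AF, Normal, Noisy, Other; an AF label maps to
#' `c(1, 0, 0, 0)`.
#'
#' @param labels Character vector of class labels.
#' @return Numeric matrix with one row per label and four columns named after
#'   [af_classes()].
#' @export
#' @examples
#' one_hot("AF")
one_hot <- function(labels) {
  labels <- as.character(labels)
  check_labels(labels)
  m <- matrix(0, length(labels), 4L, dimnames = list(NULL, af_classes()))
  m[cbind(seq_along(labels), match(labels, af_classes()))] <- 1
  m
}

#' Mean categorical cross-entropy
#'
#' `-sum_i x_i log y_i` per sample, averaged over the batch, where `x` is the
#' one-hot ground truth and `y` the predicted class probabilities. Predicted
#' probabilities are clipped at 1e-12 before the logarithm so the loss stays
#' finite.
#'
#' @param truth One-hot matrix (or a single one-hot vector).
#' @param predicted Matrix of predicted probability rows (same shape).
#' @return Non-negative scalar; zero iff every prediction puts all mass on
#'   the true class.
#' @export
#' @examples
#' cross_entropy(one_hot("AF"), matrix(rep(0.25, 4), 1))  # log(4)
cross_entropy <- function(truth, predicted) {
  if (is.null(dim(truth))) truth <- matrix(truth, 1)
  if (is.null(dim(predicted))) predicted <- matrix(predicted, 1)
  if (!all(dim(truth) == dim(predicted))) {
    stop("truth and predicted must have the same shape", call. = FALSE)
  }
  p <- pmax(predicted, 1e-12)
  mean(-rowSums(truth * log(p)))
}

#' Training configuration
#'
#' @param learning_rate Adam step size; 0.0001 is the rate of the selected
#'   ten-block model, 0.001 the optimizer's base rate.
#' @param batch_size Minibatch size (default 30).
#' @param epochs Number of passes over the training data (default 50).
#' @param dropout_rate Dropout rate used by the architecture (default 0.5;
#'   informational — the rate is carried by the architecture spec).
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment decay rates and
#'   stabilizer (defaults 0.9, 0.999, 1e-8).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param patience If not `NULL`, stop early after this many epochs without
#'   improvement (by at least `min_delta`) of the monitored loss (validation
#'   loss when a validation set is given, else training loss).
#' @param min_delta Minimum improvement counted by early stopping.
#' @param target_train_acc If not `NULL`, stop once training accuracy reaches
#'   this value (a convergence shortcut for separable data).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 30L,
                         epochs = 50L, dropout_rate = 0.5,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_epsilon = 1e-8, seed = 1L,
                         patience = NULL, min_delta = 1e-4,
                         target_train_acc = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout_rate = dropout_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_epsilon = adam_epsilon, seed = as.integer(seed),
                 patience = patience, min_delta = min_delta,
                 target_train_acc = target_train_acc),
            class = "train_config")
}

#' Stratified K-fold partition
#'
#' Assigns each segment to one of `k` folds so that fold sizes differ by at
#' most one and every fold holds each class's share of segments to within one
#' segment of exact proportionality.
#'
#' @param labels Character vector of per-segment class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; assignment is deterministic given the seed.
#' @return An object of class `fold_split`: list with `k`, `assignments`
#'   (integer fold index per segment), `seed`.
#' @export
#' @examples
#' fs <- stratified_kfold(rep(af_classes(), each = 25), k = 5, seed = 1)
#' table(fs$assignments)
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  check_labels(labels)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("class %s has fewer than k = %d members",
                 names(tab)[which.min(tab)], k), call. = FALSE)
  }
  assignments <- integer(length(labels))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # within each class, shuffle then deal round-robin into folds; rotate the
  # starting fold per class so remainders spread over folds
  start <- 0L
  for (cl in names(sort(tab, decreasing = TRUE))) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    f <- ((seq_along(idx) - 1L + start) %% k) + 1L
    assignments[idx] <- f
    start <- (start + length(idx)) %% k
  }
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> k = %d, %d segments\n", x$k,
              length(x$assignments)))
  print(table(fold = x$assignments))
  invisible(x)
}

# internal: labels + samples from a segment_dataset-or-matrix pair
dataset_xy <- function(dataset) {
  stopifnot(inherits(dataset, "segment_dataset"))
  list(X = dataset$samples, y = as.character(dataset$info$label))
}

#' Fit a network on a segment dataset
#'
#' Minibatch training with the Adam optimizer and categorical cross-entropy.
#' Dropout is active only during training. Shuffling, weight initialization
#' and dropout masks are all seeded, so two runs with the same model seed and
#' config are identical.
#'
#' @param model A `cnn_model` from [build_network()].
#' @param dataset A `segment_dataset` whose segment length matches the model
#'   input length.
#' @param config A [train_config()].
#' @param validation Optional `segment_dataset` used to monitor validation
#'   loss (and drive early stopping if `config$patience` is set).
#' @param verbose Print per-epoch progress.
#' @return The model (invisibly modified in place via its engine handle),
#'   with `$history` set to a data frame of per-epoch `loss`, `accuracy` and,
#'   when a validation set is given, `val_loss`, `val_accuracy`.
#' @export
fit <- function(model, dataset, config = train_config(),
                validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  xy <- dataset_xy(dataset)
  if (ncol(xy$X) != model$spec$input_len) {
    stop(sprintf("segment length %d does not match model input length %d",
                 ncol(xy$X), model$spec$input_len), call. = FALSE)
  }
  yidx <- match(xy$y, af_classes()) - 1L
  n <- nrow(xy$X)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  history <- list()
  best <- Inf
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      b <- ord[i:j]
      l <- net_train_batch(model$handle, xy$X[b, , drop = FALSE], yidx[b],
                           config$learning_rate, config$adam_beta1,
                           config$adam_beta2, config$adam_epsilon)
      if (!is.finite(l)) {
        stop(sprintf("training diverged (non-finite loss) in epoch %d", epoch),
             call. = FALSE)
      }
      losses <- c(losses, l)
      i <- j + 1L
    }
    pr <- predict(model, dataset)
    acc <- mean(pr$labels == xy$y)
    row <- data.frame(epoch = epoch, loss = mean(losses), accuracy = acc)
    monitored <- mean(losses)
    if (!is.null(validation)) {
      vxy <- dataset_xy(validation)
      vpr <- predict(model, validation)
      vy <- match(vxy$y, af_classes()) - 1L
      row$val_loss <- net_loss(model$handle, vxy$X, vy, FALSE)
      row$val_accuracy <- mean(vpr$labels == vxy$y)
      monitored <- row$val_loss
    }
    history[[epoch]] <- row
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.3f%s\n", epoch, row$loss, acc,
                  if (!is.null(validation))
                    sprintf("  val_loss %.4f  val_acc %.3f",
                            row$val_loss, row$val_accuracy) else ""))
    }
    if (!is.null(config$target_train_acc) &&
        acc >= config$target_train_acc) break
    if (!is.null(config$patience)) {
      if (monitored < best - config$min_delta) {
        best <- monitored
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  model$history <- do.call(rbind, history)
  model$trained <- TRUE
  model
}
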