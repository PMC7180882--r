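# translate an architecture_spec into the engine's flat layer list
spec_to_engine_layers <- function(spec) {
  layers <- list()
  add <- function(...) layers[[length(layers) + 1L]] <<- list(...)
  len <- spec$input_len
  ch <- 1L
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    if (len < b$kernel) {
      stop(sprintf(
        "infeasible architecture: conv block %d receives %d samples but has kernel %d",
        i, len, b$kernel), call. = FALSE)
    }
    out_len <- len - b$kernel + 1L
    add(type = "conv", kernel = b$kernel, in_ch = ch, out_ch = b$filters,
        in_len = len, out_len = out_len)
    len <- out_len; ch <- b$filters
    add(type = "relu")
    if (b$has_bn) add(type = "bn", channels = ch)
    if (b$pool != "none") {
      add(type = if (b$pool == "max") "maxpool" else "avgpool",
          in_len = len, out_len = len %/% 2L, channels = ch)
      len <- len %/% 2L
    }
    if (!is.na(b$dropout_after)) add(type = "dropout", rate = b$dropout_after)
  }
  if (spec$pre_flatten_pool != "none") {
    add(type = if (spec$pre_flatten_pool == "max") "maxpool" else "avgpool",
        in_len = len, out_len = len %/% 2L, channels = ch)
    len <- len %/% 2L
  }
  add(type = "flatten", len = len, channels = ch)
  units <- len * ch
  widths <- c(spec$dense_units, spec$n_classes)
  for (j in seq_along(widths)) {
    add(type = "dense", in_units = units, out_units = widths[j])
    units <- widths[j]
    if (j < length(widths)) add(type = "relu")
    if (j == 1L && !is.na(spec$dense_dropout) && spec$dense_dropout > 0) {
      add(type = "dropout", rate = spec$dense_dropout)
    }
  }
  add(type = "softmax")
  layers
}

#' Build a trainable network from an architecture spec
#'
#' Instantiates the package's convolutional training engine for the given
#' declarative architecture, with seeded Glorot-uniform weight
#' initialization. The engine-reported trainable parameter count is checked
#' against the analytic calculator ([count_trainable()]) at build time; a
#' mismatch is an internal consistency error.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for weight initialization and dropout masks.
#' @param precision `"single"` (default, the usual training precision) or
#'   `"double"` (used for numeric gradient verification).
#' @return An object of class `cnn_model`.
#' @export
#' @examples
#' m <- build_network(make_variant("Proposed-1", input_len = 9000), seed = 1)
#' m$n_params
build_network <- function(spec, seed = 1L, precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(inherits(spec, "architecture_spec"))
  layers <- spec_to_engine_layers(spec)
  handle <- net_create(layers, as.integer(seed), spec$input_len,
                       precision == "double")
  n <- net_n_params(handle)
  expected <- count_trainable(spec)
  if (n != expected) {
    stop(sprintf(
      "internal consistency error: engine reports %d trainable parameters, analytic count is %d",
      n, expected), call. = FALSE)
  }
  structure(list(handle = handle, spec = spec, seed = as.integer(seed),
                 precision = precision, n_params = n, trained = FALSE,
                 history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s: %d conv blocks, input %d, %s trainable parameters (%s)\n",
              x$spec$name, length(x$spec$blocks), x$spec$input_len,
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Trainable parameter count reported by the engine
#'
#' @param model A `cnn_model`.
#' @return Numeric scalar.
#' @export
model_param_count <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  net_n_params(model$handle)
}

#' Class probabilities and predicted labels for a segment dataset
#'
#' Runs the network in inference mode (dropout off, batch normalization using
#' running statistics). Ties in the argmax are broken toward the lowest class
#' index in the canonical order AF, Normal, Noisy, Other.
#'
#' @param object A trained (or untrained) `cnn_model`.
#' @param dataset A `segment_dataset` (see [normalize_dataset()]) or a numeric
#'   matrix with one segment per row.
#' @param batch_size Inference batch size (default 64).
#' @param ... Unused.
#' @return A list with `probs` (matrix, one row per segment, columns in
#'   [af_classes()] order) and `labels` (character vector).
#' @export
predict.cnn_model <- function(object, dataset, batch_size = 64L, ...) {
  X <- if (inherits(dataset, "segment_dataset")) dataset$samples else
    as.matrix(dataset)
  if (ncol(X) != object$spec$input_len) {
    stop(sprintf("segment length %d does not match model input length %d",
                 ncol(X), object$spec$input_len), call. = FALSE)
  }
  n <- nrow(X)
  probs <- matrix(NA_real_, n, object$spec$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    probs[i:j, ] <- net_predict(object$handle, X[i:j, , drop = FALSE])
    i <- j + 1L
  }
  colnames(probs) <- af_classes()[seq_len(object$spec$n_classes)]
  labels <- af_classes()[max.col(probs, ties.method = "first")]
  list(probs = probs, labels = labels)
}
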