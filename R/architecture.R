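#' Specify one convolutional block
#'
#' A block is a valid (no-padding, stride-1) 1D convolution followed by ReLU,
#' an optional batch-normalization layer, an optional size-2/stride-2 pooling
#' layer, and an optional dropout layer.
#'
#' @param filters Number of output channels (kernels) of the convolution.
#' @param kernel Receptive-field length of the convolution (samples).
#' @param has_bn Logical; insert a batch-normalization layer after the ReLU.
#' @param pool One of `"max"`, `"average"`, `"none"`.
#' @param dropout_after Dropout rate in `[0, 1)` applied after the block, or
#'   `NA` for no dropout.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(filters, kernel, has_bn = FALSE,
                       pool = c("max", "average", "none"),
                       dropout_after = NA_real_) {
  pool <- match.arg(pool)
  stopifnot(is.numeric(filters), length(filters) == 1, filters >= 1,
            is.numeric(kernel), length(kernel) == 1, kernel >= 1)
  if (!is.na(dropout_after) && (dropout_after < 0 || dropout_after >= 1)) {
    stop("dropout_after must be in [0, 1) or NA", call. = FALSE)
  }
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 has_bn = isTRUE(has_bn), pool = pool,
                 dropout_after = dropout_after),
            class = "block_spec")
}

#' Declarative 1D CNN architecture
#'
#' Describes the full network: an ordered list of convolutional blocks, an
#' optional extra pooling layer before the flatten, and the dense head ending
#' in a 4-way softmax.
#'
#' @param blocks List of [block_spec()] objects.
#' @param dense_units Integer vector of hidden dense-layer widths
#'   (default `c(128, 32)`); a final dense layer of `n_classes` units with
#'   softmax is always appended.
#' @param n_classes Number of output classes (4).
#' @param pre_flatten_pool One of `"none"`, `"max"`, `"average"`: an extra
#'   size-2 pooling layer inserted just before the flatten layer.
#' @param input_len Input segment length in samples (default 9000, i.e. 30 s
#'   at 300 Hz).
#' @param dense_dropout Dropout rate after the first dense layer (default 0.5).
#' @param name Optional architecture name.
#' @return An object of class `architecture_spec`.
#' @seealso [make_variant()] for the canonical architectures,
#'   [compute_layer_summaries()] for the analytic shape/parameter chain.
#' @export
architecture_spec <- function(blocks, dense_units = c(128L, 32L),
                              n_classes = 4L,
                              pre_flatten_pool = c("none", "max", "average"),
                              input_len = 9000L, dense_dropout = 0.5,
                              name = "custom") {
  pre_flatten_pool <- match.arg(pre_flatten_pool)
  stopifnot(length(blocks) >= 1,
            all(vapply(blocks, inherits, logical(1), "block_spec")),
            input_len >= 1, n_classes >= 2)
  structure(list(blocks = blocks,
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 pre_flatten_pool = pre_flatten_pool,
                 input_len = as.integer(input_len),
                 dense_dropout = dense_dropout,
                 name = name),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s: %d conv blocks, input %d samples\n",
              x$name, length(x$blocks), x$input_len))
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat(sprintf("  block %2d: conv %dx%d%s, pool=%s%s\n", i, b$filters,
                b$kernel, if (b$has_bn) " +BN" else "", b$pool,
                if (!is.na(b$dropout_after))
                  sprintf(", dropout %.2f", b$dropout_after) else ""))
  }
  if (x$pre_flatten_pool != "none")
    cat(sprintf("  pre-flatten pool: %s\n", x$pre_flatten_pool))
  cat(sprintf("  dense: %s -> %d (softmax)\n",
              paste(x$dense_units, collapse = " -> "), x$n_classes))
  invisible(x)
}

# canonical filter schedule: start at 32, double every two blocks
canonical_filters <- function(n_conv_layers) {
  as.integer(32 * 2^((seq_len(n_conv_layers) - 1) %/% 2))
}

# canonical dropout placement: after blocks n-4, n-2, n-1 (blocks 6, 8, 9 of
# the ten-block stack), rate 0.5
canonical_dropout_blocks <- function(n_conv_layers) {
  sort(unique(pmax(1L, c(n_conv_layers - 4L, n_conv_layers - 2L,
                         n_conv_layers - 1L))))
}

#' Build a canonical network variant
#'
#' Constructs the ten-block reference architecture and its named variants.
#' The reference stack (`"Proposed-1"`) uses max pooling in every block except
#' the last, one batch-normalization layer in the first block only, dropout
#' 0.5 after blocks 6, 8 and 9 and after the first dense layer, and a dense
#' head of 128 and 32 units before the 4-way softmax. Variants:
#' \describe{
#'   \item{Proposed-2}{every max pooling replaced by average pooling}
#'   \item{All-BN}{batch normalization after every convolution}
#'   \item{No-BN}{no batch normalization anywhere}
#'   \item{Maxpooling}{Proposed-1 plus one extra max pooling before flatten}
#'   \item{Max-Average}{Proposed-1 plus one extra average pooling before flatten}
#'   \item{Extra-Average}{Proposed-2 plus one extra average pooling before flatten}
#' }
#' For layer counts other than ten (grid search), the same schedule is used:
#' filters start at 32 and double every two blocks, pooling in every block but
#' the last, dropout after blocks `n-4`, `n-2`, `n-1`.
#'
#' @param name Variant name (see above).
#' @param kernel Convolution kernel size (default 5).
#' @param n_conv_layers Number of convolutional blocks, 8 to 11 (default 10).
#' @param input_len Input length in samples (default 9000).
#' @return An [architecture_spec()].
#' @export
#' @examples
#' spec <- make_variant("Proposed-2")
#' count_trainable(spec)
make_variant <- function(name = c("Proposed-1", "Proposed-2", "All-BN",
                                  "No-BN", "Maxpooling", "Max-Average",
                                  "Extra-Average"),
                         kernel = 5L, n_conv_layers = 10L,
                         input_len = 9000L) {
  name <- match.arg(name)
  if (!n_conv_layers %in% 8:11) {
    stop("n_conv_layers must be between 8 and 11", call. = FALSE)
  }
  filters <- canonical_filters(n_conv_layers)
  drop_after <- canonical_dropout_blocks(n_conv_layers)
  base_pool <- if (name %in% c("Proposed-2", "Extra-Average")) "average" else "max"
  bn_blocks <- switch(name, "All-BN" = seq_len(n_conv_layers),
                      "No-BN" = integer(0), 1L)
  blocks <- lapply(seq_len(n_conv_layers), function(i) {
    block_spec(filters = filters[i], kernel = kernel,
               has_bn = i %in% bn_blocks,
               pool = if (i == n_conv_layers) "none" else base_pool,
               dropout_after = if (i %in% drop_after) 0.5 else NA_real_)
  })
  pre_pool <- switch(name, "Maxpooling" = "max", "Max-Average" = "average",
                     "Extra-Average" = "average", "none")
  architecture_spec(blocks, dense_units = c(128L, 32L), n_classes = 4L,
                    pre_flatten_pool = pre_pool, input_len = input_len,
                    dense_dropout = 0.5, name = name)
}

#' Analytic per-layer shapes and parameter counts
#'
#' Walks the architecture and derives, without building any network, every
#' layer's output length, channel count and parameter count. Convolutions are
#' valid (no padding, stride 1): `out_len = in_len - kernel + 1`. Pooling is
#' size 2, stride 2, with floor division on odd lengths. Parameter counts:
#' convolution `kernel * in_channels * filters + filters`; batch normalization
#' 4 per channel in total of which the 2 scale/shift are trainable (the
#' running mean/variance are not); dense `in_units * out_units + out_units`.
#'
#' @param spec An [architecture_spec()].
#' @return A data frame of class `layer_summaries` with columns `layer_kind`
#'   (`conv`, `bn`, `pool`, `dropout`, `flatten`, `dense`), `output_len`,
#'   `channels`, `params_total`, `params_trainable`.
#' @export
#' @examples
#' s <- compute_layer_summaries(make_variant("Proposed-1"))
#' subset(s, params_total > 0)
compute_layer_summaries <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  rows <- list()
  add <- function(kind, len, ch, total, trainable) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer_kind = kind, output_len = as.integer(len),
      channels = as.integer(ch), params_total = total,
      params_trainable = trainable, stringsAsFactors = FALSE)
  }
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
    p <- b$kernel * ch * b$filters + b$filters
    add("conv", out_len, b$filters, p, p)
    len <- out_len
    ch <- b$filters
    if (b$has_bn) add("bn", len, ch, 4 * ch, 2 * ch)
    if (b$pool != "none") {
      len <- len %/% 2L
      if (len < 1L) {
        stop(sprintf(
          "infeasible architecture: pooling after block %d leaves no samples", i),
          call. = FALSE)
      }
      add("pool", len, ch, 0, 0)
    }
    if (!is.na(b$dropout_after)) add("dropout", len, ch, 0, 0)
  }
  if (spec$pre_flatten_pool != "none") {
    len <- len %/% 2L
    if (len < 1L) {
      stop("infeasible architecture: pre-flatten pooling leaves no samples",
           call. = FALSE)
    }
    add("pool", len, ch, 0, 0)
  }
  units <- len * ch
  add("flatten", units, 1L, 0, 0)
  widths <- c(spec$dense_units, spec$n_classes)
  for (j in seq_along(widths)) {
    p <- units * widths[j] + widths[j]
    add("dense", widths[j], 1L, p, p)
    units <- widths[j]
    if (j == 1L && !is.na(spec$dense_dropout) && spec$dense_dropout > 0) {
      add("dropout", units, 1L, 0, 0)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("layer_summaries", class(out))
  out
}

#' Total trainable parameters of an architecture
#'
#' Sums the trainable parameters over all layers of the analytic summary:
#' batch-normalization running statistics (2 per channel) are excluded, its
#' scale and shift are included.
#'
#' @param spec An [architecture_spec()].
#' @return Integer-valued numeric scalar.
#' @export
#' @examples
#' count_trainable(make_variant("Proposed-1"))  # 3212740
count_trainable <- function(spec) {
  sum(compute_layer_summaries(spec)$params_trainable)
}

#' Total parameters including non-trainable statistics
#'
#' @param spec An [architecture_spec()].
#' @return Numeric scalar: trainable parameters plus batch-normalization
#'   running statistics.
#' @export
count_params <- function(spec) {
  sum(compute_layer_summaries(spec)$params_total)
}

#' Is a canonical (layers, kernel) combination feasible?
#'
#' A stack is feasible when every convolutional layer receives at least
#' `kernel` samples and no pooling layer empties the signal. With pooling in
#' every block but the last, deep stacks with large kernels run out of
#' samples: eleven layers with kernel 5 or 7 on a 9000-sample input do not
#' fit.
#'
#' @param n_conv_layers Number of convolutional blocks.
#' @param kernel Kernel size.
#' @param input_len Input length in samples (default 9000).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' check_feasible(11, 5)  # FALSE
#' check_feasible(11, 3)  # TRUE
check_feasible <- function(n_conv_layers, kernel, input_len = 9000L) {
  stopifnot(n_conv_layers >= 1, kernel >= 1, input_len >= 1)
  len <- as.integer(input_len)
  for (i in seq_len(n_conv_layers)) {
    if (len < kernel) return(FALSE)
    len <- len - as.integer(kernel) + 1L
    if (i < n_conv_layers) {
      len <- len %/% 2L
      if (len < 1L) return(FALSE)
    }
  }
  TRUE
}

#' Print a layer-by-layer summary table of a built or declared network
#'
#' @param spec An [architecture_spec()].
#' @param ... Unused.
#' @return Invisibly, the [compute_layer_summaries()] data frame.
#' @export
describe_architecture <- function(spec, ...) {
  s <- compute_layer_summaries(spec)
  cat(sprintf("%-22s %-14s %12s\n", "Layer Type", "Output Shape", "Parameters"))
  for (i in seq_len(nrow(s))) {
    shape <- if (s$channels[i] > 1L) {
      sprintf("%d x %d", s$output_len[i], s$channels[i])
    } else {
      sprintf("%d", s$output_len[i])
    }
    cat(sprintf("%-22s %-14s %12s\n", s$layer_kind[i], shape,
                format(s$params_total[i], big.mark = ",")))
  }
  cat(sprintf("Total trainable parameters: %s\n",
              format(sum(s$params_trainable), big.mark = ",")))
  invisible(s)
}

#' Serialize an architecture spec to a plain list / JSON
#'
#' @param spec An [architecture_spec()].
#' @return A list safe to pass to `jsonlite::toJSON`.
#' @export
spec_to_list <- function(spec) {
  list(name = spec$name,
       input_len = spec$input_len,
       n_classes = spec$n_classes,
       pre_flatten_pool = spec$pre_flatten_pool,
       dense_units = spec$dense_units,
       dense_dropout = spec$dense_dropout,
       blocks = lapply(spec$blocks, function(b) {
         list(filters = b$filters, kernel = b$kernel, has_bn = b$has_bn,
              pool = b$pool,
              # NULL (absent in JSON) rather than NA: unboxed NA serializes
              # as the string "NA"
              dropout_after = if (is.na(b$dropout_after)) NULL
                              else b$dropout_after)
       }))
}

#' Rebuild an architecture spec from its list form
#'
#' @param x A list as produced by [spec_to_list()] (or parsed from JSON).
#' @return An [architecture_spec()].
#' @export
spec_from_list <- function(x) {
  blocks <- lapply(x$blocks, function(b) {
    da <- b$dropout_after
    if (is.null(da) || length(da) == 0 || !is.numeric(da) || is.na(da)) {
      da <- NA_real_
    }
    block_spec(b$filters, b$kernel, has_bn = isTRUE(b$has_bn), pool = b$pool,
               dropout_after = da)
  })
  architecture_spec(blocks, dense_units = unlist(x$dense_units),
                    n_classes = x$n_classes,
                    pre_flatten_pool = x$pre_flatten_pool,
                    input_len = x$input_len,
                    dense_dropout = x$dense_dropout, name = x$name)
}
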