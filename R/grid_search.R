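#' Enumerate the hyperparameter grid
#'
#' Cartesian product of layer counts, kernel sizes, batch sizes and learning
#' rates, in deterministic lexicographic order (layers slowest, learning
#' rate fastest). The default sets are the search space used to select the
#' ten-block model and enumerate to 300 points.
#'
#' @param n_conv_layers Integer set of convolutional layer counts.
#' @param kernels Integer set of kernel sizes.
#' @param batch_sizes Integer set of batch sizes.
#' @param learning_rates Numeric set of Adam learning rates.
#' @return A data frame of class `grid_points` with one row per combination.
#' @export
#' @examples
#' nrow(make_grid())  # 300
make_grid <- function(n_conv_layers = c(8L, 9L, 10L, 11L),
                      kernels = c(3L, 5L, 7L),
                      batch_sizes = c(30L, 50L, 70L, 90L, 110L),
                      learning_rates = c(0.00005, 0.0001, 0.0005, 0.001,
                                         0.005)) {
  sets <- list(n_conv_layers = n_conv_layers, kernels = kernels,
               batch_sizes = batch_sizes, learning_rates = learning_rates)
  if (any(lengths(sets) == 0)) {
    stop("all four hyperparameter sets must be non-empty", call. = FALSE)
  }
  g <- expand.grid(learning_rate = learning_rates, batch_size = batch_sizes,
                   kernel = kernels, n_conv_layers = n_conv_layers,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("n_conv_layers", "kernel", "batch_size", "learning_rate")]
  rownames(g) <- NULL
  class(g) <- c("grid_points", "data.frame")
  g
}

# best feasible point: highest mean F1, ties by fewer parameters then lower
# learning rate
select_best <- function(results) {
  ok <- which(results$feasible & !is.na(results$mean_f1))
  if (length(ok) == 0) return(NA_integer_)
  o <- ok[order(-results$mean_f1[ok], results$n_params[ok],
                results$learning_rate[ok])]
  o[1]
}

#' Evaluate every grid point by stratified cross-validation
#'
#' Infeasible (layers, kernel) combinations — stacks whose final convolution
#' would receive fewer samples than its kernel — are kept in the result,
#' flagged, and reported as `NA` rather than dropped. Each feasible point is
#' scored by [cross_validate()] on the canonical architecture for that layer
#' count and kernel; reported parameter counts always come from the analytic
#' calculator.
#'
#' @param grid A [make_grid()] data frame.
#' @param dataset A `segment_dataset`.
#' @param k Folds per point (default 5).
#' @param seed Base seed.
#' @param epochs Training epochs per point; scalar or one value per point
#'   (0 evaluates the untrained network).
#' @param variant Base variant for the grid architectures (default
#'   `"Proposed-1"`).
#' @param verbose Print per-point progress.
#' @return An object of class `grid_result`: the grid with columns
#'   `feasible`, `mean_f1`, `sigma`, `n_params`, plus `best` (row index of
#'   the winning point).
#' @export
run_grid <- function(grid, dataset, k = 5L, seed = 1L, epochs = 2L,
                     variant = "Proposed-1", verbose = FALSE) {
  stopifnot(inherits(grid, "grid_points") || is.data.frame(grid))
  threshold <- dataset$threshold_samples
  n <- nrow(grid)
  if (n == 0) stop("empty grid", call. = FALSE)
  epochs <- rep_len(as.integer(epochs), n)
  results <- grid
  results$feasible <- FALSE
  results$mean_f1 <- NA_real_
  results$sigma <- NA_real_
  results$n_params <- NA_real_
  for (i in seq_len(n)) {
    layers_i <- grid$n_conv_layers[i]
    kernel_i <- grid$kernel[i]
    if (!check_feasible(layers_i, kernel_i, threshold)) {
      if (verbose) {
        cat(sprintf("point %d/%d: layers=%d kernel=%d -> N/A (infeasible)\n",
                    i, n, layers_i, kernel_i))
      }
      next
    }
    spec <- make_variant(variant, kernel = kernel_i,
                         n_conv_layers = layers_i, input_len = threshold)
    results$feasible[i] <- TRUE
    results$n_params[i] <- count_trainable(spec)
    cfg <- train_config(learning_rate = grid$learning_rate[i],
                        batch_size = grid$batch_size[i],
                        epochs = epochs[i], seed = seed + i)
    rep <- cross_validate(dataset, spec, cfg, k = k, seed = seed)
    results$mean_f1[i] <- rep$average_f1
    results$sigma[i] <- rep$sigma
    if (verbose) {
      cat(sprintf("point %d/%d: layers=%d kernel=%d bs=%d lr=%g -> F1 %.1f\n",
                  i, n, layers_i, kernel_i, grid$batch_size[i],
                  grid$learning_rate[i], rep$average_f1))
    }
  }
  if (!any(results$feasible)) {
    stop("all grid points are infeasible for this segment length",
         call. = FALSE)
  }
  structure(list(results = results, best = select_best(results),
                 k = k, seed = seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d points, %d feasible\n", nrow(x$results),
              sum(x$results$feasible)))
  if (!is.na(x$best)) {
    b <- x$results[x$best, ]
    cat(sprintf("  best: layers=%d kernel=%d batch=%d lr=%g (F1 %.1f, %s params)\n",
                b$n_conv_layers, b$kernel, b$batch_size, b$learning_rate,
                b$mean_f1, format(b$n_params, big.mark = ",")))
  }
  invisible(x)
}

#' Refine the batch-size search around the winning grid point
#'
#' Re-evaluates the best point's configuration at extra batch sizes (batch
#' sizes already present for that configuration are deduplicated, not re-run)
#' and merges the new rows into the result.
#'
#' @param result A [run_grid()] result.
#' @param extra_batch_sizes Integer vector of additional batch sizes.
#' @param dataset The `segment_dataset` used for the original run.
#' @param epochs Training epochs for the new points (default 2).
#' @param verbose Print per-point progress.
#' @return An updated `grid_result`.
#' @export
refine_batch_search <- function(result, extra_batch_sizes, dataset,
                                epochs = 2L, verbose = FALSE) {
  stopifnot(inherits(result, "grid_result"))
  if (length(extra_batch_sizes) == 0) return(result)
  base <- result$results[result$best, ]
  seen <- result$results$batch_size[
    result$results$n_conv_layers == base$n_conv_layers &
    result$results$kernel == base$kernel &
    result$results$learning_rate == base$learning_rate]
  new_bs <- setdiff(unique(as.integer(extra_batch_sizes)), seen)
  if (length(new_bs) == 0) return(result)
  extra <- make_grid(n_conv_layers = base$n_conv_layers,
                     kernels = base$kernel, batch_sizes = new_bs,
                     learning_rates = base$learning_rate)
  extra_res <- run_grid(extra, dataset, k = result$k, seed = result$seed,
                        epochs = epochs, verbose = verbose)
  merged <- rbind(result$results, extra_res$results)
  rownames(merged) <- NULL
  structure(list(results = merged, best = select_best(merged),
                 k = result$k, seed = result$seed),
            class = "grid_result")
}
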