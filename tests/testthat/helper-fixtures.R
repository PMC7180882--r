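# shared fixtures: all built in code at test time

# a small architecture for fast training tests (input 300 samples)
tiny_spec <- function(input_len = 300L, dropout = NA_real_) {
  architecture_spec(
    list(block_spec(4L, 5L, has_bn = TRUE, pool = "average"),
         block_spec(8L, 5L, pool = "average"),
         block_spec(8L, 5L, pool = "none", dropout_after = dropout)),
    dense_units = c(16L), input_len = input_len, dense_dropout = 0,
    name = "tiny")
}

# a linearly separable four-class toy signal set: each class is a sinusoid
# of a distinct frequency plus noise; trivially learnable by a small CNN
toy_segments <- function(n_per_class = 10L, len = 300L, seed = 1L,
                         noise = 0.05) {
  withr::with_seed(seed, {
    freqs <- c(AF = 3, Normal = 7, Noisy = 13, Other = 21)
    labels <- rep(af_classes(), each = n_per_class)
    t <- seq_len(len) / len
    X <- t(vapply(labels, function(cl) {
      sin(2 * pi * freqs[[cl]] * t + runif(1, 0, 2 * pi)) +
        noise * rnorm(len)
    }, numeric(len)))
    dimnames(X) <- NULL
    segment_dataset(X,
                    data.frame(source_id = sprintf("T%03d", seq_along(labels)),
                               label = labels, start_index = 0L,
                               stringsAsFactors = FALSE),
                    len)
  })
}

# one small mixed-duration recording set for normalization tests
mixed_recordings <- function() {
  list(ecg_recording("R1", seq_len(18600) / 100, 300, "AF"),
       ecg_recording("R2", seq_len(4000) / 100, 300, "Normal"),
       ecg_recording("R3", seq_len(9000) / 100, 300, "Other"))
}
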