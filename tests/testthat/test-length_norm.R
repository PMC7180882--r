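test_that("threshold selection finds the modal duration bin", {
  # single-bin histogram
  expect_equal(compute_length_threshold(rep(9000L, 10), 300), 9000L)
  # mode at 30 s dominates a uniform 9-61 s remainder
  withr::with_seed(7, {
    lens <- c(rep(9000L, 70), as.integer(round(runif(30, 9, 61) * 300)))
  })
  expect_equal(compute_length_threshold(lens, 300), 9000L)
  # tie between two bins resolves to the smaller duration
  expect_equal(compute_length_threshold(c(3000L, 3000L, 9000L, 9000L), 300),
               3000L)
  expect_error(compute_length_threshold(integer(0), 300), "non-empty")
  expect_error(compute_length_threshold(c(100L, -5L), 300), "positive")
})

test_that("long recordings are chopped into stride plus end-anchored windows", {
  # the 61-s worked example: four windows
  sl <- segment_long(seq_len(18600), 9000, 0.5)
  expect_equal(sl$starts, c(0L, 4500L, 9000L, 9600L))
  expect_true(all(lengths(sl$windows) == 9000))
  # last stride window ends exactly at the end: no anchor needed
  expect_equal(segment_long(seq_len(13500), 9000, 0.5)$starts, c(0L, 4500L))
  # a 1-sample tail forces the anchor
  expect_equal(segment_long(seq_len(9001), 9000, 0.5)$starts, c(0L, 1L))
  expect_error(segment_long(seq_len(100), 200), "longer than the threshold")
  expect_error(segment_long(seq_len(300), 200, 1.5), "overlap_fraction")
})

test_that("chopping covers every sample and windows overlap as configured", {
  withr::with_seed(13, {
    for (i in 1:20) {
      L <- sample(201:2000, 1)
      x <- rnorm(L)
      sl <- segment_long(x, 200, 0.5)
      covered <- logical(L)
      for (j in seq_along(sl$starts)) {
        s <- sl$starts[j]
        covered[(s + 1):(s + 200)] <- TRUE
        expect_identical(sl$windows[[j]], x[(s + 1):(s + 200)])
      }
      expect_true(all(covered))
      # stride windows advance by T/2 (50% shared samples); only the final
      # end-anchored window may sit closer to its predecessor
      d <- diff(sl$starts)
      if (length(d) > 1) expect_true(all(d[-length(d)] == 100))
      if (length(d) > 0) expect_true(d[length(d)] <= 100)
    }
  })
})

test_that("tiling is periodic and exact", {
  # exact division: two full copies
  x <- rnorm(4500)
  expect_identical(tile_short(x, 9000), c(x, x))
  # truncated last copy, output[i] == input[i mod len]
  withr::with_seed(3, {
    for (i in 1:20) {
      n <- sample(50:199, 1)
      x <- rnorm(n)
      out <- tile_short(x, 200)
      expect_identical(out, x[((seq_len(200) - 1) %% n) + 1])
    }
  })
  expect_error(tile_short(numeric(0), 100), "non-empty")
  expect_error(tile_short(rnorm(100), 100), "shorter than the threshold")
})

test_that("normalize_dataset applies the equal/long/short branches", {
  # three recordings in three distinct duration bins: pin the threshold
  ds <- normalize_dataset(mixed_recordings(),
                          length_norm_config(threshold_samples = 9000))
  expect_equal(ds$threshold_samples, 9000L)
  expect_equal(nrow(ds$samples), 6)  # 4 (AF chopped) + 1 (tiled) + 1 (kept)
  expect_equal(ds$class_counts, c(4L, 1L, 0L, 1L))  # AF, Normal, Noisy, Other
  expect_true(all(ds$info$label == rep(c("AF", "Normal", "Other"),
                                       c(4, 1, 1))))
  # the equal-length record passes through unchanged
  kept <- ds$samples[ds$info$source_id == "R3", ]
  expect_identical(as.numeric(kept), mixed_recordings()[[3]]$samples)
  # label conservation and at least one segment per recording
  expect_true(nrow(ds$samples) >= 3)
})

test_that("a three-bin tie in the duration histogram picks the smallest", {
  # 62 s, 13.3 s and 30 s recordings: one per bin, tie resolves to 13 s
  lens <- vapply(mixed_recordings(), function(r) length(r$samples),
                 integer(1))
  expect_equal(compute_length_threshold(lens, 300), 13L * 300L)
})

test_that("normalize_dataset is deterministic and validates input", {
  a <- normalize_dataset(mixed_recordings())
  b <- normalize_dataset(mixed_recordings())
  expect_identical(a$samples, b$samples)
  expect_identical(a$info, b$info)
  expect_error(normalize_dataset(list()), "non-empty")
  recs <- list(ecg_recording("X", 1:9000, 300, "AF"),
               ecg_recording("Y", 1:9000, 200, "AF"))
  expect_error(normalize_dataset(recs), "one sampling rate")
})
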