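test_that("AF recordings carry the three AF signatures", {
  rr_cvs <- numeric(10)
  bands <- numeric(10)
  for (i in 1:10) {
    r <- gen_recording("AF", 30, seed = 100 + i)
    f <- ecg_features(r)
    rr_cvs[i] <- f["rr_cv"]
    bands[i] <- f["af_band_power"]
    # matched Normal recording for the band-power comparison
    fn <- ecg_features(gen_recording("Normal", 30, seed = 100 + i))
    # absent P wave: the pre-QRS window carries far less energy than Normal
    expect_lt(f["p_wave_energy"], 0.5 * fn["p_wave_energy"])
    expect_gt(bands[i], fn["af_band_power"])  # 4-8 Hz oscillation present
  }
  expect_true(all(rr_cvs > 0.15))  # irregular R-R intervals
})

test_that("Normal recordings have a regular rhythm with P waves", {
  for (i in 1:10) {
    f <- ecg_features(gen_recording("Normal", 30, seed = 200 + i))
    expect_lt(f["rr_cv"], 0.05)
    expect_gt(f["p_wave_energy"], 0.05)
  }
})

test_that("durations map exactly to sample counts", {
  expect_length(gen_recording("Other", 30, fs = 300, seed = 1)$samples, 9000)
  expect_length(gen_recording("Noisy", 9, fs = 300, seed = 1)$samples, 2700)
  expect_error(gen_recording("AF", 5, seed = 1), "within")
  expect_error(gen_recording("AF", 70, seed = 1), "within")
})

test_that("generation is bitwise reproducible for a fixed seed", {
  a <- gen_recording("AF", 35.5, seed = 99)
  b <- gen_recording("AF", 35.5, seed = 99)
  expect_identical(a$samples, b$samples)
  c1 <- gen_dataset(synth_config(c(AF = 3, Normal = 3, Noisy = 3, Other = 3),
                                 seed = 7))
  c2 <- gen_dataset(synth_config(c(AF = 3, Normal = 3, Noisy = 3, Other = 3),
                                 seed = 7))
  expect_identical(lapply(c1$recordings, `[[`, "samples"),
                   lapply(c2$recordings, `[[`, "samples"))
})

test_that("gen_dataset honors counts and the duration mixture", {
  d <- gen_dataset(synth_config(c(AF = 5, Normal = 5, Noisy = 5, Other = 5),
                                mode_weight = 1.0, seed = 3))
  expect_length(d$recordings, 20)
  expect_true(all(vapply(d$recordings, function(r) length(r$samples),
                         integer(1)) == 9000))
  expect_equal(unname(table(d$labels$label)[af_classes()]), rep(5L, 4),
               ignore_attr = TRUE)
  # class imbalance preserved when counts mirror the real cohort at 1/50
  cfg <- synth_config(c(AF = 15, Normal = 103, Noisy = 1, Other = 51),
                      seed = 5)
  d2 <- gen_dataset(cfg)
  expect_equal(unname(table(d2$labels$label)[af_classes()]),
               c(15L, 103L, 1L, 51L), ignore_attr = TRUE)
})

test_that("the modal duration bin drives the threshold to 9000 samples", {
  d <- gen_dataset(synth_config(c(AF = 25, Normal = 25, Noisy = 25,
                                  Other = 25),
                                mode_weight = 0.7, seed = 17))
  lens <- vapply(d$recordings, function(r) length(r$samples), integer(1))
  expect_equal(compute_length_threshold(lens, 300), 9000L)
})

test_that("two simple features linearly separate synthetic AF from Normal", {
  n <- 30
  feats <- rbind(
    t(vapply(1:n, function(i)
      ecg_features(gen_recording("AF", 30, seed = 2000 + i)), numeric(3))),
    t(vapply(1:n, function(i)
      ecg_features(gen_recording("Normal", 30, seed = 3000 + i)),
      numeric(3))))
  lab <- rep(c(1, 0), each = n)
  df <- data.frame(feats, lab = lab)
  fit <- suppressWarnings(
    stats::glm(lab ~ rr_cv + p_wave_energy, data = df, family = "binomial"))
  acc <- mean((stats::predict(fit, type = "response") > 0.5) == lab)
  expect_gte(acc, 0.95)
})

test_that("the fixture tree round trips through the record readers", {
  d <- gen_dataset(synth_config(c(AF = 1, Normal = 1, Noisy = 1, Other = 1),
                                seed = 29))
  dir <- withr::local_tempdir()
  write_fixture_tree(d$recordings, dir)
  labels <- read_label_table(file.path(dir, "REFERENCE.csv"))
  expect_equal(labels$label, d$labels$label)
  recs <- read_ecg_dir(dir, labels)
  for (i in seq_along(recs)) {
    expect_equal(recs[[i]]$fs, 300)
    # amplitudes survive 16-bit quantization at 1000 units/mV
    expect_lt(max(abs(recs[[i]]$samples - d$recordings[[i]]$samples)),
              5e-4 + 1e-9)
    expect_equal(recs[[i]]$label, d$recordings[[i]]$label)
  }
  # an empty set still writes a header-only label CSV
  dir2 <- withr::local_tempdir()
  write_fixture_tree(list(), dir2)
  empty <- read_label_table(file.path(dir2, "REFERENCE.csv"))
  expect_equal(nrow(empty), 0)
})
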