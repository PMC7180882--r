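test_that("confusion matrix places predictions in rows, truth in columns", {
  # perfect classifier: diagonal only
  labs <- rep(af_classes(), c(3, 4, 2, 1))
  cm <- confusion4(labs, labs)
  expect_equal(sum(diag(cm)), 10)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # single misclassification lands at [predicted, truth]
  cm1 <- confusion4("AF", "Other")
  expect_equal(cm1["Other", "AF"], 1L)
  expect_equal(sum(cm1), 1)
  # conservation on random label pairs
  withr::with_seed(31, {
    truth <- sample(af_classes(), 40, TRUE)
    pred <- sample(af_classes(), 40, TRUE)
  })
  expect_equal(sum(confusion4(truth, pred)), 40)
  expect_error(confusion4(c("AF", "AF"), "AF"), "equal length")
  expect_error(confusion4("AF", "Weird"), "unknown")
})

test_that("one-vs-rest collapse matches the hand tally and conserves totals", {
  cm <- confusion4(rep("Normal", 0), rep("Normal", 0))  # start from zeros
  cm["AF", "AF"] <- 8L
  cm["Other", "AF"] <- 2L
  cm["AF", "Normal"] <- 2L
  cm["Normal", "Normal"] <- 30L
  cm["Noisy", "Noisy"] <- 28L
  cm["Other", "Other"] <- 30L
  bc <- collapse_confusion(cm, "AF")
  expect_equal(bc$tp, 8)
  expect_equal(bc$fp, 2)
  expect_equal(bc$fn, 2)
  expect_equal(bc$tn, 88)
  # identity-diagonal matrix: no off-target counts
  perfect <- confusion4(rep(af_classes(), 5), rep(af_classes(), 5))
  b <- collapse_confusion(perfect, "Noisy")
  expect_equal(b$fp + b$fn, 0)
  # totals conserved for every target over random matrices
  withr::with_seed(17, {
    for (i in 1:100) {
      truth <- sample(af_classes(), 25, TRUE)
      pred <- sample(af_classes(), 25, TRUE)
      m <- confusion4(truth, pred)
      for (target in af_classes()) {
        b <- collapse_confusion(m, target)
        expect_equal(b$tp + b$fp + b$fn + b$tn, 25)
      }
    }
  })
})

test_that("precision, recall, accuracy and F1 match their formulas", {
  bc <- structure(list(tp = 8, fp = 2, fn = 2, tn = 88, target = "AF"),
                  class = "binary_confusion")
  expect_equal(precision_pct(bc), 80)
  expect_equal(recall_pct(bc), 80)
  expect_equal(accuracy_pct(bc), 96)
  expect_equal(f1_pct(80, 80), 80)           # harmonic mean of equals
  expect_equal(f1_pct(100, 50), 200 / 3)     # 66.67
  expect_equal(f1_pct(0, 100), 0)            # annihilation
  expect_equal(f1_pct(0, 0), 0)              # convention
  # degenerate: no positive predictions
  empty <- structure(list(tp = 0, fp = 0, fn = 3, tn = 7, target = "AF"),
                     class = "binary_confusion")
  expect_warning(p <- precision_pct(empty), "zero denominator")
  expect_equal(p, 0)
})

test_that("F1 is symmetric and bounded by max(P, R)", {
  withr::with_seed(23, {
    for (i in 1:50) {
      p <- runif(1, 0, 100)
      r <- runif(1, 0, 100)
      f <- f1_pct(p, r)
      expect_equal(f, f1_pct(r, p))
      expect_lte(f, max(p, r) + 1e-9)
      expect_gte(f, 0)
    }
  })
})

test_that("average F1 reproduces the reported per-class aggregation", {
  expect_equal(average_f1(c(70, 70, 70, 70)), 70)
  # the selected model's per-class scores average to 77.8 after rounding
  expect_equal(round(average_f1(c(79.1, 90.7, 65.3, 76.0)), 1), 77.8)
  expect_equal(average_f1(c(79.1, 90.7, 65.3, 76.0)), 77.775)
  # three-class mean (excluding Noisy) used in cross-method comparisons
  expect_equal(round(mean(c(80.8, 90.4, 75.3)), 1), 82.2)
})

test_that("metrics_report aggregates a full matrix consistently", {
  withr::with_seed(41, {
    truth <- sample(af_classes(), 200, TRUE)
    pred <- ifelse(runif(200) < 0.7, truth, sample(af_classes(), 200, TRUE))
  })
  rep <- metrics_report(confusion4(truth, pred))
  expect_equal(rep$average_f1, mean(rep$per_class$f1))
  expect_equal(rep$average_f1_3class,
               mean(rep$per_class$f1[rep$per_class$class != "Noisy"]))
  expect_equal(rep$accuracy, 100 * mean(truth == pred))
  # micro-accuracy is invariant under class relabeling of the pairs
  perm <- c(Other = "AF", AF = "Other", Normal = "Noisy", Noisy = "Normal")
  rep2 <- metrics_report(confusion4(unname(perm[truth]), unname(perm[pred])))
  expect_equal(rep2$accuracy, rep$accuracy)
})

test_that("cv_report averages folds and reports the fold spread", {
  mk <- function(truth, pred) metrics_report(confusion4(truth, pred))
  labs <- rep(af_classes(), each = 5)
  identical_folds <- list(mk(labs, labs), mk(labs, labs))
  agg <- cv_report(identical_folds)
  expect_equal(agg$sigma, 0)
  expect_equal(agg$average_f1, 100)
  # two folds with known average F1: population sigma
  r1 <- mk(labs, labs)
  r1$average_f1 <- 70
  r2 <- mk(labs, labs)
  r2$average_f1 <- 80
  agg2 <- cv_report(list(r1, r2))
  expect_equal(agg2$average_f1, 75)
  expect_equal(agg2$sigma, 5)
  expect_equal(cv_report(list(r1, r2), sd_type = "sample")$sigma,
               stats::sd(c(70, 80)))
  # five-fold mean equals the hand-computed mean
  withr::with_seed(12, {
    reps <- lapply(1:5, function(i) {
      truth <- sample(af_classes(), 40, TRUE)
      pred <- ifelse(runif(40) < 0.6, truth, sample(af_classes(), 40, TRUE))
      mk(truth, pred)
    })
  })
  agg5 <- cv_report(reps)
  expect_equal(agg5$average_f1,
               mean(vapply(reps, function(r) r$average_f1, numeric(1))))
})
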