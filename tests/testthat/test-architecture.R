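# frozen reference values for the canonical ten-block stack (kernel 5,
# input 9000): conv output lengths, channels, per-layer parameter counts
REF_CONV_LENS <- c(8996, 4494, 2243, 1117, 554, 273, 132, 62, 27, 9)
REF_CONV_CH <- c(32, 32, 64, 64, 128, 128, 256, 256, 512, 512)
REF_PARAM_ROWS <- c(192, 128, 5152, 10304, 20544, 41088, 82048, 164096,
                    327936, 655872, 1311232, 589952, 4128, 132)
REF_TRAINABLE <- 3212740

test_that("the analytic shape chain matches the canonical stack exactly", {
  s <- compute_layer_summaries(make_variant("Proposed-1"))
  conv <- s[s$layer_kind == "conv", ]
  expect_equal(conv$output_len, REF_CONV_LENS)
  expect_equal(conv$channels, REF_CONV_CH)
  # parameterized layers row by row (conv, BN, dense)
  expect_equal(s$params_total[s$params_total > 0], REF_PARAM_ROWS)
  # BN: 4 statistics per channel in total, 2 trainable
  bn <- s[s$layer_kind == "bn", ]
  expect_equal(bn$params_total, 128)
  expect_equal(bn$params_trainable, 64)
  expect_equal(count_trainable(make_variant("Proposed-1")), REF_TRAINABLE)
  expect_equal(count_params(make_variant("Proposed-1")), REF_TRAINABLE + 64)
})

test_that("variant parameter counts follow their structural changes", {
  counts <- vapply(c("Proposed-1", "Proposed-2", "All-BN", "No-BN",
                     "Maxpooling", "Max-Average", "Extra-Average"),
                   function(v) count_trainable(make_variant(v)), numeric(1))
  expect_equal(unname(counts["Proposed-1"]), 3212740)
  expect_equal(unname(counts["Proposed-2"]), 3212740)  # pooling type is free
  expect_equal(unname(counts["All-BN"]), 3216644)
  expect_equal(unname(counts["No-BN"]), 3212676)
  expect_equal(unname(counts["Maxpooling"]), 2885060)
  expect_equal(unname(counts["Max-Average"]), 2885060)
  expect_equal(unname(counts["Extra-Average"]), 2885060)
})

test_that("variant structure matches its definition", {
  p1 <- make_variant("Proposed-1", 5, 10)
  expect_length(p1$blocks, 10)
  expect_equal(vapply(p1$blocks, function(b) b$has_bn, logical(1)),
               c(TRUE, rep(FALSE, 9)))
  expect_true(all(vapply(p1$blocks[-10], function(b) b$pool,
                         character(1)) == "max"))
  expect_equal(p1$blocks[[10]]$pool, "none")
  # dropout 0.5 after blocks 6, 8, 9
  expect_equal(which(!is.na(vapply(p1$blocks, function(b) b$dropout_after,
                                   numeric(1)))), c(6L, 8L, 9L))
  # filter doubling schedule
  expect_equal(vapply(p1$blocks, function(b) b$filters, integer(1)),
               as.integer(c(32, 32, 64, 64, 128, 128, 256, 256, 512, 512)))
  allbn <- make_variant("All-BN", 5, 10)
  expect_true(all(vapply(allbn$blocks, function(b) b$has_bn, logical(1))))
  p2 <- make_variant("Proposed-2")
  expect_true(all(vapply(p2$blocks[-10], function(b) b$pool,
                         character(1)) == "average"))
  ea <- make_variant("Extra-Average")
  expect_equal(ea$pre_flatten_pool, "average")
  expect_error(make_variant("NotAVariant"), "arg")
})

test_that("pre-flatten pooling halves the dense input (4608 to 2048)", {
  s1 <- compute_layer_summaries(make_variant("Proposed-1"))
  s2 <- compute_layer_summaries(make_variant("Maxpooling"))
  expect_equal(s1$output_len[s1$layer_kind == "flatten"], 4608)
  expect_equal(s2$output_len[s2$layer_kind == "flatten"], 2048)
  d1 <- s1[s1$layer_kind == "dense", "params_total"][1]
  d2 <- s2[s2$layer_kind == "dense", "params_total"][1]
  expect_equal(d1, 4608 * 128 + 128)
  expect_equal(d2, 2048 * 128 + 128)
})

test_that("feasibility detects stacks that run out of samples", {
  expect_false(check_feasible(11, 5, 9000))
  expect_false(check_feasible(11, 7, 9000))
  expect_true(check_feasible(11, 3, 9000))
  expect_true(check_feasible(10, 7, 9000))
  expect_true(check_feasible(10, 5, 9000))
  # infeasible spec errors name the failing layer
  expect_error(compute_layer_summaries(make_variant("Proposed-1",
                                                    n_conv_layers = 11)),
               "conv block 11")
})

test_that("architecture specs survive list/JSON serialization", {
  for (v in c("Proposed-2", "All-BN", "Extra-Average")) {
    spec <- make_variant(v)
    json <- jsonlite::toJSON(spec_to_list(spec), auto_unbox = TRUE)
    back <- spec_from_list(jsonlite::fromJSON(json, simplifyDataFrame = FALSE))
    expect_equal(count_trainable(back), count_trainable(spec))
    expect_equal(compute_layer_summaries(back),
                 compute_layer_summaries(spec))
  }
})
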