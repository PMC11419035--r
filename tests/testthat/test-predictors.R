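test_that("build_confusion maps labels and calls to the four cells", {
  labels <- data.frame(record_id = sprintf("r%02d", 1:20),
                       cohort = rep(c("AL", "MM"), each = 10))
  preds <- data.frame(record_id = labels$record_id,
                      call = c(rep("amyloidogenic", 10),
                               rep("non-amyloidogenic", 10)))
  cm <- build_confusion(preds, labels)
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
  # all-missing predictions: empty confusion with a warning
  preds_na <- transform(preds, call = NA_character_)
  expect_warning(cm0 <- build_confusion(preds_na, labels), "missing")
  expect_equal(cm0$n_missing, 20L)
  expect_equal(cm0$tp + cm0$fp + cm0$tn + cm0$fn, 0L)
  expect_error(build_confusion(data.frame(record_id = "zz", call = "amyloidogenic"),
                               labels), "zz")
})

test_that("a mixed fixture with known flips matches the hand tally", {
  withr::local_seed(44)
  labels <- data.frame(record_id = sprintf("m%02d", 1:20),
                       cohort = sample(c("AL", "MM", "control"), 20, TRUE))
  truth_pos <- labels$cohort == "AL"
  flip <- seq_len(20) %in% sample(20, 6)
  miss <- seq_len(20) %in% sample(20, 3)
  call <- ifelse(xor(truth_pos, flip), "amyloidogenic", "non-amyloidogenic")
  call[miss] <- NA
  cm <- build_confusion(data.frame(record_id = labels$record_id, call = call),
                        labels)
  k <- !miss
  expect_equal(cm$tp, sum(k & truth_pos & !flip))
  expect_equal(cm$fn, sum(k & truth_pos & flip))
  expect_equal(cm$tn, sum(k & !truth_pos & !flip))
  expect_equal(cm$fp, sum(k & !truth_pos & flip))
  expect_equal(cm$n_missing, 3L)
})

test_that("metrics implement the three formulas with NA for 0/0", {
  m <- metrics(list(tp = 90, fn = 10, tn = 0, fp = 0))
  expect_equal(m$sensitivity, 0.9)
  expect_true(is.na(m$specificity))
  m2 <- metrics(list(tp = 50, fn = 50, tn = 50, fp = 50))
  expect_equal(unlist(m2), c(sensitivity = 0.5, specificity = 0.5,
                             accuracy = 0.5))
  m3 <- metrics(list(tp = 120, fn = 35, tn = 1300, fp = 135))
  expect_equal(m3$accuracy, 1420 / 1590)
  m0 <- metrics(list(tp = 0, fn = 0, tn = 0, fp = 0))
  expect_true(all(is.na(unlist(m0))))
})

test_that("metric identities hold on random confusions", {
  withr::local_seed(13)
  for (i in 1:20) {
    cm <- as.list(setNames(sample(1:200, 4), c("tp", "fp", "tn", "fn")))
    m <- metrics(cm)
    prev <- (cm$tp + cm$fn) / (cm$tp + cm$fn + cm$tn + cm$fp)
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity)
    swapped <- metrics(list(tp = cm$tn, tn = cm$tp, fp = cm$fn, fn = cm$fp))
    expect_equal(swapped$sensitivity, m$specificity)
    expect_equal(swapped$specificity, m$sensitivity)
  }
})

test_that("per-tool evaluation respects chain capability", {
  labels <- data.frame(record_id = sprintf("r%02d", 1:20),
                       cohort = rep(c("AL", "MM"), 10),
                       locus = rep(c("IGK", "IGL"), each = 10))
  preds <- rbind(
    data.frame(record_id = labels$record_id, tool = "broad",
               call = "amyloidogenic"),
    data.frame(record_id = labels$record_id, tool = "lambda_only",
               call = "amyloidogenic"))
  out <- evaluate_predictions(preds, labels,
                              tool_chains = list(lambda_only = "IGL"))
  expect_equal(out$n_evaluated[out$tool == "broad"], 20L)
  expect_equal(out$n_evaluated[out$tool == "lambda_only"], 10L)
  expect_equal(out$specificity[out$tool == "broad"], 0)
  expect_equal(out$sensitivity[out$tool == "broad"], 1)
})
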