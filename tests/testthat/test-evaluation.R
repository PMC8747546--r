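test_that("confusion counts the four cells against the declared positive", {
  c1 <- confusion(
    c("normal", "normal", "anomalous", "anomalous"),
    c("normal", "anomalous", "normal", "anomalous")
  )
  expect_equal(c(c1$tp, c1$tn, c1$fp, c1$fn), c(1, 1, 1, 1))

  all_pos <- confusion(rep("normal", 5), rep("normal", 5))
  expect_equal(c(all_pos$tp, all_pos$tn, all_pos$fp, all_pos$fn), c(5, 0, 0, 0))

  set.seed(91)
  for (rep in 1:20) {
    truth <- sample(c("normal", "anomalous"), 50, replace = TRUE)
    pred <- sample(c("normal", "anomalous"), 50, replace = TRUE)
    got <- confusion(truth, pred)
    want <- oracle_confusion(truth, pred, "normal")
    expect_equal(
      c(tp = got$tp, tn = got$tn, fp = got$fp, fn = got$fn), want
    )
  }
  expect_error(confusion("normal", c("normal", "normal")), "length")
  expect_error(confusion(c("a", "b"), c("c", "d")), "not binary")
})

test_that("swapping the positive class transposes the confusion cells", {
  set.seed(92)
  truth <- sample(c("normal", "anomalous"), 40, replace = TRUE)
  pred <- sample(c("normal", "anomalous"), 40, replace = TRUE)
  a <- confusion(truth, pred, positive = "normal")
  b <- confusion(truth, pred, positive = "anomalous")
  expect_equal(a$tp, b$tn)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
})

test_that("metrics match their formulas on fixed and random counts", {
  c1 <- confusion_counts(3, 2, 1, 0)
  expect_equal(accuracy_score(c1), 5 / 6)
  c2 <- confusion_counts(50, 40, 10, 0)
  expect_equal(accuracy_score(c2), 0.9)
  expect_equal(as.numeric(precision_score(c2)), 5 / 6)
  expect_equal(as.numeric(recall_score(c2)), 1)
  expect_equal(as.numeric(f1_score(c2)), 10 / 11)

  set.seed(93)
  for (rep in 1:20) {
    k <- confusion_counts(
      sample(0:30, 1) + 1, sample(0:30, 1), sample(0:30, 1) + 1, sample(0:30, 1)
    )
    p <- k$tp / (k$tp + k$fp)
    r <- k$tp / (k$tp + k$fn)
    expect_equal(as.numeric(precision_score(k)), p)
    expect_equal(as.numeric(recall_score(k)), r)
    f <- as.numeric(f1_score(k))
    expect_equal(f, 2 * p * r / (p + r))
    expect_true(f >= min(p, r) - 1e-12 && f <= max(p, r) + 1e-12)
    expect_equal(
      accuracy_score(k), (k$tp + k$tn) / (k$tp + k$tn + k$fp + k$fn)
    )
  }
})

test_that("zero-denominator metrics return flagged zeros instead of failing", {
  none_pred <- confusion_counts(0, 10, 0, 5)
  p <- precision_score(none_pred)
  expect_equal(as.numeric(p), 0)
  expect_true(isTRUE(attr(p, "degenerate")))
  none_truth <- confusion_counts(0, 10, 3, 0)
  r <- recall_score(none_truth)
  expect_true(isTRUE(attr(r, "degenerate")))
  expect_error(accuracy_score(confusion_counts(0, 0, 0, 0)), "no observations")
  rep <- metrics_report(none_pred)
  expect_equal(rep$f1, 0, ignore_attr = TRUE)
})

test_that("evaluate_detector is consistent with its own confusion counts", {
  sp <- prepared_split(40, 20, seed = 51, series_length = 20L)
  det <- fit_detector(
    subset_normals(sp$train), "cat_ae",
    config = train_config(epochs = 30L, batch_size = 16L, seed = 7L)
  )
  rep <- evaluate_detector(det, sp$test)
  expect_equal(rep$accuracy, accuracy_score(rep$counts))
  expect_equal(rep$f1, f1_score(rep$counts), ignore_attr = TRUE)
  total <- rep$counts$tp + rep$counts$tn + rep$counts$fp + rep$counts$fn
  expect_equal(total, n_beats(sp$test))

  # permutation invariance
  perm <- rev(seq_len(n_beats(sp$test)))
  rep2 <- evaluate_detector(det, sp$test[perm])
  expect_equal(rep2$accuracy, rep$accuracy)

  # an always-normal detector on an all-normal test set is perfect
  lazy <- structure(
    list(
      model = function(x) x, threshold = 1,
      distribution = loss_distribution(c(0, 0.1)), model_type = "ae",
      normalization = NULL
    ),
    class = "threshold_detector"
  )
  all_norm <- subset_normals(sp$test)
  expect_equal(evaluate_detector(lazy, all_norm)$accuracy, 1)
})

test_that("metrics reports round-trip through the key-value file", {
  rep <- metrics_report(confusion_counts(50, 40, 10, 0), model_name = "cat_ae")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_report(rep, path)
  back <- read_metrics_report(path)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$f1, rep$f1, tolerance = 1e-9)
  expect_equal(back$tp, 50L)
  expect_equal(back$model, "cat_ae")
})
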