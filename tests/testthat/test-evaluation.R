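# Metrics, confusion bookkeeping, PR sweeps and the study runner.

test_that("confusion counts match direct enumeration", {
  ct <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(tidy(ct)[, 1:4],
               tibble::tibble(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  z <- confusion(logical(0), logical(0))
  expect_equal(confusion_total(z), 0)
  expect_error(confusion(c(TRUE, FALSE), TRUE), "same length")
  # loop oracle on random vectors
  set.seed(71)
  truth <- runif(500) < 0.3
  pred <- runif(500) < 0.5
  ct <- confusion(truth, pred)
  tp <- fn <- fp <- tn <- 0L
  for (i in 1:500) {
    if (truth[i] && pred[i]) tp <- tp + 1L
    else if (truth[i]) fn <- fn + 1L
    else if (pred[i]) fp <- fp + 1L
    else tn <- tn + 1L
  }
  expect_equal(unclass(ct), list(tp = tp, fn = fn, fp = fp, tn = tn),
               ignore_attr = TRUE)
  # cell-wise addition
  s <- ct + ct
  expect_equal(s$tp, 2L * tp)
  expect_equal(confusion_total(s), 1000)
})

test_that("precision/recall/F-measure handle degenerate tables as NA", {
  m <- prf(new_confusion(tp = 8, fn = 2, fp = 4, tn = 6))
  expect_equal(m$precision, 8 / 12)
  expect_equal(m$recall, 8 / 10)
  expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
  # harmonic-mean fixed point: p == r == x gives f1 == x
  for (x in c(0.1, 0.5, 0.93)) expect_equal(f_measure(x, x), x)
  # zero denominators are undefined, never coerced
  no_pred <- prf(new_confusion(0, 5, 0, 10))
  expect_true(is.na(no_pred$precision))
  expect_true(is.na(no_pred$f1))
  no_truth <- prf(new_confusion(0, 0, 3, 10))
  expect_true(is.na(no_truth$recall))
  # all-wrong: defined zero
  expect_equal(prf(new_confusion(0, 5, 3, 10))$f1, 0)
})

test_that("F-measure lies between precision and recall (fuzzed)", {
  set.seed(72)
  for (i in 1:10000) {
    ct <- new_confusion(sample(0:50, 1), sample(0:50, 1),
                        sample(0:50, 1), sample(0:50, 1))
    m <- prf(ct)
    if (!is.na(m$f1)) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("pr_curve sweeps thresholds like the brute-force evaluation", {
  # perfect detector: a point with p = 1, r = 1
  truth <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- c(rep(1, 5), rep(0, 5))
  pr <- pr_curve(truth, perfect)
  expect_true(any(pr$precision == 1 & pr$recall == 1))
  # threshold 0 predicts everything positive: recall 1
  set.seed(73)
  scores <- runif(200)
  truth <- runif(200) < 0.25
  pr <- pr_curve(truth, scores)
  expect_equal(pr$recall[pr$threshold == 0], 1)
  # recall non-increasing in threshold
  expect_true(all(diff(pr$recall) <= 1e-12))
  # per-threshold brute force oracle
  for (j in seq_len(nrow(pr))) {
    tau <- pr$threshold[j]
    pred <- scores >= tau
    expect_equal(pr$precision[j], sum(truth & pred) / sum(pred))
    expect_equal(pr$recall[j], sum(truth & pred) / sum(truth))
  }
  # the filtered variant additionally gates on the final label
  fl <- sample(c("ablation", "targeting", "other"), 200, replace = TRUE)
  prf_ <- pr_curve(truth, scores, final_label = fl)
  for (j in seq_len(nrow(prf_))) {
    pred <- (fl == "ablation") & scores >= prf_$threshold[j]
    expect_equal(prf_$recall[j], sum(truth & pred) / sum(truth))
  }
  expect_error(pr_curve(truth, scores[1:10]), "same length")
  expect_error(pr_curve(truth, scores * 2), "0, 1")
})

test_that("study reports tally per-fold and cumulative results", {
  rep_ <- study_report()
  ps <- rep_$per_sequence
  cum <- rep_$cumulative
  for (m in unique(ps$method)) {
    rows <- ps[ps$method == m, ]
    crow <- cum[cum$method == m, ]
    # cumulative confusion is the cell-wise sum of the fold confusions
    expect_equal(crow$tp, sum(rows$tp))
    expect_equal(crow$fn, sum(rows$fn))
    expect_equal(crow$fp, sum(rows$fp))
    expect_equal(crow$tn, sum(rows$tn))
    # totals cover every annotated validation frame exactly once
    expect_equal(crow$tp + crow$fn + crow$fp + crow$tn,
                 nrow(study_dataset()))
  }
  # filtered positives are a subset of raw positives in every fold
  preds <- rep_$predictions
  for (f in unique(preds$fold)) {
    raw <- preds[preds$method == "raw_cnn" & preds$fold == f, ]
    fil <- preds[preds$method == "filtered_cnn" & preds$fold == f, ]
    expect_true(all(!fil$pred | raw$pred))
  }
  # tidiers expose the same tables
  expect_identical(tidy(rep_), ps)
  expect_identical(glance(rep_), cum)
  # timelines cover each validation procedure
  expect_setequal(names(rep_$timelines),
                  unique(study_dataset()$procedure_id))
})

test_that("evaluation reruns bitwise-identically under pinned seeds", {
  ds <- tiny_procedures()
  run <- function() {
    evaluate_study(ds, methods = c("raw_cnn", "filtered_cnn"),
                   train_cfg = train_config(iterations = 120, seed = 1),
                   seed = 9)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$per_sequence, r2$per_sequence)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$pr, r2$pr)
})

test_that("reports serialise to CSV and JSON", {
  rep_ <- study_report()
  dir <- file.path(tempdir(), "report-out")
  write_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "per_sequence.csv")))
  expect_true(file.exists(file.path(dir, "pr_curve.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true(all(c("cumulative", "timelines", "config") %in% names(js)))
})

test_that("result plots build without error", {
  rep_ <- study_report()
  expect_s3_class(plot_pr_curve(rep_$pr), "ggplot")
  expect_s3_class(autoplot(rep_), "ggplot")
  expect_s3_class(plot_timeline(rep_$timelines[[1]]$predicted), "ggplot")
  expect_s3_class(plot_timeline(rep_$timelines[[1]]), "ggplot")
  expect_s3_class(autoplot(tiny_model()), "ggplot")
})
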