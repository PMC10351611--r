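# Evaluation metrics: confusion-matrix arithmetic, IoU geometry, mIoU
# averaging convention, and all-point interpolated average precision
# against an enumeration oracle.

rec <- function(id, score, box = NULL) mfadnet:::detection_record(id, score, box)

test_that("confusion-derived metrics match closed-form arithmetic", {
  man <- data.frame(image_id = sprintf("i%03d", 1:390),
                    label = rep(c(1L, 0L), c(130, 260)))
  # scores arranged to give TP=120, FN=10, TN=250, FP=10
  scores <- c(rep(0.9, 120), rep(0.1, 10), rep(0.1, 250), rep(0.9, 10))
  recs <- Map(rec, man$image_id, scores)
  m <- classification_metrics(recs, man)
  expect_equal(m$sensitivity, 12 / 13, tolerance = 1e-9)
  expect_equal(m$specificity, 25 / 26, tolerance = 1e-9)
  expect_equal(m$accuracy, 370 / 390, tolerance = 1e-9)
  expect_equal(m$f1, 240 / 260, tolerance = 1e-9)
  expect_identical(m$confusion, c(TP = 120L, FP = 10L, TN = 250L,
                                  FN = 10L))
  expect_identical(sum(m$confusion), 390L)
  # metrics recomputed from the emitted confusion matrix agree exactly
  cm <- m$confusion
  expect_identical(m$accuracy, unname((cm["TP"] + cm["TN"]) / sum(cm)))
  expect_identical(m$f1, unname(2 * cm["TP"] /
                                  (2 * cm["TP"] + cm["FP"] + cm["FN"])))
})

test_that("perfect and degenerate classification cases behave", {
  man <- data.frame(image_id = c("a", "b"), label = c(1L, 0L))
  m <- classification_metrics(list(rec("a", 1), rec("b", 0)), man)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity", "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, f1 = 1))
  man0 <- data.frame(image_id = c("a", "b"), label = c(0L, 0L))
  warns <- capture_warnings(
    m0 <- classification_metrics(list(rec("a", 0.1), rec("b", 0.2)), man0))
  expect_match(warns, "sensitivity", all = FALSE)
  expect_true(is.nan(m0$sensitivity))
  expect_error(classification_metrics(list(rec("a", 1)), man),
               "no detection record .* b")
})

test_that("IoU follows half-open area arithmetic", {
  a <- bounding_box(0, 0, 10, 10)
  expect_identical(box_iou(a, a), 1)
  expect_identical(box_iou(a, bounding_box(20, 20, 30, 30)), 0)
  b <- bounding_box(5, 5, 15, 15)
  expect_equal(box_iou(a, b), 25 / 175, tolerance = 1e-9)
  expect_identical(box_iou(a, b), box_iou(b, a))
  # touching edges do not intersect under the half-open convention
  expect_identical(box_iou(a, bounding_box(10, 0, 20, 10)), 0)
})

test_that("mean IoU averages over all stone images with misses as zero", {
  gt <- list(a = bounding_box(0, 0, 10, 10), b = bounding_box(2, 2, 6, 6))
  recs <- list(rec("a", 0.9, bounding_box(5, 5, 15, 15)),
               rec("b", 0.8, bounding_box(2, 2, 6, 6)))
  expect_equal(mean_iou(recs, gt), (1 / 7 + 1) / 2, tolerance = 1e-9)
  # a missing prediction contributes zero
  expect_equal(mean_iou(recs[2], gt), 0.5)
  expect_equal(mean_iou(list(rec("a", 0.9), rec("b", 0.8)), gt), 0)
  # perfect predictions
  perfect <- list(rec("a", 1, gt$a), rec("b", 1, gt$b))
  expect_identical(mean_iou(perfect, gt), 1)
})

test_that("average precision matches the enumeration oracle", {
  gt <- list(p1 = bounding_box(0, 0, 4, 4), p2 = bounding_box(8, 8, 12, 12),
             p3 = bounding_box(2, 8, 6, 12))
  # (0.9, hit), (0.8, miss), (0.7, hit); third positive undetected
  recs <- list(rec("p1", 0.9, gt$p1),
               rec("p2", 0.8, bounding_box(0, 8, 2, 10)),
               rec("p3", 0.7, gt$p3))
  got <- average_precision(recs, gt)
  want <- oracle_ap(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 3)
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(got, 1 / 3 + 1 / 3 * 2 / 3, tolerance = 1e-9)
  # order of records is irrelevant
  expect_equal(average_precision(rev(recs), gt), got)
  # single correct detection, no false positives
  expect_identical(average_precision(list(rec("p1", 0.9, gt$p1)),
                                     gt["p1"]), 1)
  # all boxes under the IoU threshold
  off <- list(rec("p1", 0.9, bounding_box(20, 20, 24, 24)))
  expect_identical(average_precision(off, gt), 0)
})

test_that("randomised AP cases agree with the oracle", {
  set.seed(55)
  for (k in 1:25) {
    n_pos <- sample(2:6, 1)
    gt <- stats::setNames(lapply(seq_len(n_pos), function(i)
      bounding_box(10 * i, 0, 10 * i + 4, 4)),
      sprintf("p%d", seq_len(n_pos)))
    hits <- runif(n_pos) < 0.6
    detected <- runif(n_pos) < 0.8
    scores <- sample(seq_len(1000), n_pos) / 1000  # distinct scores
    recs <- lapply(which(detected), function(i)
      rec(sprintf("p%d", i), scores[i],
          if (hits[i]) gt[[i]] else bounding_box(200, 200, 204, 204)))
    if (length(recs) == 0) next
    got <- average_precision(recs, gt)
    want <- oracle_ap(scores[detected], hits[detected], n_pos)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("full evaluation report combines parts and validates coverage", {
  man <- data.frame(image_id = c("a", "b", "c"), label = c(1L, 1L, 0L))
  gt <- list(a = bounding_box(0, 0, 4, 4), b = bounding_box(4, 4, 8, 8))
  recs <- list(rec("a", 0.9, gt$a), rec("b", 0.4), rec("c", 0.2))
  r <- evaluate_detections(recs, man, gt)
  expect_s3_class(r, "mfadnet_metrics")
  expect_equal(r$miou, 0.5)
  expect_equal(r$accuracy, 2 / 3, tolerance = 1e-9)
  expect_error(evaluate_detections(recs, man, gt["a"]), "missing")
})
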