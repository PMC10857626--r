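test_that("confusion matrices count, normalize, and average correctly", {
  cm <- confusion(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unname(cm$normalized),
               matrix(c(0.5, 0, 0.5, 1), 2, 2))
  expect_equal(cm$mean_class_accuracy, 0.75)
  expect_equal(cm$overall_accuracy, 0.75)
  perfect <- confusion(letters[1:4], letters[1:4])
  expect_equal(unname(perfect$normalized), diag(4))
  expect_equal(perfect$mean_class_accuracy, 1)
  expect_error(confusion(c("a", "b"), c("a", "z"), c("a", "b")),
               "outside the class set")
  set.seed(61)
  yt <- sample(letters[1:3], 60, replace = TRUE)
  yp <- sample(letters[1:3], 60, replace = TRUE)
  cm2 <- confusion(yt, yp)
  expect_equal(unname(rowSums(cm2$normalized)), rep(1, 3),
               tolerance = 1e-9)
  # identities: overall = trace/total, mean class accuracy = macro recall
  expect_equal(cm2$overall_accuracy,
               sum(diag(cm2$counts)) / sum(cm2$counts))
  expect_equal(cm2$mean_class_accuracy,
               prf1(cm2$counts)$macro[["recall"]])
})

test_that("precision/recall/F1 match direct definitions", {
  perfect <- confusion(letters[1:3], letters[1:3])
  pr <- prf1(perfect$counts)
  expect_true(all(pr$per_class[, c("precision", "recall", "f1")] == 1))
  # TP=2, FP=1, FN=1 for class a
  cm <- confusion(c("a", "a", "a", "b", "b", "b"),
                  c("a", "a", "b", "a", "b", "b"))
  pr2 <- prf1(cm$counts)
  a <- pr2$per_class[pr2$per_class$class == "a", ]
  expect_equal(a$precision, 2 / 3)
  expect_equal(a$recall, 2 / 3)
  expect_equal(a$f1, 2 / 3)
  # precision 1, recall 0 -> F1 = 0 (harmonic mean with a zero)
  m <- matrix(c(0, 0, 2, 4), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  pr3 <- suppressWarnings(prf1(m))
  expect_equal(pr3$per_class$f1[1], 0)
})

test_that("prf1 is equivariant under class relabeling", {
  set.seed(62)
  yt <- sample(c("a", "b", "c"), 90, replace = TRUE)
  yp <- sample(c("a", "b", "c"), 90, replace = TRUE)
  pr <- prf1(confusion(yt, yp)$counts)
  swap <- c(a = "c", b = "a", c = "b")
  pr2 <- prf1(confusion(unname(swap[yt]), unname(swap[yp]))$counts)
  for (cl in c("a", "b", "c")) {
    expect_equal(
      pr$per_class[pr$per_class$class == cl, c("precision", "recall", "f1")],
      pr2$per_class[pr2$per_class$class == swap[[cl]],
                    c("precision", "recall", "f1")],
      ignore_attr = TRUE)
  }
  expect_equal(pr$macro, pr2$macro)
})

test_that("ROC AUC matches worked examples and the pairwise oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc, 0.75)
  expect_warning(r <- roc_auc(c(1, 1), c(0.2, 0.4)), "single-class")
  expect_true(is.na(r$auc))
  set.seed(63)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    truth <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)   # duplicates exercise tie handling
    expect_equal(roc_auc(truth, scores)$auc, bf_auc(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  truth <- sample(c(0, 1), 50, replace = TRUE)
  scores <- rnorm(50) + truth
  expect_equal(roc_auc(truth, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("evaluation reports render deterministically and round-trip", {
  set.seed(65)
  classes <- c("lie", "run", "sit", "walk")
  yt <- sample(classes, 80, replace = TRUE)
  prob <- matrix(runif(320), 80, 4, dimnames = list(NULL, classes))
  prob <- prob / rowSums(prob)
  # nudge probabilities toward the truth so predictions are non-trivial
  prob[cbind(1:80, match(yt, classes))] <-
    prob[cbind(1:80, match(yt, classes))] + 1
  prob <- prob / rowSums(prob)
  yp <- classes[max.col(prob)]
  rep_ <- evaluation_report(yt, yp, prob, classes)
  expect_equal(dim(rep_$normalized), c(4, 4))
  expect_true(all(rep_$auc >= 0 & rep_$auc <= 1))
  d <- withr::local_tempdir()
  p1 <- file.path(d, "r1.json"); p2 <- file.path(d, "r2.json")
  render_report(rep_, p1)
  render_report(rep_, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- parse_report(p1)
  expect_equal(back$overall_accuracy, rep_$overall_accuracy)
  expect_equal(back$mean_class_accuracy, rep_$mean_class_accuracy)
  expect_equal(back$macro$f1, unname(rep_$macro["f1"]))
  txt <- readLines(file.path(d, "r1.txt"))
  expect_true(any(grepl("Mean Accuracy", txt)))
  expect_length(grep("lie|run|sit|walk", txt), 5)  # 4 rows + header
})
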