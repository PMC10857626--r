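#' Confusion matrix with row normalization
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted
#' as class `j`; the normalized matrix divides each row by its support,
#' so every supported row sums to 1 (zero-support rows are rendered as
#' zeros). The mean per-class accuracy is the mean of the normalized
#' diagonal over classes with support — identical to macro recall.
#'
#' @param y_true,y_pred equal-length label vectors; every prediction
#'   must be in `classes`.
#' @param classes class vocabulary; default sorted union of the truth
#'   labels.
#' @return object of class `confusion` with `counts`, `normalized`,
#'   `overall_accuracy` (trace/total) and `mean_class_accuracy`.
#' @export
confusion <- function(y_true, y_pred, classes = sort(unique(y_true))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal lengths")
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown) > 0L)
    stop("label(s) outside the class set: ", paste(unknown, collapse = ", "))
  counts <- table(factor(y_true, levels = classes),
                  factor(y_pred, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, pred = classes))
  support <- rowSums(counts)
  normalized <- counts / ifelse(support > 0, support, 1)
  normalized[support == 0, ] <- 0
  diagonal <- diag(normalized)
  structure(
    list(classes = classes, counts = counts, normalized = normalized,
         support = support,
         overall_accuracy = sum(diag(counts)) / max(1, sum(counts)),
         mean_class_accuracy = mean(diagonal[support > 0])),
    class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  print(round(x$normalized, 2))
  cat(sprintf("Mean Accuracy = %.2f%%\n", 100 * x$mean_class_accuracy))
  invisible(x)
}

#' Per-class precision, recall, F1 and macro means
#'
#' From a square confusion-count matrix: `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, F1 their harmonic mean; 0/0 cases are
#' defined as 0 with a warning. Macro means are unweighted over classes
#' with support.
#'
#' @param counts square confusion matrix (rows = truth), e.g.
#'   `confusion(...)$counts`.
#' @return list with `per_class` (data frame: class, precision, recall,
#'   f1, support) and `macro` (named vector).
#' @export
prf1 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  classes <- rownames(counts)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(counts)))
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  zeroed <- FALSE
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0 & num == 0)) zeroed <<- TRUE
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  if (zeroed) warning("0/0 precision or recall defined as 0")
  support <- rowSums(counts)
  sup <- support > 0
  list(per_class = data.frame(class = classes, precision = precision,
                              recall = recall, f1 = f1, support = support,
                              row.names = NULL, stringsAsFactors = FALSE),
       macro = c(precision = mean(precision[sup]),
                 recall = mean(recall[sup]),
                 f1 = mean(f1[sup])))
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps a threshold over the unique scores (predict positive when
#' `score >= threshold`), plots TPR against FPR, and integrates by the
#' trapezoid rule. The result equals the Mann-Whitney U statistic
#' normalized by `n_pos * n_neg`.
#'
#' @param truth binary vector (logical, or 0/1) for the class under
#'   evaluation.
#' @param scores finite numeric scores, higher = more positive.
#' @return list with `fpr`, `tpr` (curve points, chance-anchored at
#'   (0,0) and (1,1)) and `auc`; `auc` is `NA` with a warning when only
#'   one class is present.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(scores), all(is.finite(scores)))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined with a single-class truth; returning NA")
    return(list(fpr = c(0, 1), tpr = c(0, 1), auc = NA_real_))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / n_neg,
                numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Full evaluation report
#'
#' Assembles the evaluation surface for a test split: confusion counts
#' and row-normalized matrix, per-class precision/recall/F1 with macro
#' means, overall and mean per-class accuracy, and per-class one-vs-rest
#' ROC/AUC when a probability matrix is supplied.
#'
#' @param y_true,y_pred label vectors.
#' @param prob optional probability matrix (rows = samples, columns
#'   named by class) for ROC/AUC.
#' @param classes class vocabulary; default sorted union of the truth.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred, prob = NULL,
                              classes = sort(unique(y_true))) {
  cm <- confusion(y_true, y_pred, classes)
  pr <- prf1(cm$counts)
  roc <- NULL
  auc <- setNames(rep(NA_real_, length(classes)), classes)
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    if (is.null(colnames(prob)) || !all(classes %in% colnames(prob)))
      stop("`prob` must have one named column per class")
    roc <- list()
    for (cl in classes) {
      r <- suppressWarnings(roc_auc(y_true == cl, prob[, cl]))
      roc[[cl]] <- r
      auc[cl] <- r$auc
    }
  }
  structure(
    list(classes = classes, counts = cm$counts,
         normalized = cm$normalized, support = cm$support,
         overall_accuracy = cm$overall_accuracy,
         mean_class_accuracy = cm$mean_class_accuracy,
         per_class = pr$per_class, macro = pr$macro,
         auc = auc, macro_auc = mean(auc, na.rm = TRUE), roc = roc),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", length(x$classes), "classes |",
      sum(x$counts), "samples\n")
  print(round(x$normalized, 2))
  cat(sprintf("Mean Accuracy = %.2f%% | Overall = %.2f%% | macro F1 = %.3f\n",
              100 * x$mean_class_accuracy, 100 * x$overall_accuracy,
              x$macro[["f1"]]))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes a machine-readable JSON file and, next to it, a plain-text
#' table with 2-decimal row-normalized confusion entries and a
#' "Mean Accuracy" footer. Output is deterministic for a fixed report.
#'
#' @param report an `evaluation_report`.
#' @param path output path for the JSON file; the text table is written
#'   to the same path with extension `.txt`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    schema_version = 1L,
    classes = report$classes,
    counts = unname(apply(report$counts, 1L, as.integer, simplify = FALSE)),
    normalized = unname(apply(report$normalized, 1L, as.numeric,
                              simplify = FALSE)),
    support = as.integer(report$support),
    overall_accuracy = report$overall_accuracy,
    mean_class_accuracy = report$mean_class_accuracy,
    per_class = report$per_class,
    macro = as.list(report$macro),
    auc = as.list(report$auc),
    macro_auc = report$macro_auc)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- utils::capture.output({
    print(round(report$normalized, 2))
    cat(sprintf("Mean Accuracy = %.2f%%\n",
                100 * report$mean_class_accuracy))
  })
  writeLines(txt, sub("\\.[^.]*$", ".txt", path))
  invisible(path)
}

#' Read back a JSON evaluation report
#' @param path path written by [render_report()].
#' @return the parsed report payload (plain list).
#' @export
parse_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
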