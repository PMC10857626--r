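#' Tree-ensemble importance ranker
#'
#' Returns a ranker function (the default importance oracle for
#' [rank_features()] and [rfe()]): a seeded random forest
#' ([ranger::ranger()]) whose impurity (Gini) importance scores the
#' features. Any function with the same signature — `(features matrix,
#' labels) -> named importance vector` — can substitute, e.g. a
#' linear-coefficient ranker.
#'
#' @param seed RNG seed used for every fit; default 42.
#' @param num_trees number of trees; default 200.
#' @return a ranker function.
#' @export
ranker_forest <- function(seed = 42, num_trees = 200) {
  force(seed); force(num_trees)
  function(x, labels) {
    df <- as.data.frame(x)
    df$.label <- factor(labels)
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = df,
      num.trees = num_trees, importance = "impurity", seed = seed,
      num.threads = 1L, classification = TRUE)
    imp <- fit$variable.importance
    imp[colnames(x)]
  }
}

#' Rank features by model importance
#'
#' Fits the importance oracle on all features and returns a strict
#' ranking (most important first); tied importances are broken by
#' lexicographic feature-name order so the ranking is deterministic.
#'
#' @param table a `feature_table` with >= 2 features and >= 2 classes.
#' @param ranker importance oracle; default [ranker_forest()].
#' @return data frame with columns `feature`, `importance`, `rank`
#'   (1 = most important).
#' @export
rank_features <- function(table, ranker = ranker_forest()) {
  x <- feature_matrix(table)
  if (ncol(x) < 2L) stop("need at least 2 features to rank")
  if (length(unique(table$label)) < 2L)
    stop("need at least 2 classes to rank features")
  imp <- ranker(x, table$label)
  if (is.null(names(imp)) || !setequal(names(imp), colnames(x)))
    stop("ranker must return one named importance per feature")
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = as.numeric(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

# Stratified k-fold accuracy of a seeded random forest on the given
# features; the per-iteration "model performance" recorded by rfe().
cv_accuracy <- function(x, labels, folds = 3, seed = 42) {
  labels <- factor(labels)
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(labels[tr])) < 2L) next
    df <- as.data.frame(x[tr, , drop = FALSE])
    df$.label <- labels[tr]
    fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                          num.trees = 100, seed = seed, num.threads = 1L,
                          classification = TRUE)
    pred <- predict(fit, as.data.frame(x[!tr, , drop = FALSE]))$predictions
    correct <- correct + sum(pred == labels[!tr])
  }
  correct / length(labels)
}

#' Recursive feature elimination
#'
#' Starting from all `M` features, runs exactly `M - k` iterations; each
#' iteration refits the importance oracle on the surviving features,
#' removes the single least-important feature (ties broken by the
#' deterministic rule of [rank_features()]), and records the model
#' performance (stratified cross-validated accuracy) on the surviving
#' set. The loop length is fixed — performance is recorded, not used for
#' early stopping.
#'
#' @param table a `feature_table`.
#' @param k number of features to keep, `1 <= k <= M`.
#' @param ranker importance oracle; default [ranker_forest()].
#' @param cv_folds folds for the performance trace; default 3.
#' @param seed seed for the performance-trace CV splits; default 42.
#' @return object of class `rfe_result` with `selected` (the k
#'   survivors, original column order), `eliminated` (first-removed
#'   first) and `performance` (length `M - k + 1`, starting with the
#'   all-feature model).
#' @export
rfe <- function(table, k, ranker = ranker_forest(), cv_folds = 3,
                seed = 42) {
  fn <- feature_names(table)
  M <- length(fn)
  if (!(k >= 1 && k <= M))
    stop("`k` must satisfy 1 <= k <= ", M, " (number of features)")
  surviving <- fn
  eliminated <- character(0)
  x <- feature_matrix(table)
  perf <- cv_accuracy(x, table$label, folds = cv_folds, seed = seed)
  for (i in seq_len(M - k)) {
    sub <- feature_table(x[, surviving, drop = FALSE], surviving,
                         table$label)
    rk <- rank_features(sub, ranker)
    least <- rk$feature[nrow(rk)]
    surviving <- setdiff(surviving, least)
    eliminated <- c(eliminated, least)
    perf <- c(perf, cv_accuracy(x[, surviving, drop = FALSE],
                                table$label, folds = cv_folds,
                                seed = seed))
  }
  structure(
    list(selected = fn[fn %in% surviving], eliminated = eliminated,
         performance = perf, k = as.integer(k)),
    class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("<rfe_result>", length(x$eliminated), "eliminations ->",
      length(x$selected), "selected features\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' SMOTE minority-class oversampling
#'
#' Generates synthetic minority samples by interpolation: each synthetic
#' point is `x_i + u * (x_nn - x_i)` where `x_i` is a uniformly drawn
#' minority sample, `x_nn` one of its `k_nn` nearest same-class
#' neighbors (Euclidean distance on z-scored features), and
#' `u ~ Uniform(0, 1)`. Original rows are preserved verbatim first;
#' synthetic rows are appended. With targets equal to the current counts
#' the output equals the input. Apply to the training split only.
#'
#' @param table a `feature_table`.
#' @param targets `"balance"` (raise every class to the majority count)
#'   or a named vector of per-class target counts (must be >= current
#'   counts; classes not named keep their count).
#' @param k_nn number of nearest neighbors; default 5. Must be smaller
#'   than every oversampled class.
#' @param seed RNG seed; the output is bit-reproducible given the seed.
#' @return a `feature_table` with per-class counts equal to the targets.
#' @export
smote <- function(table, targets = "balance", k_nn = 5, seed = 1) {
  validate_feature_table(table)
  x <- feature_matrix(table)
  labels <- table$label
  counts <- table(labels)
  if (identical(targets, "balance")) {
    targets <- setNames(rep(max(counts), length(counts)), names(counts))
  } else {
    if (is.null(names(targets))) stop("`targets` must be named by class")
    unknown <- setdiff(names(targets), names(counts))
    if (length(unknown) > 0L)
      stop("target for unknown class(es): ", paste(unknown, collapse = ", "))
    full <- setNames(as.integer(counts), names(counts))
    full[names(targets)] <- pmax(full[names(targets)], 0L)
    if (any(targets < counts[names(targets)]))
      stop("targets must be >= current class counts")
    full[names(targets)] <- as.integer(targets)
    targets <- full
  }
  # z-score for the neighbor metric only; synthesis stays in raw space
  mu <- colMeans(x)
  sg <- apply(x, 2L, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  xz <- sweep(sweep(x, 2L, mu), 2L, sg, `/`)
  set.seed(seed)
  syn_rows <- list()
  syn_labels <- character(0)
  for (cl in sort(names(targets))) {
    n_need <- targets[[cl]] - as.integer(counts[[cl]])
    if (n_need <= 0L) next
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      stop("class `", cl, "` has fewer than 2 samples; cannot oversample")
    if (k_nn >= length(idx))
      stop("k_nn (", k_nn, ") must be smaller than class size (",
           length(idx), ") for class `", cl, "`")
    dmat <- as.matrix(stats::dist(xz[idx, , drop = FALSE]))
    diag(dmat) <- Inf
    nn <- apply(dmat, 1L, function(d) order(d)[seq_len(k_nn)])
    nn <- matrix(nn, nrow = k_nn)                  # k_nn x class size
    pick_i <- sample.int(length(idx), n_need, replace = TRUE)
    pick_j <- sample.int(k_nn, n_need, replace = TRUE)
    u <- runif(n_need)
    base <- x[idx[pick_i], , drop = FALSE]
    nbr <- x[idx[nn[cbind(pick_j, pick_i)]], , drop = FALSE]
    syn_rows[[cl]] <- base + u * (nbr - base)
    syn_labels <- c(syn_labels, rep(cl, n_need))
  }
  if (length(syn_rows) == 0L) return(table)
  out <- rbind(x, do.call(rbind, syn_rows))
  feature_table(out, feature_names(table), c(labels, syn_labels))
}
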