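#' Disease classification from communication genes
#'
#' Trains a gradient-boosted tree classifier on the expression of
#' condition-specific communication genes in a bulk cohort and evaluates
#' it by AUC on a held-out test set.
#'
#' @name ad_prediction
NULL

#' Rank (Mann-Whitney) AUC
#'
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum of
#' the positive-class scores (average ranks for ties). Equals trapezoidal
#' ROC integration; all-tied scores give 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   second level / `TRUE` / `1` is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- if (is.logical(labels)) labels
  else if (is.factor(labels)) labels == levels(labels)[2]
  else labels == max(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stopf("need both classes to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and evaluate a gradient-boosted disease classifier
#'
#' Stratified random split at `train_frac`; an xgboost binary classifier
#' (logistic objective) is fit on the training expression of `genes` and
#' test-set AUC is computed with the rank formulation ([auc_rank()]).
#' Genes absent from the matrix are dropped with a warning; a class absent
#' from train or test after the split is an error (try another seed).
#'
#' @param expr genes x samples matrix.
#' @param labels vector of class labels, one per sample (two classes; the
#'   lexicographically larger one — e.g. `"disease"` vs `"control"` — or
#'   the second factor level is the positive class).
#' @param genes gene list to use as features.
#' @param train_frac training fraction (default 0.75).
#' @param seed split + fit seed.
#' @param nrounds,max_depth,eta xgboost hyperparameters (defaults 200
#'   trees, depth 3, learning rate 0.1).
#' @return Object of class `prediction_report`: list with `auc`, `genes`,
#'   `train_ids`, `test_ids`, `probabilities` (named, test set), `seed`
#'   and the hyperparameters.
#' @export
train_evaluate <- function(expr, labels, genes, train_frac = 0.75,
                           seed = 1L, nrounds = 200, max_depth = 3,
                           eta = 0.1) {
  if (length(labels) != ncol(expr))
    stopf("labels length %d != %d samples", length(labels), ncol(expr))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stopf("need exactly 2 classes, got %d",
                                  length(classes))
  y <- as.integer(as.character(labels) == classes[2])
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    warnf("dropping %d gene(s) absent from the matrix", length(missing))
  genes <- setdiff(genes, missing)
  if (length(genes) == 0) stopf("no requested gene present in the matrix")
  x <- t(expr[genes, , drop = FALSE])

  idx_train <- with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      ids <- which(y == cl)
      sample(ids, round(train_frac * length(ids)))
    }))
  })
  idx_test <- setdiff(seq_along(y), idx_train)
  if (length(unique(y[idx_train])) < 2 || length(unique(y[idx_test])) < 2)
    stopf("a class is absent from train or test; use a different seed")

  booster <- with_seed(seed, xgboost::xgboost(
    x[idx_train, , drop = FALSE],
    factor(y[idx_train], levels = c(0, 1)),
    nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
    nthread = 1, verbosity = 0, seed = seed))
  prob <- predict(booster, x[idx_test, , drop = FALSE])
  structure(list(
    auc = auc_rank(prob, y[idx_test] == 1),
    genes = genes,
    positive_class = classes[2],
    train_ids = colnames(expr)[idx_train],
    test_ids = colnames(expr)[idx_test],
    probabilities = setNames(prob, colnames(expr)[idx_test]),
    seed = seed,
    params = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                  train_frac = train_frac)),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "prediction_report: AUC = %.3f (%d genes, %d train / %d test, positive = %s)\n",
    x$auc, length(x$genes), length(x$train_ids), length(x$test_ids),
    x$positive_class))
  invisible(x)
}

#' Write a prediction report
#'
#' Writes a JSON-style key-value report and a per-sample probability TSV.
#'
#' @param report a `prediction_report`.
#' @param dir output directory.
#' @export
write_prediction_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(auc = report$auc, n_genes = length(report$genes),
         positive_class = report$positive_class, seed = report$seed,
         params = report$params),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write.table(
    data.frame(sample = names(report$probabilities),
               probability = unname(report$probabilities)),
    file.path(dir, "probabilities.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
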