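# Confusion-matrix metrics, ROC/AUC, stratified independent-test and k-fold
# cross-validation protocols, and tabular reports.

#' Confusion counts for binary predictions
#'
#' Positive class is 1.
#'
#' @param labels Observed binary labels (0/1).
#' @param predictions Predicted binary labels (0/1), same length.
#' @return Object of class `nm_confusion`: named integer vector
#'   `c(TP, TN, FP, FN)`.
#' @export
nm_confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop_validation("labels (%d) and predictions (%d) differ in length",
                    length(labels), length(predictions))
  if (length(labels) < 1L) stop_validation("need at least one row")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(c(labels, predictions) %in% c(0L, 1L)))
    stop_validation("labels and predictions must be binary 0/1")
  structure(c(TP = sum(labels == 1L & predictions == 1L),
              TN = sum(labels == 0L & predictions == 0L),
              FP = sum(labels == 0L & predictions == 1L),
              FN = sum(labels == 1L & predictions == 0L)),
            class = "nm_confusion")
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' Standard binary metrics of a confusion matrix:
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Acc = (TP+TN)/(TP+TN+FP+FN)` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`.
#' When any factor of the MCC denominator is zero the MCC is reported as 0
#' (the usual degenerate-case convention).  `Sn` (or `Sp`) is reported as
#' `NA` — undefined, not zero — when no positive (negative) example was
#' evaluated.
#'
#' @param counts An `nm_confusion`, or a named vector with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Object of class `nm_metrics`: named numeric vector
#'   `c(Sn, Sp, Acc, MCC)`.
#' @export
nm_metrics <- function(counts) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts)))
    stop_validation("counts must have elements TP, TN, FP, FN")
  cts <- as.numeric(counts[need])
  if (any(cts < 0)) stop_validation("counts must be non-negative")
  if (sum(cts) == 0) stop_validation("all counts are zero: nothing evaluated")
  TP <- cts[1]; TN <- cts[2]; FP <- cts[3]; FN <- cts[4]
  Sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  Sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  Acc <- (TP + TN) / sum(cts)
  den <- (TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  MCC <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  structure(c(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC), class = "nm_metrics")
}

#' @export
print.nm_metrics <- function(x, ...) {
  cat(sprintf("Sn = %s  Sp = %s  Acc = %.4f  MCC = %.4f\n",
              ifelse(is.na(x["Sn"]), "NA", sprintf("%.4f", x["Sn"])),
              ifelse(is.na(x["Sp"]), "NA", sprintf("%.4f", x["Sp"])),
              x["Acc"], x["MCC"]))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores (ties grouped, contributing
#' trapezoid midpoints) and integrates the curve by the trapezoidal rule;
#' with tied scores handled this way the AUC equals the Mann-Whitney rank
#' statistic.
#'
#' @param labels Observed binary labels; both classes must be present.
#' @param scores Continuous classifier scores (higher = more positive).
#' @return Object of class `nm_roc`: list with `auc` and `curve` (data
#'   frame of `threshold`, `fpr`, `tpr` including the (0,0) and (1,1)
#'   endpoints).
#' @export
nm_roc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop_validation("labels and scores differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_validation("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fp / n0),
                      tpr = c(0, tp / n1))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve), class = "nm_roc")
}

#' @export
print.nm_roc <- function(x, ...) {
  cat(sprintf("<nm_roc> AUC = %.4f (%d curve points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' @method plot nm_roc
#' @export
plot.nm_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Stratified 80:20 split
#'
#' Per class, `round(test_frac * class size)` rows go to the test set and
#' the remainder to training; the partition is deterministic under `seed`,
#' disjoint and exhaustive.
#'
#' @param labels Binary labels (0/1).
#' @param test_frac Test fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
nm_split <- function(labels, test_frac = 0.2, seed = 1L) {
  labels <- as.integer(labels)
  if (length(labels) < 5L) stop_validation("need at least 5 rows to split")
  cls <- table(factor(labels, levels = c(0L, 1L)))
  if (any(cls == 0L)) stop_validation("both classes must be present")
  if (any(cls < 2L)) stop_validation("each class needs at least 2 members")
  set.seed(as.integer(seed))
  test <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(test_frac * length(idx)))
  }))
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

## Stratified fold assignment balanced across folds: within each class,
## whole multiples of k spread evenly and the remainder goes to the folds
## with the fewest rows so far (ties to the lowest fold index).
fold_assignments <- function(labels, k, seed) {
  labels <- as.integer(labels)
  cls <- table(factor(labels, levels = c(0L, 1L)))
  if (k < 2L) stop_validation("k must be at least 2")
  if (any(cls < k)) stop_validation("need at least k rows per class")
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  totals <- integer(k)
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    sizes <- rep(base, k)
    if (extra > 0L) {
      lucky <- order(totals, seq_len(k))[seq_len(extra)]
      sizes[lucky] <- sizes[lucky] + 1L
    }
    fold[idx] <- rep(seq_len(k), sizes)
    totals <- totals + sizes
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into k stratified folds; each fold is tested exactly
#' once by a model trained on the other k - 1.  The standard scaler is
#' refitted inside every training fold (no leakage into the held-out
#' fold).  Fold sizes are balanced to within one row overall.
#'
#' @param x Labeled `nm_windows` or a numeric feature matrix.
#' @param labels Binary labels when `x` is a matrix.
#' @param model,family,params Passed to [nm_fit()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and training.
#' @return Object of class `nm_cv`: list with `folds` (per-fold data frame
#'   of n, Sn, Sp, Acc, MCC, AUC), `mean` (metric means over folds) and
#'   `assignment` (fold index per row).
#' @export
nm_kfold <- function(x, labels = NULL, model = "bagging", family = NULL,
                     params = list(), k = 5L, seed = 1L) {
  if (inherits(x, "nm_windows")) {
    tab <- nm_feature_table(x)
    X <- tab$features; y <- tab$label
  } else {
    X <- as.matrix(x)
    if (is.null(labels)) stop_validation("labels are required with a feature matrix")
    y <- as.integer(labels)
  }
  fold <- fold_assignments(y, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- nm_fit(X[tr, , drop = FALSE], y[tr], model = model,
                  family = family, params = params, seed = seed)
    sc <- predict(fit, X[te, , drop = FALSE], type = "score")
    met <- nm_metrics(nm_confusion(y[te], as.integer(sc >= 0.5)))
    auc <- if (length(unique(y[te])) == 2L) nm_roc(y[te], sc)$auc else NA_real_
    data.frame(fold = f, n = length(te), Sn = met["Sn"], Sp = met["Sp"],
               Acc = met["Acc"], MCC = met["MCC"], AUC = auc,
               row.names = NULL)
  })
  folds <- do.call(rbind, rows)
  structure(list(
    model = model, k = k, seed = as.integer(seed), folds = folds,
    mean = colMeans(folds[, c("Sn", "Sp", "Acc", "MCC", "AUC")], na.rm = TRUE),
    assignment = fold
  ), class = "nm_cv")
}

#' @export
print.nm_cv <- function(x, ...) {
  cat(sprintf("<nm_cv> %d-fold cross-validation of '%s' (seed %d)\n",
              x$k, x$model, x$seed))
  print(x$folds, digits = 3)
  cat("mean:", paste(sprintf("%s=%.3f", names(x$mean), x$mean),
                     collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate models under the study protocols
#'
#' Runs one or more registered classifiers on a labeled dataset under the
#' independent-test protocol (stratified 80:20 split; scaler and model see
#' the training partition only) or stratified 5-fold cross-validation, and
#' collects Sn, Sp, Acc, MCC and AUC per (dataset, model).
#'
#' @param x Labeled `nm_windows` or a numeric feature matrix.
#' @param labels Binary labels when `x` is a matrix.
#' @param models Character vector of model names (see [nm_models()]);
#'   `"ensemble"` expands to the eight ensemble models, `"conventional"`
#'   to the five baselines, `"all"` to the full registry.
#' @param protocol `"independent"` (default) or `"kfold"`.
#' @param k Folds for the k-fold protocol (default 5).
#' @param test_frac Test fraction for the independent protocol.
#' @param seed Integer seed.
#' @param dataset Dataset tag recorded in the report (e.g. `"A2OM"`);
#'   defaults to the windows' centre base plus `"2OM"` when available.
#' @return Object of class `nm_eval`: data frame with columns `dataset`,
#'   `model`, `family`, `protocol`, `n_eval`, `Sn`, `Sp`, `Acc`, `MCC`,
#'   `AUC`.
#' @export
nm_evaluate <- function(x, labels = NULL, models = "bagging",
                        protocol = c("independent", "kfold"), k = 5L,
                        test_frac = 0.2, seed = 1L, dataset = NULL) {
  protocol <- match.arg(protocol)
  reg <- nm_models()
  if (identical(models, "all")) {
    sel <- reg
  } else if (identical(models, "ensemble")) {
    sel <- reg[reg$family %in% c("bagging", "boosting"), ]
  } else if (identical(models, "conventional")) {
    sel <- reg[reg$family == "conventional", ]
  } else {
    sel <- do.call(rbind, lapply(models, resolve_spec))
  }
  if (inherits(x, "nm_windows")) {
    if (is.null(dataset)) {
      cb <- unique(x$center)
      dataset <- if (length(cb) == 1L) paste0(cb, "2OM") else "mixed"
    }
    tab <- nm_feature_table(x)
    X <- tab$features; y <- tab$label
  } else {
    X <- as.matrix(x)
    if (is.null(labels)) stop_validation("labels are required with a feature matrix")
    y <- as.integer(labels)
    if (is.null(dataset)) dataset <- "dataset"
  }
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    name <- sel$name[i]; fam <- sel$family[i]
    if (protocol == "independent") {
      sp <- nm_split(y, test_frac = test_frac, seed = seed)
      fit <- nm_fit(X[sp$train, , drop = FALSE], y[sp$train], model = name,
                    family = fam, seed = seed)
      sc <- predict(fit, X[sp$test, , drop = FALSE], type = "score")
      met <- nm_metrics(nm_confusion(y[sp$test], as.integer(sc >= 0.5)))
      auc <- nm_roc(y[sp$test], sc)$auc
      data.frame(dataset = dataset, model = name, family = fam,
                 protocol = "independent_80_20", n_eval = length(sp$test),
                 Sn = met[["Sn"]], Sp = met[["Sp"]], Acc = met[["Acc"]],
                 MCC = met[["MCC"]], AUC = auc)
    } else {
      cv <- nm_kfold(X, y, model = name, family = fam, k = k, seed = seed)
      data.frame(dataset = dataset, model = name, family = fam,
                 protocol = sprintf("kfold_%d", k), n_eval = length(y),
                 Sn = cv$mean[["Sn"]], Sp = cv$mean[["Sp"]],
                 Acc = cv$mean[["Acc"]], MCC = cv$mean[["MCC"]],
                 AUC = cv$mean[["AUC"]])
    }
  })
  structure(do.call(rbind, rows), class = c("nm_eval", "data.frame"))
}

#' Write an evaluation report
#'
#' Renders the metric columns at two decimals (the conventional display
#' precision for these benchmarks) alongside full-precision columns, and
#' writes TSV or CSV.
#'
#' @param x An `nm_eval` data frame from [nm_evaluate()].
#' @param path Output file; `NULL` returns the rendered table only.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return The rendered data frame, invisibly when written to `path`.
#' @export
nm_report <- function(x, path = NULL, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!inherits(x, "data.frame") || nrow(x) == 0L)
    stop_validation("empty evaluation: nothing to report")
  if (!("protocol" %in% names(x)) || any(!nzchar(x$protocol)))
    stop_validation("every row needs a protocol tag")
  out <- x
  for (cl in intersect(c("Sn", "Sp", "Acc", "MCC", "AUC"), names(x))) {
    out[[paste0(cl, "_full")]] <- x[[cl]]
    out[[cl]] <- ifelse(is.na(x[[cl]]), NA, sprintf("%.2f", x[[cl]]))
  }
  if (is.null(path)) return(out)
  sep <- if (format == "tsv") "\t" else ","
  ok <- try(utils::write.table(out, path, sep = sep, row.names = FALSE,
                               quote = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop_io("cannot write report to '%s'", path)
  invisible(out)
}
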