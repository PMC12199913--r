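# Classifier registry, training, prediction and persistence.
#
# The registry mirrors the study design: eight ensemble classifiers (four
# bagging-family, four boosting-family) plus five conventional baselines
# used for cross-comparison.  Every backend is wrapped behind a uniform
# fit/score interface so that training is reproducible from (data, model
# name, hyperparameters, seed) alone.

MODEL_SERIALIZATION_VERSION <- 1L

#' Registry of available classifiers
#'
#' Eight ensemble models — bagging family: random forest, extra trees,
#' decision tree, bagged trees; boosting family: gradient boosting,
#' histogram-based gradient boosting, AdaBoost, XGBoost — and five
#' conventional baselines (random forest, SVM, k-nearest neighbour, a
#' single-hidden-layer neural network, decision tree).  Names repeat across
#' families where the study uses the same algorithm in both roles; the
#' (name, family) pair is unique.
#'
#' @return Data frame with columns `name`, `family` and `seed` (default
#'   training seed), in a fixed order.
#' @export
nm_models <- function() {
  data.frame(
    name = c("random_forest", "extra_trees", "decision_tree", "bagging",
             "gradient_boost", "hist_gradient_boost", "adaboost", "xgboost",
             "random_forest", "svm", "knn", "ann", "decision_tree"),
    family = rep(c("bagging", "boosting", "conventional"), c(4L, 4L, 5L)),
    seed = 1L,
    stringsAsFactors = FALSE
  )
}

#' Default hyperparameters of a registered model
#'
#' @param name Model name from [nm_models()].
#' @return Named list of hyperparameters (possibly empty).
#' @export
nm_default_params <- function(name) {
  switch(name,
    random_forest       = list(ntree = 500L, mtry = NULL),  # mtry: floor(sqrt(p))
    extra_trees         = list(num.trees = 500L, num.random.splits = 1L),
    decision_tree       = list(cp = 0.01, minsplit = 20L),
    bagging             = list(ntree = 100L),                # mtry fixed at p
    gradient_boost      = list(nrounds = 100L, eta = 0.1, max_depth = 3L),
    hist_gradient_boost = list(nrounds = 100L, eta = 0.1, max_leaves = 31L),
    adaboost            = list(n_rounds = 50L, learning_rate = 1),
    xgboost             = list(nrounds = 100L, eta = 0.3, max_depth = 6L),
    svm                 = list(kernel = "radial", cost = 1),
    knn                 = list(k = 5L),
    ann                 = list(size = 8L, decay = 0, maxit = 100L),
    stop_validation("unknown model '%s'", name)
  )
}

resolve_spec <- function(model, family = NULL) {
  reg <- nm_models()
  hit <- if (is.null(family)) reg[reg$name == model, , drop = FALSE]
         else reg[reg$name == model & reg$family == family, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop_validation("unknown model '%s'%s", model,
                    if (is.null(family)) "" else paste0(" in family '", family, "'"))
  hit[1L, , drop = FALSE]   # name clashes resolve to the ensemble entry
}

#' Train a classifier on encoded windows
#'
#' The central fitting function.  Input windows are encoded to the
#' 522-dimensional feature space (unless a feature matrix is supplied
#' directly), a standard scaler is fitted on these training rows only, and
#' the requested classifier is trained on the scaled features.  Everything
#' needed for prediction — model name, hyperparameters, seed, scaler and
#' fitted state — is stored in the returned object, so results are
#' reproducible from the object alone and no scaler or model state can
#' leak across a train/test boundary.
#'
#' @param x Labeled `nm_windows` (label column used), or a numeric feature
#'   matrix (then `labels` is required).
#' @param labels Binary labels (0/1), one per row of `x`; ignored when `x`
#'   is a labeled `nm_windows`.
#' @param model Model name from [nm_models()] (default `"bagging"`, the
#'   study's best performer).
#' @param family Optional family to disambiguate names that appear in both
#'   the ensemble and conventional groups; defaults to the ensemble entry.
#' @param params Named list of hyperparameter overrides, merged over
#'   [nm_default_params()].
#' @param seed Integer seed controlling every stochastic element of
#'   training; equal seeds give identical predictions.
#' @param scale Fit and apply a standard scaler (default `TRUE`).
#' @return An object of class `nm_fit`.
#' @seealso [predict.nm_fit()], [nm_save_model()], [nm_evaluate()]
#' @examples
#' w <- nm_simulate(center_base = "A", n_pos = 30, n_neg = 30, seed = 1)
#' fit <- nm_fit(w, model = "decision_tree", seed = 1)
#' predict(fit, w)[1:3, ]
#' @export
nm_fit <- function(x, labels = NULL, model = "bagging", family = NULL,
                   params = list(), seed = 1L, scale = TRUE) {
  spec <- resolve_spec(model, family)
  if (inherits(x, "nm_windows")) {
    tab <- nm_feature_table(x)
    X <- tab$features; y <- tab$label
    center <- unique(x$center)
  } else {
    X <- as.matrix(x)
    if (is.null(labels)) stop_validation("labels are required with a feature matrix")
    y <- as.integer(labels)
    center <- NULL
  }
  if (length(y) != nrow(X)) stop_validation("labels must match rows")
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop_validation("labels must be binary 0/1")
  tab_y <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab_y == 0L))
    stop_validation("training data contain a single class; need both 0 and 1")
  if (any(tab_y < 2L)) stop_validation("need at least 2 rows per class")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  prm <- utils::modifyList(nm_default_params(spec$name), params)
  scaler <- if (scale) nm_fit_scaler(X) else NULL
  Xs <- if (scale) nm_apply_scaler(X, scaler) else X
  fit <- fit_backend(spec$name, Xs, y, prm, as.integer(seed))
  structure(list(
    model = spec$name, family = spec$family, params = prm,
    seed = as.integer(seed), scaler = scaler, feature_names = colnames(X),
    center_base = if (!is.null(center) && length(center) == 1L) center else NA_character_,
    n_train = nrow(X), class_counts = as.integer(tab_y), backend = fit
  ), class = "nm_fit")
}

fit_backend <- function(name, X, y, prm, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  p <- ncol(X)
  set.seed(seed)
  switch(name,
    random_forest = list(
      kind = "randomForest",
      fit = randomForest::randomForest(
        x = X, y = yf, ntree = prm$ntree,
        mtry = prm$mtry %||% max(1L, floor(sqrt(p))))),
    bagging = list(
      kind = "randomForest",
      fit = randomForest::randomForest(x = X, y = yf, ntree = prm$ntree,
                                       mtry = p)),
    extra_trees = {
      df <- data.frame(X, check.names = FALSE); df$.y <- yf
      list(kind = "ranger",
           fit = ranger::ranger(dependent.variable.name = ".y", data = df,
                                probability = TRUE, splitrule = "extratrees",
                                num.random.splits = prm$num.random.splits,
                                num.trees = prm$num.trees, replace = FALSE,
                                sample.fraction = 1, seed = seed,
                                num.threads = 1L))
    },
    decision_tree = {
      df <- data.frame(.y = yf, X, check.names = FALSE)
      list(kind = "rpart",
           fit = rpart::rpart(.y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                cp = prm$cp, minsplit = prm$minsplit,
                                xval = 0L)))
    },
    gradient_boost = xgb_backend(X, y, seed, list(
      objective = "binary:logistic", eta = prm$eta, max_depth = prm$max_depth,
      tree_method = "exact", nthread = 1L), prm$nrounds),
    hist_gradient_boost = xgb_backend(X, y, seed, list(
      objective = "binary:logistic", eta = prm$eta, max_depth = 0L,
      max_leaves = prm$max_leaves, grow_policy = "lossguide",
      tree_method = "hist", nthread = 1L), prm$nrounds),
    xgboost = xgb_backend(X, y, seed, list(
      objective = "binary:logistic", eta = prm$eta, max_depth = prm$max_depth,
      nthread = 1L), prm$nrounds),
    adaboost = list(kind = "adaboost",
                    fit = ada_fit(X, y, prm$n_rounds, prm$learning_rate)),
    svm = list(kind = "svm",
               fit = e1071::svm(X, yf, kernel = prm$kernel, cost = prm$cost,
                                probability = TRUE)),
    knn = list(kind = "knn", X = X, y = yf, k = prm$k),
    ann = list(kind = "nnet",
               fit = nnet::nnet(X, y, size = prm$size, decay = prm$decay,
                                maxit = prm$maxit, entropy = TRUE,
                                MaxNWts = 100000L, trace = FALSE)),
    stop_validation("unknown model '%s'", name)
  )
}

xgb_backend <- function(X, y, seed, params, nrounds) {
  params$seed <- seed
  d <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                            verbose = 0)
  list(kind = "xgboost", raw = xgboost::xgb.save.raw(bst), params = params,
       nrounds = nrounds)
}

score_backend <- function(object, X) {
  b <- object$backend
  switch(b$kind,
    randomForest = unname(predict(b$fit, X, type = "prob")[, "1"]),
    ranger = unname(predict(b$fit, data = data.frame(X, check.names = FALSE),
                            num.threads = 1L)$predictions[, "1"]),
    rpart = unname(predict(b$fit, as.data.frame(X, check.names = FALSE),
                           type = "prob")[, "1"]),
    xgboost = {
      bst <- xgboost::xgb.load.raw(b$raw)
      unname(predict(bst, xgboost::xgb.DMatrix(X)))
    },
    adaboost = ada_score(b$fit, X),
    svm = {
      pr <- attr(predict(b$fit, X, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    knn = {
      pred <- class::knn(b$X, X, b$y, k = b$k, prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    },
    nnet = as.numeric(predict(b$fit, X)),
    stop_validation("unknown backend '%s'", b$kind)
  )
}

#' Predict Nm-site scores for new windows
#'
#' Applies the stored scaler and fitted classifier.  Scores lie in
#' \[0, 1\]; the hard call is `score >= 0.5`.  A feature matrix must carry
#' exactly the training feature names (any mismatch is an error rather
#' than a silent reorder).
#'
#' @param object An `nm_fit`.
#' @param newdata `nm_windows`, a character vector of 41-nt sequences, or
#'   a numeric feature matrix with matching columns.
#' @param type `"both"` (default; data frame of score and class),
#'   `"score"` or `"class"`.
#' @param ... Unused.
#' @return Data frame with columns `score` and `class`, or the requested
#'   vector.
#' @export
predict.nm_fit <- function(object, newdata, type = c("both", "score", "class"),
                           ...) {
  type <- match.arg(type)
  if (inherits(newdata, "nm_windows") || is.character(newdata)) {
    X <- nm_features(newdata)
  } else {
    X <- as.matrix(newdata)
    if (is.null(colnames(X)) || !identical(colnames(X), object$feature_names))
      stop_validation("feature columns do not match the trained model")
  }
  if (!is.null(object$scaler)) X <- nm_apply_scaler(X, object$scaler)
  score <- pmin(1, pmax(0, score_backend(object, X)))
  cls <- as.integer(score >= 0.5)
  switch(type,
    both = data.frame(id = rownames(X) %||% as.character(seq_along(score)),
                      score = score, class = cls),
    score = score,
    class = cls)
}

#' @export
print.nm_fit <- function(x, ...) {
  cat(sprintf("<nm_fit> %s (%s family)\n", x$model, x$family))
  cat(sprintf("  trained on %d windows (neg %d / pos %d), %d features, seed %d\n",
              x$n_train, x$class_counts[1], x$class_counts[2],
              length(x$feature_names), x$seed))
  if (!is.na(x$center_base))
    cat(sprintf("  centre base: %s\n", x$center_base))
  invisible(x)
}

#' @method summary nm_fit
#' @export
summary.nm_fit <- function(object, ...) {
  print(object)
  cat("  hyperparameters:\n")
  for (nm in names(object$params)) {
    val <- object$params[[nm]]
    cat(sprintf("    %s = %s\n", nm,
                if (is.null(val)) "<auto>" else paste(val, collapse = ", ")))
  }
  if (!is.null(object$scaler))
    cat(sprintf("  scaler fitted on %d rows\n", object$scaler$fitted_on))
  invisible(object)
}

#' Save a trained model to disk
#'
#' Serializes the full `nm_fit` object (model name, hyperparameters, seed,
#' scaler, feature names and fitted state) together with a format-version
#' tag; [nm_load_model()] refuses files written under a different version
#' rather than misreading them.
#'
#' @param object An `nm_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
nm_save_model <- function(object, path) {
  stopifnot(inherits(object, "nm_fit"))
  payload <- list(format = "nmpred_model",
                  version = MODEL_SERIALIZATION_VERSION,
                  object = object)
  ok <- try(saveRDS(payload, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop_io("cannot write model to '%s'", path)
  invisible(path)
}

#' Load a trained model from disk
#'
#' @param path File written by [nm_save_model()].
#' @return The stored `nm_fit`.
#' @export
nm_load_model <- function(path) {
  if (!file.exists(path)) stop_io("cannot read model '%s': no such file", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_io("cannot read model '%s': %s",
                                                  path, conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "nmpred_model"))
    stop_validation("'%s' is not an nmpred model file", path)
  if (!identical(payload$version, MODEL_SERIALIZATION_VERSION))
    stop_validation("model file version %s does not match supported version %d",
                    deparse(payload$version), MODEL_SERIALIZATION_VERSION)
  payload$object
}
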