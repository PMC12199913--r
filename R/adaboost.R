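# AdaBoost (discrete SAMME) over depth-1 decision stumps.
#
# Binary SAMME with rpart stumps as weak learners: at each round a stump is
# fitted under the current case weights, its weighted error e_m determines
# the stage weight alpha_m = lr * log((1 - e_m)/e_m), and the weights of
# misclassified cases are multiplied by exp(alpha_m).  The final score is
# the alpha-weighted fraction of stumps voting for the positive class, so
# it lies in [0, 1] and 0.5 is the usual decision threshold.

ada_fit <- function(X, y, n_rounds = 50L, learning_rate = 1) {
  y <- as.integer(y)                # 0/1
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), X, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = 1L, cp = 0, minsplit = 2L,
                               xval = 0L, maxcompete = 0L, maxsurrogate = 0L)
  stumps <- list(); alphas <- numeric(0)
  eps <- 1e-10
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5 && m > 1L) break   # no better than chance: stop boosting
    err <- min(max(err, eps), 1 - eps)
    alpha <- learning_rate * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err <= eps) break             # perfect stump: ensemble is done
  }
  list(stumps = stumps, alphas = alphas)
}

ada_score <- function(model, X) {
  df <- as.data.frame(X, check.names = FALSE)
  votes <- vapply(model$stumps, function(fit)
    as.integer(as.character(predict(fit, df, type = "class"))), integer(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  drop(votes %*% model$alphas) / sum(model$alphas)
}
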