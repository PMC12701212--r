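# The classifier families evaluated for ROI classification, behind one
# train/score interface. All families expose a positive-class probability so
# both soft and hard voting are possible. Positive class = "future_malignant"
# (or the second factor level for generic labels).

CLASSIFIER_FAMILIES <- c("random_forest", "gradient_boosting", "mlp", "knn",
                         "adaboost", "svm", "naive_bayes", "ann", "lda",
                         "qda", "extra_trees", "ensemble_voting")

#' Classifier specification
#'
#' @param family one of `random_forest`, `gradient_boosting`, `mlp`, `knn`,
#'   `adaboost`, `svm`, `naive_bayes`, `ann`, `lda`, `qda`, `extra_trees`,
#'   `ensemble_voting`.
#' @param hyperparams named list; family-specific entries with conventional
#'   defaults (e.g. `k` for knn in {1,3,5,7,9,11}; `kernel` in
#'   {linear, polynomial, rbf} and `degree`, `cost` for svm; `num_trees`;
#'   `hidden` units and the published optimizer settings for `ann`).
#' @param seed RNG seed for stochastic families.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(family, hyperparams = list(), seed = 0L) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  hp <- hyperparams
  if (family == "knn") {
    hp$k <- hp$k %||% 9L
    if (!hp$k %in% c(1L, 3L, 5L, 7L, 9L, 11L))
      stop("knn k must be one of 1, 3, 5, 7, 9, 11")
  }
  if (family == "svm") {
    hp$kernel <- hp$kernel %||% "polynomial"
    if (!hp$kernel %in% c("linear", "polynomial", "rbf"))
      stop("svm kernel must be linear, polynomial or rbf")
    hp$degree <- hp$degree %||% 3L
    hp$cost <- hp$cost %||% 1
  }
  if (family %in% c("random_forest", "extra_trees"))
    hp$num_trees <- hp$num_trees %||% 100L
  if (family == "gradient_boosting") {
    hp$nrounds <- hp$nrounds %||% 100L
    hp$max_depth <- hp$max_depth %||% 3L
    hp$eta <- hp$eta %||% 0.3
  }
  if (family == "adaboost") hp$n_rounds <- hp$n_rounds %||% 50L
  if (family == "mlp") {
    hp$hidden <- hp$hidden %||% 32L
    hp$maxit <- hp$maxit %||% 200L
    hp$decay <- hp$decay %||% 1e-4
  }
  if (family == "ann") {
    hp$hidden <- hp$hidden %||% 32L
    hp$batch_size <- hp$batch_size %||% 128L
    hp$learning_rate <- hp$learning_rate %||% 1e-4
    hp$epochs <- hp$epochs %||% 100L
  }
  structure(list(family = family, hyperparams = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Soft/hard voting ensemble specification
#'
#' The default membership mirrors the best leave-one-patient-out scheme of
#' the study: LDA, k-NN (k = 9), polynomial-kernel SVM, naive Bayes and
#' extra trees under soft voting.
#'
#' @param members list of at least two `classifier_spec`s.
#' @param voting "soft" (mean member probability, threshold 0.5) or "hard"
#'   (majority of member labels, ties broken toward the positive class).
#' @param seed RNG seed forwarded to members without one.
#' @return list of class `ensemble_spec` (also a `classifier_spec`).
#' @export
ensemble_spec <- function(members = NULL, voting = c("soft", "hard"), seed = 0L) {
  voting <- match.arg(voting)
  if (is.null(members))
    members <- list(
      classifier_spec("lda", seed = seed),
      classifier_spec("knn", list(k = 9L), seed = seed),
      classifier_spec("svm", list(kernel = "polynomial"), seed = seed),
      classifier_spec("naive_bayes", seed = seed),
      classifier_spec("extra_trees", seed = seed))
  if (length(members) < 2) stop("ensemble needs at least two members")
  structure(list(family = "ensemble_voting", members = members,
                 voting = voting, hyperparams = list(), seed = as.integer(seed)),
            class = c("ensemble_spec", "classifier_spec"))
}

# ---- small in-package learners -------------------------------------------

# Single-hidden-layer network: ReLU hidden units, softmax output, trained by
# mini-batch Adam with the published settings (batch 128, lr 1e-4,
# 100 epochs).
ann_fit <- function(X, y01, hidden, batch_size, lr, epochs, seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * 2, sd = sqrt(2 / hidden)), hidden, 2)
  b2 <- numeric(2)
  Y <- cbind(1 - y01, y01)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1, n)]
      xb <- X[bi, , drop = FALSE]; yb <- Y[bi, , drop = FALSE]
      h_pre <- sweep(xb %*% params$W1, 2, params$b1, "+")
      h <- pmax(h_pre, 0)
      o <- sweep(h %*% params$W2, 2, params$b2, "+")
      o <- o - apply(o, 1, max)
      eo <- exp(o); prob <- eo / rowSums(eo)
      d_o <- (prob - yb) / nrow(xb)
      grads <- list(
        W1 = t(xb) %*% ((d_o %*% t(params$W2)) * (h_pre > 0)),
        b1 = colSums((d_o %*% t(params$W2)) * (h_pre > 0)),
        W2 = t(h) %*% d_o,
        b2 = colSums(d_o))
      t <- t + 1
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mh <- m[[nm]] / (1 - beta1^t)
        vh <- v[[nm]] / (1 - beta2^t)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  params
}

ann_prob <- function(params, X) {
  h <- pmax(sweep(X %*% params$W1, 2, params$b1, "+"), 0)
  o <- sweep(h %*% params$W2, 2, params$b2, "+")
  o <- o - apply(o, 1, max)
  eo <- exp(o)
  (eo / rowSums(eo))[, 2]
}

# AdaBoost (SAMME) with depth-1 rpart stumps.
adaboost_fit <- function(X, y01, n_rounds, seed) {
  set.seed(seed)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  yf <- factor(y01, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (b in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = yf), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != yf)) / sum(w)
    if (err >= 0.5 || err <= 1e-12) {
      if (err <= 1e-12) { stumps[[b]] <- fit; alphas[b] <- 10 }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[b]] <- fit; alphas[b] <- alpha
    w <- w * exp(alpha * ifelse(pred != yf, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, names = names(df))
}

adaboost_prob <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- model$names
  if (length(model$stumps) == 0) return(rep(0.5, nrow(df)))
  margin <- rep(0, nrow(df))
  for (b in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[b]], df, type = "class")
    margin <- margin + model$alphas[b] * ifelse(pred == "1", 1, -1)
  }
  1 / (1 + exp(-2 * margin / max(sum(model$alphas), 1e-12)))
}

# k-NN with the nearest-neighbour tie-break: when the vote among the k
# nearest is tied, the label of the single nearest neighbour decides.
knn_predict <- function(Xtr, ytr01, Xte, k) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  prob <- numeric(nrow(Xte)); lab <- integer(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    nb <- order(d2[i, ])[seq_len(k)]
    votes <- ytr01[nb]
    prob[i] <- mean(votes)
    lab[i] <- if (sum(votes) * 2 == k) votes[1] else as.integer(sum(votes) * 2 > k)
  }
  list(prob = prob, label = lab)
}

# ---- unified train / score interface -------------------------------------

#' Train a classifier
#'
#' Fits the family named in `spec` on standardized training features (the
#' caller standardizes per training fold) and returns a model whose
#' [predict_scores()] method yields positive-class probabilities.
#' Stochastic families are seeded from `spec$seed`, so refits are identical.
#'
#' @param spec a [classifier_spec()] or [ensemble_spec()].
#' @param X numeric matrix of training features.
#' @param y labels; the positive class is `"future_malignant"` when present,
#'   otherwise the second factor level.
#' @return object of class `mammodelta_model`.
#' @export
train_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("single-class training fold")
  pos <- if ("future_malignant" %in% levels(y)) "future_malignant" else levels(y)[2]
  y01 <- as.integer(y == pos)
  hp <- spec$hyperparams
  set.seed(spec$seed)
  fit <- switch(spec$family,
    lda = MASS::lda(X, grouping = y01),
    qda = {
      # tiny deterministic jitter keeps the class covariances nonsingular
      # when a feature is constant within one class
      Xj <- X + matrix(stats::rnorm(length(X), sd = 1e-7), nrow(X))
      MASS::qda(Xj, grouping = y01)
    },
    naive_bayes = e1071::naiveBayes(X, factor(y01)),
    svm = {
      # decision-value SVM with our own Platt calibration: one libsvm fit
      # instead of the five extra internal fits probability=TRUE would run
      fit <- e1071::svm(X, factor(y01), kernel = if (hp$kernel == "rbf")
        "radial" else hp$kernel, degree = hp$degree %||% 3,
        cost = hp$cost %||% 1)
      dv <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                            "decision.values"))
      # decision values are oriented toward the first class seen in training
      sgn <- if (colnames(attr(stats::predict(fit, X[1, , drop = FALSE],
                                              decision.values = TRUE),
                               "decision.values")) == "0/1") -1 else 1
      cal <- suppressWarnings(stats::glm.fit(cbind(1, sgn * dv), y01,
                                             family = stats::binomial()))
      list(svm = fit, platt = cal$coefficients, sign = sgn)
    },
    random_forest = ranger::ranger(x = as.data.frame(X), y = factor(y01),
                                   num.trees = hp$num_trees, probability = TRUE,
                                   num.threads = 1, seed = spec$seed),
    extra_trees = ranger::ranger(x = as.data.frame(X), y = factor(y01),
                                 num.trees = hp$num_trees, probability = TRUE,
                                 splitrule = "extratrees", num.threads = 1,
                                 seed = spec$seed),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(X, label = y01),
      nrounds = hp$nrounds, verbose = 0),
    mlp = nnet::nnet(X, y01, size = hp$hidden, decay = hp$decay,
                     maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                     MaxNWts = 100000),
    ann = ann_fit(X, y01, hp$hidden, hp$batch_size, hp$learning_rate,
                  hp$epochs, spec$seed),
    adaboost = adaboost_fit(X, y01, hp$n_rounds, spec$seed),
    knn = list(Xtr = X, ytr01 = y01, k = hp$k),
    ensemble_voting = lapply(spec$members, function(m) train_classifier(m, X, y))
  )
  structure(list(spec = spec, fit = fit, positive = pos, levels = levels(y)),
            class = "mammodelta_model")
}

#' Positive-class scores of a fitted model
#'
#' @param model a `mammodelta_model` from [train_classifier()].
#' @param X feature matrix (same standardization as training).
#' @return numeric vector of probabilities of the positive class.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  hp <- model$spec$hyperparams
  switch(model$spec$family,
    lda = stats::predict(model$fit, X)$posterior[, "1"],
    qda = stats::predict(model$fit, X)$posterior[, "1"],
    naive_bayes = stats::predict(model$fit, X, type = "raw")[, "1"],
    svm = {
      dv <- as.numeric(attr(stats::predict(model$fit$svm, X,
                                           decision.values = TRUE),
                            "decision.values"))
      eta <- model$fit$platt[1] + model$fit$platt[2] * model$fit$sign * dv
      1 / (1 + exp(-eta))
    },
    random_forest = stats::predict(model$fit, data = as.data.frame(X),
                                   num.threads = 1)$predictions[, "1"],
    extra_trees = stats::predict(model$fit, data = as.data.frame(X),
                                 num.threads = 1)$predictions[, "1"],
    gradient_boosting = stats::predict(model$fit, xgboost::xgb.DMatrix(X)),
    mlp = as.numeric(stats::predict(model$fit, X)),
    ann = ann_prob(model$fit, X),
    adaboost = adaboost_prob(model$fit, X),
    knn = knn_predict(model$fit$Xtr, model$fit$ytr01, X, model$fit$k)$prob,
    ensemble_voting = {
      probs <- vapply(model$fit, function(m) predict_scores(m, X),
                      numeric(nrow(X)))
      if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1)
      rowMeans(probs)
    })
}

#' Ensemble prediction (scores and labels)
#'
#' Soft voting averages the member probabilities and thresholds at 0.5;
#' hard voting takes the majority of member labels with ties broken toward
#' the positive class (sensitivity first).
#'
#' @param model a fitted `mammodelta_model` with family `ensemble_voting`.
#' @param X feature matrix.
#' @return list with `scores` and integer `labels` (1 = positive).
#' @export
ensemble_predict <- function(model, X) {
  stopifnot(model$spec$family == "ensemble_voting")
  X <- as.matrix(X)
  probs <- vapply(model$fit, function(m) predict_scores(m, X), numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1)
  scores <- rowMeans(probs)
  if (model$spec$voting == "soft") {
    labels <- as.integer(scores >= 0.5)
  } else {
    votes <- rowSums(probs >= 0.5)
    labels <- as.integer(votes * 2 >= length(model$fit))  # tie -> positive
  }
  list(scores = scores, labels = labels)
}

#' Predicted labels of any fitted model
#' @param model a `mammodelta_model`.
#' @param X feature matrix.
#' @param threshold probability cut-off for non-ensemble families.
#' @return integer vector (1 = positive class).
#' @export
predict_labels <- function(model, X, threshold = 0.5) {
  if (model$spec$family == "ensemble_voting")
    return(ensemble_predict(model, X)$labels)
  if (model$spec$family == "knn") {
    res <- knn_predict(model$fit$Xtr, model$fit$ytr01, as.matrix(X), model$fit$k)
    return(res$label)
  }
  as.integer(predict_scores(model, X) >= threshold)
}
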