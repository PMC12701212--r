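# Feature ranking with eight techniques and the majority-rule merge of
# their top lists into the final subset.

RANKERS <- c("t_test", "mrmr", "importance_extra_trees",
             "importance_random_forest", "importance_gradient_boosting",
             "univariate_k_best", "sequential_forward", "sequential_backward")

new_ranked_list <- function(ranker, selected, scores = NULL) {
  if (anyDuplicated(selected)) stop("ranked list contains duplicates")
  structure(list(ranker = ranker, selected = selected, scores = scores),
            class = "ranked_feature_list")
}

#' @export
print.ranked_feature_list <- function(x, ...) {
  cat(sprintf("<ranked_feature_list %s: %d features; top: %s>\n",
              x$ranker, length(x$selected),
              paste(utils::head(x$selected, 3), collapse = ", ")))
  invisible(x)
}

welch_t <- function(x, y01) {
  a <- x[y01 == 1]; b <- x[y01 == 0]
  va <- stats::var(a); vb <- stats::var(b)
  den <- sqrt(va / length(a) + vb / length(b))
  if (!is.finite(den) || den == 0) return(0)
  abs(mean(a) - mean(b)) / den
}

anova_f <- function(x, y01) {
  # one-way ANOVA F score (the classic univariate filter)
  mu <- mean(x)
  groups <- split(x, y01)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - mu)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(x) - length(groups)
  if (ssw <= 0 || dfw <= 0) return(0)
  (ssb / dfb) / (ssw / dfw)
}

discretize_mi <- function(x, bins = 8L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

mutual_info <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

mrmr_rank <- function(X, y01, k) {
  d <- lapply(seq_len(ncol(X)), function(j) discretize_mi(X[, j]))
  rel <- vapply(d, function(dj) mutual_info(dj, y01), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(ncol(X))
  red_sum <- numeric(ncol(X))
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0) rel[remaining]
    else rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    for (j in remaining) red_sum[j] <- red_sum[j] + mutual_info(d[[j]], d[[pick]])
  }
  selected
}

lda_cv_accuracy <- function(X, y, folds = 5L, seed = 1L) {
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  correct <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- tryCatch(MASS::lda(X[tr, , drop = FALSE], grouping = y[tr]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])$class
    correct <- correct + sum(pred == y[!tr])
  }
  correct / n
}

sequential_select <- function(X, y, k, direction = c("forward", "backward"),
                              seed = 1L) {
  direction <- match.arg(direction)
  p <- ncol(X)
  if (direction == "forward") {
    sel <- integer(0)
    while (length(sel) < k) {
      cand <- setdiff(seq_len(p), sel)
      acc <- vapply(cand, function(j)
        lda_cv_accuracy(X[, c(sel, j), drop = FALSE], y, seed = seed), numeric(1))
      sel <- c(sel, cand[which.max(acc)])
    }
    sel
  } else {
    sel <- seq_len(p)
    while (length(sel) > k) {
      acc <- vapply(seq_along(sel), function(i)
        lda_cv_accuracy(X[, sel[-i], drop = FALSE], y, seed = seed), numeric(1))
      sel <- sel[-which.max(acc)]
    }
    sel
  }
}

#' Rank features with one of eight selection techniques
#'
#' Techniques: absolute Welch t statistic (`t_test`); greedy
#' maximum-relevance-minimum-redundancy mutual-information ranking (`mrmr`);
#' impurity importances from extremely randomized trees, random forests and
#' gradient-boosted trees (`importance_*`); the univariate ANOVA-F filter
#' (`univariate_k_best`); and greedy wrapper selection, forward or backward,
#' around a linear-discriminant learner scored by 5-fold cross-validated
#' accuracy (`sequential_forward` / `sequential_backward`). Deterministic for
#' a fixed `seed`.
#'
#' @param X numeric matrix or data.frame of ROI features (columns named).
#' @param y two-level factor or vector of ROI labels.
#' @param ranker one of the eight technique names (see `RANKERS` in the
#'   source).
#' @param k number of features to keep (default 25).
#' @param seed RNG seed for the stochastic rankers.
#' @return a `ranked_feature_list`.
#' @export
rank_features <- function(X, y, ranker, k = 25L, seed = 1L) {
  ranker <- match.arg(ranker, RANKERS)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("feature columns must be named")
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (k > ncol(X)) stop("k exceeds the number of features")
  y01 <- as.integer(y == levels(y)[2])
  ord_scores <- NULL
  idx <- switch(ranker,
    t_test = {
      s <- apply(X, 2, welch_t, y01 = y01)
      ord_scores <- s
      order(s, decreasing = TRUE)[seq_len(k)]
    },
    univariate_k_best = {
      s <- apply(X, 2, anova_f, y01 = y01)
      ord_scores <- s
      order(s, decreasing = TRUE)[seq_len(k)]
    },
    mrmr = mrmr_rank(X, y01, k),
    importance_extra_trees = {
      set.seed(seed)
      fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = 200,
                            splitrule = "extratrees", importance = "impurity",
                            num.threads = 1, seed = seed)
      s <- fit$variable.importance
      ord_scores <- s
      order(s, decreasing = TRUE)[seq_len(k)]
    },
    importance_random_forest = {
      set.seed(seed)
      fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = 200,
                            importance = "impurity", num.threads = 1, seed = seed)
      s <- fit$variable.importance
      ord_scores <- s
      order(s, decreasing = TRUE)[seq_len(k)]
    },
    importance_gradient_boosting = {
      set.seed(seed)
      dm <- xgboost::xgb.DMatrix(X, label = y01)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = 3, eta = 0.3,
                                              nthread = 1, seed = seed),
                                data = dm, nrounds = 50, verbose = 0)
      imp <- xgboost::xgb.importance(model = fit)
      s <- stats::setNames(rep(0, ncol(X)), colnames(X))
      s[imp$Feature] <- imp$Gain
      ord_scores <- s
      order(s, decreasing = TRUE)[seq_len(k)]
    },
    sequential_forward = sequential_select(X, y, k, "forward", seed),
    sequential_backward = sequential_select(X, y, k, "backward", seed)
  )
  sel <- colnames(X)[idx]
  sc <- if (!is.null(ord_scores)) unname(ord_scores[idx]) else NULL
  new_ranked_list(ranker, sel, sc)
}

#' Majority-rule merge of ranked feature lists
#'
#' A feature enters the final subset when it appears in at least `min_votes`
#' of the lists. The output is ordered by the feature registry (features
#' outside the registry keep first-appearance order after registry members),
#' so the merge is invariant to permuting its inputs. Raising `min_votes`
#' can only shrink the subset.
#'
#' @param lists list of `ranked_feature_list`s (or plain character vectors).
#' @param min_votes minimum number of lists a feature must appear in
#'   (default 4, calibrated so the merge of the study's eight published
#'   rankings returns its published 14-feature selection).
#' @return object of class `feature_subset` with elements `names` and
#'   `rule`.
#' @export
majority_merge <- function(lists, min_votes = 4L) {
  if (length(lists) < 2) stop("need at least two ranked lists")
  sets <- lapply(lists, function(l)
    unique(if (inherits(l, "ranked_feature_list")) l$selected else as.character(l)))
  votes <- table(unlist(sets))
  keep <- names(votes)[votes >= min_votes]
  if (length(keep) == 0)
    stop("majority merge is empty; lower min_votes")
  reg <- feature_registry()$name
  ordered <- c(reg[reg %in% keep], setdiff(keep, reg))
  structure(list(names = ordered,
                 rule = sprintf("feature kept iff present in >= %d of %d lists",
                                min_votes, length(sets)),
                 votes = votes[ordered]),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset: %d features (%s)>\n  %s\n",
              length(x$names), x$rule, paste(x$names, collapse = ", ")))
  invisible(x)
}

#' The study's eight published feature rankings
#'
#' A transcription of the eight ranked lists (one per selection technique)
#' published for the classification round, shipped as a plain-text fixture.
#' Majority-merging them with the default `min_votes` reproduces the
#' published 14-feature selection.
#'
#' @return named list of character vectors, one per ranker.
#' @export
published_rankings <- function() {
  path <- system.file("extdata", "published_rankings.csv", package = "mammodelta")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df$feature, df$ranker)[unique(df$ranker)]
}

#' Export rankings as CSV
#' @param lists list of `ranked_feature_list`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rankings <- function(lists, path) {
  df <- do.call(rbind, lapply(lists, function(l)
    data.frame(ranker = l$ranker, rank = seq_along(l$selected),
               feature = l$selected, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
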