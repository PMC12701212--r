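test_that("ADASYN balances to near-parity and keeps originals unchanged", {
  set.seed(1)
  X <- rbind(matrix(rnorm(10 * 4, mean = 2), 10, 4),
             matrix(rnorm(100 * 4), 100, 4))
  y <- factor(c(rep("pos", 10), rep("neg", 100)), levels = c("neg", "pos"))
  out <- adasyn_balance(X, y, seed = 3)
  counts <- table(out$y)
  expect_gte(min(counts) / max(counts), 0.9)   # within 10% of 1:1
  expect_true(sum(out$y == "pos") >= 90 && sum(out$y == "pos") <= 110)
  expect_identical(out$X[seq_len(nrow(X)), ], X)
  expect_false(any(out$synthetic[seq_len(nrow(X))]))
})

test_that("ADASYN leaves balanced input essentially untouched", {
  set.seed(2)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- factor(rep(c("a", "b"), each = 60))
  out <- adasyn_balance(X, y, seed = 1)
  expect_lte(nrow(out$X) - nrow(X), ceiling(0.01 * nrow(X)))
})

test_that("every synthetic sample lies on a segment between minority points", {
  set.seed(7)
  Xm <- matrix(rnorm(12 * 3), 12, 3)
  X <- rbind(Xm, matrix(rnorm(80 * 3, mean = 3), 80, 3))
  y <- factor(c(rep("min", 12), rep("maj", 80)), levels = c("maj", "min"))
  out <- adasyn_balance(X, y, seed = 11)
  syn <- out$X[out$synthetic, , drop = FALSE]
  expect_gt(nrow(syn), 0)
  for (i in seq_len(nrow(syn))) {
    s <- syn[i, ]
    resid <- Inf
    for (a in seq_len(nrow(Xm))) for (b in seq_len(nrow(Xm))) {
      if (a == b) next
      d <- Xm[b, ] - Xm[a, ]
      lam <- sum((s - Xm[a, ]) * d) / sum(d * d)
      if (lam < -1e-9 || lam > 1 + 1e-9) next
      resid <- min(resid, sqrt(sum((Xm[a, ] + lam * d - s)^2)))
    }
    expect_lt(resid, 1e-9)
  }
})

test_that("a too-small minority falls back to duplication with a warning", {
  X <- rbind(matrix(rnorm(3 * 2), 3, 2), matrix(rnorm(40 * 2, 2), 40, 2))
  y <- factor(c(rep("m", 3), rep("M", 40)), levels = c("M", "m"))
  expect_warning(out <- adasyn_balance(X, y, seed = 1), "duplication")
  expect_equal(sum(out$y == "m"), 40)
})

test_that("classifier families fit separable data and are seed-deterministic", {
  d <- make_separable_data(n = 120, p = 4, gap = 5)
  for (fam in c("lda", "svm", "naive_bayes", "knn", "extra_trees",
                "random_forest", "gradient_boosting", "adaboost", "ann")) {
    # the ann defaults (batch 128, lr 1e-4, 100 epochs) are sized for the
    # full ROI table; on this 120-row toy give the optimizer enough steps
    hp <- if (fam == "ann") list(learning_rate = 0.01, epochs = 300) else list()
    spec <- classifier_spec(fam, hp, seed = 4)
    m <- train_classifier(spec, d$X, d$y)
    acc <- mean(predict_labels(m, d$X) == (d$y == levels(d$y)[2]))
    expect_gt(acc, 0.95)
    s1 <- predict_scores(m, d$X)
    m2 <- train_classifier(spec, d$X, d$y)
    expect_identical(s1, predict_scores(m2, d$X))
  }
  expect_error(train_classifier(classifier_spec("lda"), d$X,
                                rep("one", nrow(d$X))), "single-class")
})

test_that("svm-linear and lda reach 100% training accuracy on separable data", {
  d <- make_separable_data(n = 80, p = 2, gap = 8)
  for (spec in list(classifier_spec("lda"),
                    classifier_spec("svm", list(kernel = "linear")))) {
    m <- train_classifier(spec, d$X, d$y)
    expect_equal(mean(predict_labels(m, d$X) == (d$y == "1")), 1)
  }
})

test_that("label-permuted training yields chance-level held-out AUC", {
  set.seed(15)
  aucs <- replicate(20, {
    X <- matrix(rnorm(160 * 4), 160, 4); colnames(X) <- paste0("f", 1:4)
    y <- factor(rep(c(0, 1), 80))
    tr <- sample(160, 110)
    m <- train_classifier(classifier_spec("lda"), X[tr, ], sample(y[tr]))
    s <- predict_scores(m, X[-tr, ])
    compute_metrics(as.integer(s >= 0.5), y[-tr] == 1, scores = s)$auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("ensemble voting follows its stated rules", {
  d <- make_separable_data(n = 60, p = 3, gap = 6)
  es <- ensemble_spec(members = list(classifier_spec("lda"),
                                     classifier_spec("naive_bayes"),
                                     classifier_spec("knn", list(k = 5))),
                      voting = "soft")
  m <- train_classifier(es, d$X, d$y)
  out <- ensemble_predict(m, d$X)
  expect_equal(out$labels, as.integer(out$scores >= 0.5))
  expect_equal(mean(out$labels == (d$y == "1")), 1)
  # soft arithmetic: mean of {0.9, 0.2, 0.7} crosses 0.5
  expect_equal(mean(c(0.9, 0.2, 0.7)) >= 0.5, TRUE)
  # hard 2-2 tie goes to the positive class
  fake <- m
  fake$spec$voting <- "hard"
  probs <- matrix(c(0.9, 0.9, 0.1, 0.1), 1)  # two votes up, two down
  votes <- rowSums(probs >= 0.5)
  expect_equal(as.integer(votes * 2 >= ncol(probs)), 1L)
})

test_that("metrics reproduce the published confusion arithmetic", {
  # sensitivity from 58/62, specificity 7179/7263, accuracy 7237/7325
  preds <- c(rep(1, 58), rep(0, 4), rep(0, 7179), rep(1, 84))
  labs <- c(rep(1, 62), rep(0, 7263))
  r <- compute_metrics(preds, labs)
  expect_equal(round(r$sensitivity, 2), 93.55)
  expect_equal(round(r$specificity, 2), 98.84)
  expect_equal(round(r$accuracy, 2), 98.80)
  expect_equal(r$tp + r$fn + r$tn + r$fp, r$n_total)
})

test_that("AUC is the rank statistic: separable gives 1, random gives ~0.5", {
  labs <- rep(c(1, 0), c(40, 60))
  scores <- c(runif(40, 0.6, 1), runif(60, 0, 0.4))
  expect_equal(compute_metrics(as.integer(scores >= 0.5), labs,
                               scores = scores)$auc, 1)
  set.seed(19)
  labs <- rep(c(1, 0), each = 2500)
  r <- compute_metrics(rep(0, 5000), labs, scores = runif(5000))
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labs <- rbinom(300, 1, 0.3)
  scores <- rnorm(300) + labs
  mine <- compute_metrics(as.integer(scores > 0), labs, scores = scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labs, scores, quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("FP per image and per-patient sensitivity are computed", {
  labs <- c(1, 0, 0, 0, 1, 0)
  preds <- c(1, 1, 0, 0, 0, 1)
  imgs <- c("a", "a", "a", "b", "b", "c")
  pats <- c("p1", "p1", "p1", "p2", "p2", "p3")
  r <- compute_metrics(preds, labs, images = imgs, patients = pats)
  expect_equal(r$fp_per_image, 2 / 3)
  expect_equal(r$per_patient_sensitivity, 0.5)  # p1 detected, p2 missed
})

test_that("extended McNemar matches hand arithmetic and symmetry", {
  labs <- rep(1, 20)
  a <- rep(1, 20)                       # always right
  expect_equal(mcnemar_extended(a, a, labs)$p_value, 1)
  # b = 10 discordant favouring A, c = 2 favouring B
  labs <- rep(1, 40)
  pa <- c(rep(1, 30), rep(0, 10)); pb <- c(rep(1, 20), rep(0, 18), rep(1, 2))
  r <- mcnemar_extended(pa, pb, labs)
  expect_equal(r$b, 10); expect_equal(r$c, 2)
  expect_equal(r$statistic, 49 / 12, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(49 / 12, 1, lower.tail = FALSE))
  # b == c: minimal statistic, maximal p
  pa2 <- c(rep(1, 35), rep(0, 5)); pb2 <- c(rep(0, 5), rep(1, 35))
  r2 <- mcnemar_extended(pa2, pb2, labs)
  expect_equal(r2$b, r2$c)
  expect_gt(r2$p_value, 0.5)
})

test_that("extended McNemar agrees with the base implementation", {
  set.seed(31)
  labs <- rbinom(200, 1, 0.5)
  pa <- ifelse(runif(200) < 0.8, labs, 1 - labs)
  pb <- ifelse(runif(200) < 0.7, labs, 1 - labs)
  mine <- mcnemar_extended(pa, pb, labs)
  ref <- stats::mcnemar.test(table(factor(pa == labs, c(FALSE, TRUE)),
                                   factor(pb == labs, c(FALSE, TRUE))))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("pairwise McNemar applies the multiplicity adjustment", {
  set.seed(37)
  labs <- rbinom(150, 1, 0.5)
  preds <- list(a = ifelse(runif(150) < 0.9, labs, 1 - labs),
                b = ifelse(runif(150) < 0.6, labs, 1 - labs),
                c = labs)
  out <- mcnemar_pairwise(preds, labs)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_adjusted >= out$p_value))
  expect_true(all(out$p_adjusted <= 1))
})

test_that("grouped CV keeps patients intact and pools all ROIs", {
  set.seed(41)
  n_pat <- 8
  rows <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    k <- 12
    mal <- i <= 4
    data.frame(f1 = rnorm(k) + ifelse(mal & seq_len(k) == 1, 6, 0),
               f2 = rnorm(k),
               patient_id = sprintf("p%d", i), view = "CC", roi_id = seq_len(k),
               label = ifelse(mal & seq_len(k) == 1, "future_malignant", "normal"),
               case_label = ifelse(mal, "malignant", "normal"))
  }))
  rep <- run_cv(rows, cv_scheme("lopo"), classifier_spec("lda"),
                feature_subset = c("f1", "f2"), seed = 1, audit = TRUE)
  expect_equal(rep$n_total, nrow(rows))
  aud <- attr(rep, "audit")
  expect_length(aud, n_pat)   # one fold per patient
  for (fold in aud) {
    expect_length(fold$test_patients, 1)
    expect_false(fold$test_patients %in% fold$training_patients)
    expect_false(fold$test_patients %in% fold$scaler_patients)
    expect_false(fold$test_patients %in% fold$adasyn_patients)
  }
  # kfold: disjoint folds covering all patients, stratified
  rep5 <- run_cv(rows, cv_scheme("kfold", 4), classifier_spec("lda"),
                 feature_subset = c("f1", "f2"), seed = 1, audit = TRUE)
  aud5 <- attr(rep5, "audit")
  tested <- unlist(lapply(aud5, function(f) f$test_patients))
  expect_setequal(tested, sprintf("p%d", 1:8))
  expect_equal(length(tested), 8)
})

test_that("grouped CV separates a constructed signal perfectly", {
  set.seed(43)
  rows <- do.call(rbind, lapply(1:10, function(i) {
    k <- 10
    mal <- i <= 5
    data.frame(f1 = rnorm(k) + ifelse(mal & seq_len(k) <= 2, 8, 0),
               f2 = rnorm(k),
               patient_id = sprintf("p%d", i), view = "CC", roi_id = seq_len(k),
               label = ifelse(mal & seq_len(k) <= 2, "future_malignant", "normal"),
               case_label = ifelse(mal, "malignant", "normal"))
  }))
  rep <- run_cv(rows, cv_scheme("lopo"), classifier_spec("lda"),
                feature_subset = c("f1", "f2"), seed = 2)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$auc, 1)
})
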