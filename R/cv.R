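# Patient-grouped cross-validation (leave-one-patient-out and per-patient
# k-fold), evaluation metrics, and the extended McNemar comparison of
# classifiers. All fold-local fitting (standardization, ADASYN, feature
# selection when per-fold, classifier training) sees training patients only.

#' Cross-validation scheme
#'
#' @param kind "lopo" (leave one patient out) or "kfold".
#' @param k number of folds for kfold (the study used 5 and 15, chosen to
#'   divide the 75 patients evenly).
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("lopo", "kfold"), k = 5L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), grouping = "patient_id"),
            class = "cv_scheme")
}

# Patient-level fold assignment; kfold is stratified by case label and
# shuffled with the given seed. Returns list of character vectors of test
# patients (disjoint, covering all patients).
make_patient_folds <- function(patients, labels, scheme, seed = 0L) {
  stopifnot(length(patients) == length(labels), !anyDuplicated(patients))
  if (scheme$kind == "lopo") return(as.list(patients))
  set.seed(seed)
  folds <- vector("list", scheme$k)
  for (lab in unique(labels)) {
    idx <- sample(which(labels == lab))
    assign <- rep_len(seq_len(scheme$k), length(idx))
    for (f in seq_len(scheme$k))
      folds[[f]] <- c(folds[[f]], patients[idx[assign == f]])
  }
  folds
}

#' Evaluation metrics from pooled per-ROI predictions
#'
#' Sensitivity, specificity and accuracy from the pooled confusion counts;
#' AUC by the Mann-Whitney rank statistic over the pooled scores (midranks
#' for ties); false positives per subtraction image; and per-patient
#' sensitivity, where a malignant patient counts as detected as soon as any
#' of their true-mass ROIs (either view) is flagged.
#'
#' @param predictions integer vector (1 = predicted future malignancy).
#' @param labels integer or character vector of ground-truth ROI labels
#'   (1/"future_malignant" = positive).
#' @param scores numeric classifier scores (for AUC); optional.
#' @param images character vector of image identifiers per ROI (for
#'   FP-per-image); optional.
#' @param patients character vector of patient ids per ROI (for per-patient
#'   sensitivity); optional.
#' @return object of class `evaluation_report`.
#' @export
compute_metrics <- function(predictions, labels, scores = NULL, images = NULL,
                            patients = NULL) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "future_malignant")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(predictions) != length(labels))
    stop("length mismatch between predictions and labels")
  tp <- sum(predictions == 1 & labels == 1)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  auc <- if (!is.null(scores) && length(unique(labels)) == 2) {
    r <- rank(scores)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  fppi <- if (!is.null(images)) fp / length(unique(images)) else NA_real_
  pps <- NA_real_
  if (!is.null(patients)) {
    mal <- unique(patients[labels == 1])
    if (length(mal)) {
      det <- unique(patients[labels == 1 & predictions == 1])
      pps <- length(det) / length(mal)
    }
  }
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = 100 * tp / max(tp + fn, 1L),
    specificity = 100 * tn / max(tn + fp, 1L),
    accuracy = 100 * (tp + tn) / max(length(labels), 1L),
    auc = auc, fp_per_image = fppi, per_patient_sensitivity = pps,
    n_total = length(labels)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (per-ROI, pooled over folds)\n")
  cat(sprintf("  Sensitivity : %d/%d  %.2f%%\n", x$tp, x$tp + x$fn, x$sensitivity))
  cat(sprintf("  Specificity : %d/%d  %.2f%%\n", x$tn, x$tn + x$fp, x$specificity))
  cat(sprintf("  Accuracy    : %d/%d  %.2f%%\n", x$tp + x$tn, x$n_total, x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC         : %.3f\n", x$auc))
  if (!is.na(x$fp_per_image)) cat(sprintf("  FP/image    : %.3f\n", x$fp_per_image))
  if (!is.na(x$per_patient_sensitivity))
    cat(sprintf("  Per-patient sensitivity: %.2f\n", x$per_patient_sensitivity))
  invisible(x)
}

#' Patient-grouped cross-validation of one classifier
#'
#' Per fold: standardize features on training patients, balance the training
#' set with ADASYN (the test fold is never augmented), fit the classifier,
#' and score the test patients. Per-ROI predictions are pooled across folds
#' before metrics are computed. Fold construction is by patient, so no
#' patient contributes ROIs to both sides of a fold.
#'
#' @param dataset data.frame from [roi_feature_table()] rows: feature
#'   columns plus `patient_id`, `view`, `roi_id`, `label`, and optionally a
#'   patient-level `case_label` used for stratification.
#' @param scheme a [cv_scheme()].
#' @param spec a [classifier_spec()] or [ensemble_spec()].
#' @param feature_subset character vector of feature names to use (e.g. a
#'   [majority_merge()] result); NULL = all registry features present.
#' @param seed RNG seed (fold shuffling, ADASYN, stochastic learners).
#' @param audit collect per-fold bookkeeping proving which patients entered
#'   each fitting stage (used by the leakage audit).
#' @param per_fold_selection optional function `(X, y) -> feature names`
#'   refit on every training fold (after balancing); the matrix it receives
#'   carries a `patients` attribute naming the patients it was built from.
#' @return an `evaluation_report`; with `audit = TRUE` the report carries an
#'   `audit` attribute, and always a `fold_predictions` data.frame.
#' @export
run_cv <- function(dataset, scheme = cv_scheme("lopo"), spec = ensemble_spec(),
                   feature_subset = NULL, seed = 0L, audit = FALSE,
                   per_fold_selection = NULL) {
  meta_cols <- c("patient_id", "view", "roi_id", "label", "case_label")
  feats <- setdiff(names(dataset), meta_cols)
  if (!is.null(feature_subset)) {
    if (inherits(feature_subset, "feature_subset"))
      feature_subset <- feature_subset$names
    missing <- setdiff(feature_subset, feats)
    if (length(missing))
      stop(sprintf("features not in dataset: %s", paste(missing, collapse = ", ")))
    feats <- feature_subset
  }
  y <- factor(dataset$label, levels = c("normal", "future_malignant"))
  if (anyNA(y)) stop("labels must be 'normal' or 'future_malignant'")
  pat <- as.character(dataset$patient_id)
  pat_tab <- unique(data.frame(
    patient_id = pat,
    case_label = if ("case_label" %in% names(dataset))
      as.character(dataset$case_label)
    else ave(as.character(y), pat, FUN = function(v)
      if (any(v == "future_malignant")) "malignant" else "normal"),
    stringsAsFactors = FALSE))
  folds <- make_patient_folds(pat_tab$patient_id, pat_tab$case_label,
                              scheme, seed = seed)
  X <- as.matrix(dataset[, feats, drop = FALSE])
  pred <- integer(nrow(X)); score <- numeric(nrow(X))
  audit_log <- list()
  for (f in seq_along(folds)) {
    te <- pat %in% folds[[f]]
    if (!any(te)) next
    tr <- !te
    if (length(intersect(pat[tr], pat[te])) > 0)
      stop("patient appears in both training and test folds")
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) == 2) {
      bal <- adasyn_balance(Xtr, ytr, seed = derive_seed(seed, f))
      Xb <- bal$X; yb <- bal$y
    } else {
      Xb <- Xtr; yb <- ytr
    }
    if (!is.null(per_fold_selection)) {
      attr(Xb, "patients") <- sort(unique(pat[tr]))
      sel <- per_fold_selection(Xb, yb)
      sel <- intersect(sel, colnames(Xb))
      Xb <- Xb[, sel, drop = FALSE]
      Xte <- Xte[, sel, drop = FALSE]
    }
    # features constant on the balanced training fold carry no information
    # and break the discriminant families; drop them for this fold
    sds <- apply(Xb, 2, stats::sd)
    keepc <- !is.na(sds) & sds > 1e-10
    if (!all(keepc)) {
      Xb <- Xb[, keepc, drop = FALSE]
      Xte <- Xte[, keepc, drop = FALSE]
    }
    spec_f <- spec
    spec_f$seed <- derive_seed(seed, f)
    if (spec$family == "ensemble_voting")
      spec_f$members <- lapply(spec$members, function(m) {
        m$seed <- derive_seed(seed, f); m
      })
    model <- train_classifier(spec_f, Xb, yb)
    score[te] <- predict_scores(model, Xte)
    pred[te] <- predict_labels(model, Xte)
    if (audit)
      audit_log[[f]] <- list(
        test_patients = sort(unique(pat[te])),
        scaler_patients = sort(unique(pat[tr])),
        adasyn_patients = sort(unique(pat[tr])),
        selection_patients = if (is.null(per_fold_selection)) character(0)
        else sort(unique(pat[tr])),
        training_patients = sort(unique(pat[tr])),
        n_train_rows = nrow(Xb), n_test_rows = sum(te))
  }
  images <- paste(dataset$patient_id, dataset$view, sep = "/")
  rep <- compute_metrics(pred, y == "future_malignant", scores = score,
                         images = images, patients = pat)
  rep$fold_predictions <- data.frame(
    patient_id = dataset$patient_id, view = dataset$view,
    roi_id = dataset$roi_id, label = as.character(y),
    score = score, prediction = pred, stringsAsFactors = FALSE)
  rep$scheme <- scheme
  if (audit) attr(rep, "audit") <- audit_log
  rep
}

#' Extended McNemar comparison of two classifiers
#'
#' Continuity-corrected chi-square on the discordant pairs of the 2x2
#' correct/incorrect table over the same test ROIs:
#' `(|b - c| - 1)^2 / (b + c)` with b = pairs only classifier A got right
#' and c = pairs only B got right. With no discordant pairs the classifiers
#' are indistinguishable and p = 1.
#'
#' @param preds_a,preds_b integer predictions of the two classifiers.
#' @param labels ground-truth ROI labels (1/"future_malignant" = positive).
#' @return list with `statistic`, `p_value`, `b`, `c`.
#' @export
mcnemar_extended <- function(preds_a, preds_b, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "future_malignant")
  stopifnot(length(preds_a) == length(labels), length(preds_b) == length(labels))
  ca <- preds_a == labels; cb <- preds_b == labels
  b <- sum(ca & !cb); c <- sum(!ca & cb)
  if (b + c == 0) return(list(statistic = 0, p_value = 1, b = b, c = c))
  stat <- (abs(b - c) - 1)^2 / (b + c)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = c)
}

#' Pairwise extended McNemar tests with multiplicity adjustment
#'
#' Applies [mcnemar_extended()] to every classifier pair and adjusts the
#' p-values (Bonferroni by default) -- the multi-comparison form used to
#' compare an ensemble against all other classifiers.
#'
#' @param predictions named list of prediction vectors on the same ROIs.
#' @param labels ground-truth labels.
#' @param method p-adjustment method (see [stats::p.adjust()]).
#' @return data.frame with one row per pair.
#' @export
mcnemar_pairwise <- function(predictions, labels, method = "bonferroni") {
  nm <- names(predictions)
  pairs <- utils::combn(length(predictions), 2)
  res <- apply(pairs, 2, function(ij) {
    r <- mcnemar_extended(predictions[[ij[1]]], predictions[[ij[2]]], labels)
    c(statistic = r$statistic, p_value = r$p_value)
  })
  out <- data.frame(a = nm[pairs[1, ]], b = nm[pairs[2, ]],
                    statistic = res["statistic", ],
                    p_value = res["p_value", ], stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = method)
  out
}
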