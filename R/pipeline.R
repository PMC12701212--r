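# End-to-end orchestration. Part A establishes the ground truth by
# registering the future round onto the current one and propagating the mass
# annotation; Part B aligns and subtracts the prior from the current round,
# segments candidate ROIs, extracts features and evaluates classifiers under
# patient-grouped cross-validation.

#' Default pipeline configuration
#'
#' Nested per-module parameter lists; every value can be overridden and the
#' whole object round-trips through JSON (see [read_pipeline_config()]).
#'
#' @param seed master seed.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 0L) {
  structure(list(
    preprocess = preprocess_config(),
    registration = demons_config(),
    subtraction = list(unsharp_radius = 5, unsharp_amount = 1.0,
                       keep_signed = FALSE),
    segmentation = segmentation_config(),
    glcm = glcm_spec(),
    selection = list(min_votes = 4L, k = 25L, mode = "fixed"),
    classify = list(voting = "soft"),
    cv = list(kind = "lopo", k = 5L),
    seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(seed = raw$seed %||% 0L)
  for (section in intersect(names(raw), names(cfg))) {
    if (is.list(raw[[section]]))
      for (key in intersect(names(raw[[section]]), names(cfg[[section]])))
        cfg[[section]][[key]] <- raw[[section]][[key]]
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(lapply(cfg, unclass), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Part A: propagate future mass annotations onto the current round
#'
#' For every malignant case and view with a mass: preprocess the future and
#' current images, register future to current (current fixed) with Demons,
#' and warp the expert mask through the field. The future images play no
#' further role after this step. Failures are logged per case and skipped.
#'
#' @param cohort a `cohort_manifest`.
#' @param config a [default_config()]-style `pipeline_config`.
#' @param progress print one line per case.
#' @return named list `masks[[patient_id]][[view]]` of propagated
#'   `annotation_mask`s, with a `failures` attribute.
#' @export
run_part_a <- function(cohort, config = default_config(), progress = FALSE) {
  out <- list()
  failures <- character(0)
  for (cs in cohort$cases) {
    if (cs$label != "malignant") next
    if (progress) message("part A: ", cs$patient_id)
    for (view in names(cs$future_masks)) {
      res <- tryCatch({
        cur <- preprocess_image(cs$images[[paste0("current_", view)]],
                                config$preprocess)
        fut <- preprocess_image(cs$images[[paste0("future_", view)]],
                                config$preprocess)
        field <- demons_register(cur, fut, config$registration)
        propagate_future_mask(cs$future_masks[[view]], field)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s/%s: %s", cs$patient_id, view,
                                        conditionMessage(res)))
      } else {
        out[[cs$patient_id]][[view]] <- res
      }
    }
  }
  attr(out, "failures") <- failures
  out
}

process_case_view <- function(cs, view, gt_mask, config) {
  cur <- preprocess_image(cs$images[[paste0("current_", view)]], config$preprocess)
  pri <- preprocess_image(cs$images[[paste0("prior_", view)]], config$preprocess)
  breast <- segment_breast(cur)
  field <- demons_register(cur, pri, config$registration)
  pri_reg <- warp_image(pri, field)
  sub <- temporal_subtract(cur, pri_reg,
                           keep_signed = isTRUE(config$subtraction$keep_signed))
  enh <- unsharp_enhance(sub, radius = config$subtraction$unsharp_radius,
                         amount = config$subtraction$unsharp_amount)
  enh$pixels <- pmin(enh$pixels, 1)
  list(enhanced = enh, breast = breast)
}

#' Part B: subtraction, segmentation, features and grouped evaluation
#'
#' Per case and view: preprocess prior and current, register prior to
#' current, subtract, enhance, segment candidate ROIs, label them against
#' the Part A ground truth, and extract the 98-feature vector per ROI. The
#' pooled feature table is then evaluated with the configured classifier
#' under the configured patient-grouped scheme. Per-case failures are
#' logged and excluded.
#'
#' @param cohort a `cohort_manifest`.
#' @param gt_masks output of [run_part_a()].
#' @param config a `pipeline_config`.
#' @param spec classifier/ensemble specification (default: the soft-voting
#'   ensemble of LDA, k-NN (k=9), polynomial SVM, naive Bayes and extra
#'   trees).
#' @param scheme a [cv_scheme()] (default LOPO).
#' @param feature_subset `"fixed"` (the published 14-feature majority
#'   selection; default), `"all"`, or an explicit character vector.
#' @param progress print one line per case.
#' @return list with `report` (an `evaluation_report`), `dataset` (the
#'   feature table), `threshold` and `failures`.
#' @export
run_part_b <- function(cohort, gt_masks, config = default_config(),
                       spec = NULL, scheme = NULL, feature_subset = "fixed",
                       progress = FALSE) {
  if (is.null(spec)) spec <- ensemble_spec(voting = config$classify$voting)
  if (is.null(scheme)) scheme <- cv_scheme(config$cv$kind, config$cv$k)
  segcfg <- config$segmentation
  thr <- segcfg$threshold
  tables <- list()
  failures <- character(0)
  prepared <- list()
  for (cs in cohort$cases) {
    if (progress) message("part B: ", cs$patient_id)
    for (view in c("CC", "MLO")) {
      key <- paste(cs$patient_id, view, sep = "/")
      res <- tryCatch(process_case_view(cs, view, NULL, config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s: %s", key, conditionMessage(res)))
        next
      }
      prepared[[key]] <- list(case = cs, view = view, data = res)
    }
  }
  if (identical(thr, "auto")) {
    imgs <- lapply(prepared, function(p) p$data$enhanced)
    gts <- lapply(prepared, function(p)
      gt_masks[[p$case$patient_id]][[p$view]])
    breasts <- lapply(prepared, function(p) p$data$breast)
    thr <- select_threshold(imgs, gts, breasts, segcfg)
  }
  for (key in names(prepared)) {
    p <- prepared[[key]]
    res <- tryCatch({
      rois <- segment_one(p$data$enhanced, p$data$breast, segcfg, thr)
      gt <- gt_masks[[p$case$patient_id]][[p$view]]
      rois <- assign_gt_labels(rois, gt, segcfg$overlap_fraction)
      roi_feature_table(rois, p$data$enhanced,
                        list(patient_id = p$case$patient_id, view = p$view,
                             age = p$case$age,
                             birads_density = p$case$birads_density),
                        config$glcm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", key, conditionMessage(res)))
      next
    }
    res$case_label <- rep(p$case$label, nrow(res))
    tables[[key]] <- res
  }
  if (length(tables) == 0) stop("no case produced ROIs; nothing to evaluate")
  dataset <- do.call(rbind, tables)
  rownames(dataset) <- NULL
  subset_names <- NULL
  if (identical(feature_subset, "fixed")) {
    subset_names <- majority_merge(published_rankings(),
                                   config$selection$min_votes)$names
  } else if (!identical(feature_subset, "all")) {
    subset_names <- feature_subset
  }
  report <- run_cv(dataset, scheme = scheme, spec = spec,
                   feature_subset = subset_names, seed = config$seed)
  list(report = report, dataset = dataset, threshold = thr,
       failures = failures)
}

#' Localization error of propagated masks on a synthetic cohort
#'
#' Compares each propagated mask centroid with the generator's true
#' current-round mass center; a case/view counts as localized when the
#' centroid error is below the true mass radius.
#'
#' @param cohort a synthetic `cohort_manifest` (cases carry `truth`).
#' @param gt_masks output of [run_part_a()].
#' @return data.frame with one row per malignant case/view.
#' @export
localization_report <- function(cohort, gt_masks) {
  rows <- list()
  for (cs in cohort$cases) {
    truth <- attr(cs, "truth")
    if (is.null(truth) || length(truth) == 0) next
    for (view in names(truth)) {
      m <- gt_masks[[cs$patient_id]][[view]]
      if (is.null(m) || sum(m$pixels) == 0) {
        rows[[paste(cs$patient_id, view)]] <- data.frame(
          patient_id = cs$patient_id, view = view, error_px = NA_real_,
          radius = truth[[view]]$radius, localized = FALSE)
        next
      }
      idx <- which(m$pixels > 0)
      ctr <- c(mean(((idx - 1) %% nrow(m$pixels)) + 1),
               mean(((idx - 1) %/% nrow(m$pixels)) + 1))
      err <- sqrt(sum((ctr - truth[[view]]$center)^2))
      rows[[paste(cs$patient_id, view)]] <- data.frame(
        patient_id = cs$patient_id, view = view, error_px = err,
        radius = truth[[view]]$radius, localized = err < truth[[view]]$radius)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
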